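---
title: "Methods: radiobiological modelling of spherical-applicator kV IORT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiobiological modelling of spherical-applicator kV IORT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iortbio)
```

## The problem

After breast-conserving surgery, residual microscopic cancer cells remain
in the tumour bed, their density falling with distance from the excision
surface. Intraoperative radiotherapy with a low-kV source in a spherical
applicator (IB-IORT) delivers a single large dose whose intensity drops
steeply with depth, so the question of whether a prescription "covers" the
residual disease has no single answer: it depends on how far the cells
infiltrate. This package quantifies that dependence through three linked
quantities:

1. the **average survival** of the residual cancer-cell population under
   the non-uniform dose;
2. the **equivalent uniform dose (EUD)** — the constant dose that would
   produce the same average survival; and
3. the **therapeutic ratio (TR)** — how much better interspersed normal
   tissue survives under the falling applicator dose than under that
   EUD-matched uniform dose.

## Dose field

The applicator dose is modelled as spherically symmetric. The normalized
depth-dose curve is

$$f(x) = \left(\frac{r_0}{r_0 + x}\right)^2 e^{-a x - b x^2},$$

inverse square from the source at the sphere centre times a two-parameter
attenuation/scatter term. The coefficients $(a, b)$ are solved exactly
from the two non-surface anchor points (fraction 0.35 at 1 cm, 0.10 at
2 cm for the 50 kV beam with the 4-cm applicator), giving
$a \approx 0.0196\ \mathrm{cm^{-1}}$, $b \approx 0.219\ \mathrm{cm^{-2}}$
and $f(2.5\,\mathrm{cm}) \approx 0.048$, comfortably below the 10%
clinical falloff requirement at 2.5 cm. A single-exponential attenuation
term cannot pass through both anchors, which is why the quadratic exponent
is needed.

This module is the package's stand-in for commissioning data that are not
publicly deposited: it reproduces the printed anchor doses exactly, but
between 0 and 1 cm it is an interpolation constrained only by smoothness.
Two consequences matter for interpreting everything downstream:

* **What it does capture** — the overall falloff scale, the anchor doses,
  and the sub-10% dose beyond 2.5 cm. EUDs, which average survival over
  the infiltrated region, inherit the anchor accuracy to within roughly
  ten percent.
* **What it cannot capture** — the dose gradient within the first few
  millimetres, which no printed anchor constrains. Therapeutic ratios at
  small infiltration extents and high doses are exponentially sensitive to
  exactly that gradient, so they carry much wider uncertainty than the
  EUDs; this is also why the TR-versus-extent curve can peak at 9 mm
  rather than 6 mm depending on the assumed near-surface shape. A real
  commissioning curve, if available, can be supplied to
  `fit_radial_dose()` as additional anchors.

`perturb_dose_model()` produces scaled/jittered refits for propagating a
dosimetric uncertainty of up to ~10% through the pipeline.

The 40 kV beam is given the same normalized shape — the energy difference
has a minor dosimetric effect — but its surface dose rate is lower by a
factor 1.87, so the standard treatment time is 0.9 h instead of 0.5 h, and
`forty_kv_delivery()` reports the surface dose reached if a 40 kV
treatment is stopped at the 50 kV time.

## Survival model

Survival follows the modified linear-quadratic (MLQ) model,

$$SF = \exp\!\big(-\alpha D - \beta\,G(\lambda T + \delta D)\,D^2\big),
\qquad G(\theta) = \frac{2(\theta + e^{-\theta} - 1)}{\theta^2},$$

where the dose-protraction factor $G \in (0, 1]$ accounts for
sublethal-damage repair (rate $\lambda$) during the delivery time $T$, and
the $\delta D$ term extends the repair argument at high doses, where the
classical LQ model is known to overestimate killing. Setting $\delta = 0$
recovers classical LQ exactly.

Parameter defaults (packaged in `cell_lines()`): two cancer lines —
acutely responding C1 ($\alpha = 0.3\,\mathrm{Gy^{-1}}$,
$\beta = 0.03\,\mathrm{Gy^{-2}}$, $\alpha/\beta = 10$ Gy) and slowly
responding C2 ($0.2$, $0.052$, $3.85$ Gy) — and three normal tissues with
$\alpha/\beta = 3.1$ Gy chosen so that acute $SF(2\,\mathrm{Gy})$ is 0.3
(N1), 0.5 (N2) and 0.7 (N3). All five share
$\delta = 0.15\,\mathrm{Gy^{-1}}$ and $\lambda = 0.693\,\mathrm{h^{-1}}$,
i.e. a 1-hour repair half-life.

## Infiltration profiles and shell averaging

Residual cancer-cell density versus depth is either

* **half-Gaussian**: $f_0\,e^{-x^2/2\sigma^2}$ with the infiltration
  extent defined as $3\sigma$ and the density truncated to zero beyond it
  (at the cutoff the shape has fallen to $e^{-4.5} \approx 1.1\%$ of its
  surface value, low enough that the truncated tail is negligible); or
* **linear**: $f_0\,(1 - x/\mathrm{extent})$.

Extents of 1.5, 3, 6, 9 and 15 mm and surface fractions $f_0$ of 10%, 1%
and 0.01% span the study grid. The half-Gaussian is the shape that "hugs"
the falling dose curve: its mean infiltration depth is $0.79\sigma$
against $1.0\sigma$ for the linear profile of equal extent, which is why
it yields equal-or-higher EUD and TR throughout.

Averages are taken over concentric spherical shells of 0.5 mm radial
thickness tiling exactly $[0, \mathrm{extent}]$ — at most 30 shells for
the largest extent. Shell volumes are exact spherical-shell differences,
and dose and density are evaluated at shell midpoints; with monotone
integrands and sub-millimetre shells the midpoint rule keeps the
discretization error far below the dosimetric uncertainty. Both the
cancer average (weights $V_i f_c$) and the normal average (weights
$V_i(1 - f_c)$) are restricted to the infiltrated region, because that is
the region over which the tumour-kill average is defined; extending the
normal-tissue average deeper would raise every TR and is a modelling
choice, not a computation detail, so it is left to the user via the
profile extent.

Two exact structural properties follow from the weight ratio and are
enforced in the tests: the cancer average (hence the EUD) is invariant to
the surface fraction $f_0$ (it cancels), and a uniform dose field gives
$TR = 1$ identically.

## Numerics

* $G(\theta)$ is evaluated by its Taylor series
  $1 - \theta/3 + \theta^2/12$ below $\theta = 10^{-4}$ to avoid the
  catastrophic cancellation in $\theta + e^{-\theta} - 1$; above the
  switch the closed form is used and the two branches agree to ~$10^{-8}$
  at the joint.
* All survival averaging runs in log space with a weighted log-sum-exp;
  TRs are formed as $\exp(\ln\overline{SF}_{IB} - \ln\overline{SF}_{EB})$.
  At 25 Gy the uniform-field normal survival reaches $10^{-16}$ and below,
  so naive ratios would be dominated by underflow.
* The EUD equation
  $\beta G(\lambda T + \delta E)E^2 + \alpha E + \ln\overline{SF} = 0$ has
  a strictly increasing left side, so the positive root is unique. It is
  found with `stats::uniroot()` on $[0, E_{hi}]$, doubling $E_{hi}$ from
  30 Gy until the sign changes, at tolerance $10^{-12}$ Gy; the round trip
  through `survival_fraction()` recovers the input survival to $10^{-9}$.
* Degenerate inputs: an all-zero weight vector (profile mass entirely
  outside the grid) is an error; $\overline{SF} = 1$ maps to EUD 0; a
  treatment time of 0 is accepted as the acute limit $G \to 1$.
* Table rendering rounds display values to two decimals but always
  carries full-precision companion columns; tests and comparisons use the
  latter.

## The scenario grid

`run_scenario_grid()` evaluates the full cross-product — 2 beams × 5
prescriptions (8–25 Gy) × 10 profiles × 3 surface fractions × 2 cancer
lines × 3 normal tissues, 1800 scenarios — in a few seconds on one core,
solving each EUD once per (beam, dose, profile shape, cancer line) since
it is exactly independent of $f_0$ and of the normal tissue. Failures are
per-row, recorded in an `error` column. `render_tables()` reshapes the
grid into the standard report layouts (EUD by dose × extent; TR by cell
pairing; TR by surface fraction; TR by extent; profile-comparison curves).
"Average" TR columns are arithmetic means over the listed cell pairings,
matching how the reference tables are constructed.

## Uncertainty budget

The EUD/TR results carry type-B uncertainty combined in quadrature from
uncorrelated components: density calculation (~3%), shell volumes (~3%),
applicator dosimetry (~10%), scatter correction (~7%), and ~20% each for
$\alpha$ and $\beta$ — a total of about 31% (`uncertainty_budget()`).

## Known limitations

* Spherical symmetry throughout; no applicator anisotropy, no multifocal
  (gap-containing) lesions, no tissue heterogeneity beyond the three
  normal-tissue classes.
* The averaging of survival assumes independent clonogens; this is more
  defensible for interspersed cancer cells than for organized normal
  tissue, so TR should be read as a relative sparing index, not an NTCP.
* No cell-cycle effects, reoxygenation or repopulation; no alternative
  high-dose formalisms (USC, LQ-L).
* The uniform-dose comparator uses the same delivery time and MLQ form as
  the applicator treatment; it is an idealization, not a model of any
  specific electron-beam device.
* As discussed above, everything downstream of the first few millimetres
  of the reconstructed dose curve is only as good as the anchors that
  constrain it; high-dose small-extent TRs are order-of-magnitude
  indicators.
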