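# iortbio

Radiobiological modelling of intraoperative radiotherapy (IORT) delivered
from a low-kV x-ray source inside a spherical applicator placed in the
lumpectomy cavity, compared against a hypothetical uniform-dose
intraoperative treatment of the same target volume.

The package is aimed at medical physicists and radiobiology modellers who
want to ask: *given how rapidly the applicator dose falls off, and given an
assumed residual cancer-cell infiltration profile in the tumour bed, what
uniform dose is the treatment actually equivalent to, and how much normal
tissue does the falling dose spare?*

## The model

**Dose field.** For a spherical applicator of radius $r_0$ (2 cm for the
4-cm applicator), the normalized depth-dose curve is reconstructed from
printed anchor points (surface fraction 1, 0.35 at 1 cm, 0.10 at 2 cm) with
an inverse-square-times-attenuation model, solved exactly from the anchors:

$$f(x) = \left(\frac{r_0}{r_0+x}\right)^2 e^{-a x - b x^2},
\qquad D(x) = D_{\mathrm{Rx}} \, f(x),$$

where $x$ is depth from the applicator surface. The 40 kV beam shares this
shape but delivers dose at 1/1.87 the 50 kV surface rate (0.9 h vs 0.5 h
per treatment).

**Cell survival.** Survival after a single protracted dose follows the
modified linear-quadratic (MLQ) model with the dose-protraction factor
$G(\theta) = 2(\theta + e^{-\theta} - 1)/\theta^2$:

$$SF(x) = \exp\!\big(-\alpha D(x) - \beta\, G(\lambda T + \delta D(x))\, D(x)^2\big),$$

which softens the classical LQ prediction at high single doses. Parameters
for two breast-cancer lines (C1: $\alpha/\beta = 10$ Gy; C2: 3.85 Gy) and
three normal tissues ($\alpha/\beta = 3.1$ Gy, $SF(2\,\mathrm{Gy})$ of
0.3/0.5/0.7) ship with the package, all with $\delta = 0.15$ Gy$^{-1}$ and
$\lambda = 0.693$ h$^{-1}$ (1 h repair half-life).

**EUD and therapeutic ratio.** Residual cancer cells are distributed in
depth by a half-Gaussian (truncated at $3\sigma$) or linear profile with
surface fraction $f_0$. Survival is averaged over concentric 0.5-mm
spherical shells with weights $V_i f_c(x_i)$,

$$\overline{SF} = \frac{\sum_i SF(x_i)\, V(x_i)\, f_c(x_i)}
                       {\sum_i V(x_i)\, f_c(x_i)},$$

and the equivalent uniform dose (EUD) is the unique root of
$\beta G(\lambda T + \delta E)E^2 + \alpha E + \ln\overline{SF} = 0$. The
therapeutic ratio compares normal-tissue survival (weights $V_i(1-f_c)$)
between the applicator field and the EUD-matched uniform field:

$$TR = \overline{SF}_{\mathrm{normal}}(\mathrm{IB}) \,/\,
       \overline{SF}_{\mathrm{normal}}(\mathrm{EUD});$$

$TR > 1$ means the applicator treatment spares more normal tissue at equal
cancer-cell kill. All averages are formed in log space, so TRs of order
$10^3$ near the survival underflow limit are computed stably.

## Worked example

```r
library(iortbio)

model <- fit_radial_dose(ib_anchors_50kv())
model
#> Radial dose model: f(x) = (r0/(r0+x))^2 exp(-a x - b x^2)
#>   r0 = 2 cm, a = 0.0196385 /cm, b = 0.219253 /cm^2
#>   fit to 3 anchors; f(2.5 cm) = 0.0478

sc <- scenario_spec(beam_spec("50kV"), prescription = 20,
                    cancer = cell_params("C1"), normal = cell_params("N1"),
                    profile = density_profile("half_gaussian", extent_mm = 6,
                                              f0 = 1e-4),
                    dose_model = model)
therapeutic_ratio(sc, details = TRUE)
#>   sf_cancer_avg   eud sf_normal_ib sf_normal_eb    tr
#> 1     0.0002867 15.49    7.558e-07    3.471e-09 217.7
```

Reading: a 20 Gy surface prescription over a 6-mm half-Gaussian
infiltration kills cancer cells like a uniform 15.5 Gy treatment would
(the EUD), while radiosensitive normal tissue in the infiltrated shell
survives about 218 times better under the falling applicator dose than it
would under that uniform dose.

The full study grid (both beams, 5 prescriptions, 10 profiles, 3 surface
fractions, 6 cell pairings — 1800 scenarios) runs in a few seconds:

```r
res <- run_scenario_grid()
render_tables(res, "table5", dir = "results")   # TR by dose x extent
```

A command-line wrapper for the same sweep is installed at
`inst/scripts/iort-grid.R`. The type-B uncertainty attached to the EUD/TR
results is summarized by `uncertainty_budget()` (total ≈ 31%).

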