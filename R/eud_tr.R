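#' Define one IORT treatment scenario
#'
#' Bundles everything needed to evaluate a single treatment scenario: the
#' beam (delivery time and relative dose rate), the surface prescription,
#' the cancer and normal cell parameter sets, the infiltration profile, the
#' fitted radial dose model and the spherical-shell grid over the
#' infiltrated region `[0, extent]`.
#'
#' @param beam A [beam_spec()].
#' @param prescription Surface prescription dose, Gy.
#' @param cancer,normal [cell_params()] sets for the cancer line and the
#'   interspersed normal tissue.
#' @param profile A [density_profile()].
#' @param dose_model A fitted [fit_radial_dose()] model.
#' @param step_cm Shell thickness for the averaging grid (default 0.5 mm).
#' @return A list of class `iort_scenario`; the grid is built to match the
#'   profile extent.
#' @export
#' @examples
#' sc <- scenario_spec(beam_spec("50kV"), 20, cell_params("C1"), cell_params("N1"),
#'                     density_profile("half_gaussian", 6), fit_radial_dose(ib_anchors_50kv()))
scenario_spec <- function(beam, prescription, cancer, normal, profile,
                          dose_model, step_cm = 0.05) {
  stopifnot(inherits(beam, "beam_spec"), inherits(cancer, "cell_params"),
            inherits(normal, "cell_params"), inherits(profile, "density_profile"),
            inherits(dose_model, "radial_dose_model"))
  if (length(prescription) != 1L || prescription <= 0) {
    stop("`prescription` must be a single positive dose in Gy", call. = FALSE)
  }
  grid <- build_shell_grid(dose_model$r0, profile$extent_cm, step_cm)
  structure(
    list(beam = beam, prescription = prescription, cancer = cancer,
         normal = normal, profile = profile, dose_model = dose_model,
         grid = grid),
    class = "iort_scenario")
}

# Shell-midpoint doses for a scenario, Gy.
shell_doses <- function(spec) {
  dose_at_depth(spec$dose_model, spec$prescription, spec$grid$depth)
}

#' Population- and volume-weighted average survival
#'
#' Weighted mean of MLQ/LQ survival over a set of doses,
#' `sum(w_i SF_i) / sum(w_i)`, evaluated with a weighted log-sum-exp so the
#' result stays accurate when individual survival fractions underflow.
#'
#' This is the averaging primitive behind [average_sf_cancer()] and
#' [average_sf_normal()]; exposing it keeps hand-built toy configurations
#' (explicit doses and weights) on the same code path.
#'
#' @param dose Shell doses, Gy.
#' @param weights Non-negative weights (e.g. shell volume times cell
#'   fraction); at least one must be positive.
#' @param cell A [cell_params()] set.
#' @param T_hours Delivery time, hours.
#' @param model `"MLQ"` or `"LQ"`.
#' @param log If `TRUE` return the natural log of the average.
#' @return Average survival fraction (or its log).
#' @export
average_survival <- function(dose, weights, cell, T_hours,
                             model = c("MLQ", "LQ"), log = FALSE) {
  if (length(dose) != length(weights)) {
    stop("`dose` and `weights` must have the same length", call. = FALSE)
  }
  if (any(weights < 0)) stop("`weights` must be >= 0", call. = FALSE)
  keep <- weights > 0
  if (!any(keep)) {
    stop("all weights are zero: degenerate profile/grid combination", call. = FALSE)
  }
  ls <- log_survival_fraction(dose[keep], cell, T_hours, model)
  lw <- log(weights[keep])
  m <- max(lw + ls)
  lavg <- m + log(sum(exp(lw + ls - m))) - log(sum(weights[keep]))
  if (log) lavg else exp(lavg)
}

#' Average cancer-cell survival over the infiltrated volume
#'
#' Volume- and density-weighted mean of the MLQ survival at the shell
#' midpoints, with weights `V_i * f_c(x_i)`. The surface fraction `f0`
#' cancels exactly in the weight ratio, so the average (and hence the EUD)
#' does not depend on it.
#'
#' @param spec An [scenario_spec()] object.
#' @param log If `TRUE` return the log average.
#' @return Average cancer survival fraction (or its log).
#' @export
average_sf_cancer <- function(spec, log = FALSE) {
  stopifnot(inherits(spec, "iort_scenario"))
  w <- spec$grid$volume * density_fraction(spec$profile, spec$grid$depth)
  average_survival(shell_doses(spec), w, spec$cancer, spec$beam$T_hours,
                   model = "MLQ", log = log)
}

#' Solve the MLQ survival equation for the equivalent uniform dose
#'
#' The equivalent uniform dose (EUD) is the constant dose that, delivered
#' over the same time, reproduces a given average survival:
#' \deqn{\beta\, G(\lambda T + \delta E)\, E^2 + \alpha E + \ln \bar{SF} = 0.}
#' The left side is strictly increasing in `E`, so the positive root is
#' unique; it is found by bracketed root search ([stats::uniroot()] with a
#' doubling bracket expansion) to an absolute tolerance of ~1e-12 Gy.
#'
#' @param sf_avg Average survival fraction; must be in (0, 1]. `sf_avg = 1`
#'   returns 0 Gy.
#' @param cell The [cell_params()] set the average was computed with.
#' @param T_hours Delivery time, hours.
#' @param upper Initial upper bracket in Gy (expanded automatically).
#' @return EUD in Gy. The round trip
#'   `survival_fraction(solve_eud(s, ...), ...)` recovers `s` to ~1e-9.
#' @export
#' @examples
#' s <- survival_fraction(12, cell_params("C1"), 0.5)
#' solve_eud(s, cell_params("C1"), 0.5)  # 12
solve_eud <- function(sf_avg, cell, T_hours, upper = 30) {
  stopifnot(inherits(cell, "cell_params"))
  if (length(sf_avg) != 1L || sf_avg <= 0) {
    stop("`sf_avg` must be a single survival fraction in (0, 1]", call. = FALSE)
  }
  if (sf_avg >= 1) return(0)
  lsf <- log(sf_avg)
  obj <- function(E) {
    cell$alpha * E +
      cell$beta * protraction_factor(cell$lam * T_hours + cell$delta * E) * E^2 +
      lsf
  }
  hi <- upper
  while (obj(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("no sign change found while expanding the EUD bracket",
                       call. = FALSE)
  }
  stats::uniroot(obj, c(0, hi), tol = 1e-12)$root
}

#' Average normal-tissue survival in the IORT or uniform-dose field
#'
#' Eq.-3-style average over the same shell grid with weights
#' `V_i * f_n(x_i)` (`f_n = 1 - f_c`), using the normal tissue's MLQ
#' parameters. Two fields are supported:
#' * `"IB"`: the non-uniform applicator dose `D(x_i)`;
#' * `"EB"`: a uniform dose equal to the EUD, for which the weighted
#'   average collapses to `SF_normal(EUD)` exactly.
#'
#' @param spec An [scenario_spec()] object.
#' @param field `"IB"` or `"EB"`.
#' @param eud EUD in Gy; required for the `"EB"` field (computed via
#'   [solve_eud()] from the cancer average if omitted).
#' @param log If `TRUE` return the log average.
#' @return Average normal-cell survival fraction (or its log).
#' @export
average_sf_normal <- function(spec, field = c("IB", "EB"), eud = NULL,
                              log = FALSE) {
  stopifnot(inherits(spec, "iort_scenario"))
  field <- match.arg(field)
  if (field == "IB") {
    w <- spec$grid$volume * normal_fraction(spec$profile, spec$grid$depth)
    return(average_survival(shell_doses(spec), w, spec$normal,
                            spec$beam$T_hours, model = "MLQ", log = log))
  }
  if (is.null(eud)) {
    eud <- solve_eud(average_sf_cancer(spec), spec$cancer, spec$beam$T_hours)
  }
  ls <- log_survival_fraction(eud, spec$normal, spec$beam$T_hours, "MLQ")
  if (log) ls else exp(ls)
}

#' Therapeutic ratio of applicator-based IORT over uniform-dose IORT
#'
#' The therapeutic ratio compares normal-tissue survival under the real,
#' rapidly falling applicator dose with survival under the uniform
#' equivalent dose that kills cancer cells equally well:
#' \deqn{TR = \frac{\bar{SF}_{normal}(IB)}{\bar{SF}_{normal}(EB = EUD)}.}
#' `TR > 1` means the applicator treatment spares more normal tissue at
#' matched cancer-cell kill. The ratio is formed in log space because the
#' denominator can approach the double underflow limit at high doses.
#'
#' @param spec An [scenario_spec()] object.
#' @param details If `TRUE`, return a one-row data frame with the average
#'   cancer survival, EUD, both normal-tissue averages and the TR.
#' @return The TR (dimensionless), or the detail data frame.
#' @export
therapeutic_ratio <- function(spec, details = FALSE) {
  stopifnot(inherits(spec, "iort_scenario"))
  sfc <- average_sf_cancer(spec)
  eud <- solve_eud(sfc, spec$cancer, spec$beam$T_hours)
  l_ib <- average_sf_normal(spec, "IB", log = TRUE)
  l_eb <- average_sf_normal(spec, "EB", eud = eud, log = TRUE)
  tr <- exp(l_ib - l_eb)
  if (!details) return(tr)
  data.frame(sf_cancer_avg = sfc, eud = eud,
             sf_normal_ib = exp(l_ib), sf_normal_eb = exp(l_eb), tr = tr)
}

#' Default study-grid configuration
#'
#' The full cross-product evaluated in the study: both beam energies,
#' prescriptions 8-25 Gy, half-Gaussian and linear infiltration profiles at
#' five extents, three surface density fractions, both cancer lines and all
#' three normal tissues, on 0.5-mm shells with the anchor-fitted 50 kV dose
#' shape (the 40 kV depth-dose shape is taken identical; only delivery time
#' and dose rate differ).
#'
#' @param anchors Anchor table for the dose-model fit.
#' @param r0 Applicator radius, cm.
#' @return A named list understood by [run_scenario_grid()].
#' @export
paper_grid_config <- function(anchors = ib_anchors_50kv(), r0 = 2) {
  list(
    beams = c("50kV", "40kV"),
    prescriptions = c(8, 10, 15, 20, 25),
    kinds = c("half_gaussian", "linear"),
    extents_mm = c(1.5, 3, 6, 9, 15),
    surface_fractions = c(1e-4, 1e-2, 0.1),
    cancer = c("C1", "C2"),
    normal = c("N1", "N2", "N3"),
    step_cm = 0.05,
    anchors = anchors,
    r0 = r0
  )
}

#' Run the full scenario grid
#'
#' Evaluates every combination of beam, prescription, infiltration profile,
#' surface fraction and cancer/normal pairing in the configuration,
#' returning one row per scenario with the average cancer survival, EUD,
#' normal-tissue averages and TR. The EUD is solved once per
#' (beam, prescription, profile shape, cancer line) — it is exactly
#' invariant to the surface fraction and does not involve the normal
#' tissue. Per-scenario failures are recorded in the `error` column rather
#' than aborting the grid.
#'
#' @param config A configuration list as returned by [paper_grid_config()].
#' @param dose_model Optional pre-fitted [fit_radial_dose()] model
#'   (otherwise fitted from `config$anchors`).
#' @return A data frame with columns `beam`, `prescription`, `kind`,
#'   `extent_mm`, `f0`, `cancer`, `normal`, `sf_cancer_avg`, `eud`,
#'   `sf_normal_ib`, `sf_normal_eb`, `tr`, `error`.
#' @export
run_scenario_grid <- function(config = paper_grid_config(), dose_model = NULL) {
  if (is.null(dose_model)) {
    dose_model <- fit_radial_dose(config$anchors, r0 = config$r0)
  }
  cells <- lapply(stats::setNames(nm = unique(c(config$cancer, config$normal))),
                  cell_params)
  combos <- expand.grid(
    normal = config$normal, f0 = config$surface_fractions,
    cancer = config$cancer, extent_mm = config$extents_mm,
    kind = config$kinds, prescription = config$prescriptions,
    beam = config$beams,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  eud_cache <- new.env(parent = emptyenv())
  n <- nrow(combos)
  out <- cbind(combos,
               data.frame(sf_cancer_avg = rep(NA_real_, n), eud = NA_real_,
                          sf_normal_ib = NA_real_, sf_normal_eb = NA_real_,
                          tr = NA_real_, error = NA_character_))
  for (i in seq_len(n)) {
    row <- combos[i, ]
    res <- tryCatch({
      beam <- beam_spec(row$beam)
      profile <- density_profile(row$kind, row$extent_mm, row$f0)
      spec <- scenario_spec(beam, row$prescription, cells[[row$cancer]],
                            cells[[row$normal]], profile, dose_model,
                            step_cm = config$step_cm)
      sfc <- average_sf_cancer(spec)
      key <- paste(row$beam, row$prescription, row$kind, row$extent_mm,
                   row$cancer, sep = "|")
      if (is.null(eud_cache[[key]])) {
        eud_cache[[key]] <- solve_eud(sfc, spec$cancer, beam$T_hours)
      }
      eud <- eud_cache[[key]]
      l_ib <- average_sf_normal(spec, "IB", log = TRUE)
      l_eb <- average_sf_normal(spec, "EB", eud = eud, log = TRUE)
      list(sfc = sfc, eud = eud, ib = exp(l_ib), eb = exp(l_eb),
           tr = exp(l_ib - l_eb))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$sf_cancer_avg[i] <- res$sfc
      out$eud[i] <- res$eud
      out$sf_normal_ib[i] <- res$ib
      out$sf_normal_eb[i] <- res$eb
      out$tr[i] <- res$tr
    }
  }
  out[, c("beam", "prescription", "kind", "extent_mm", "f0", "cancer",
          "normal", "sf_cancer_avg", "eud", "sf_normal_ib", "sf_normal_eb",
          "tr", "error")]
}
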