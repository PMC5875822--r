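#' Printed dose anchor points for the 50 kV beam with the 4-cm applicator
#'
#' Commissioning-style anchor points for the Intrabeam 50 kV beam and the
#' 4-cm spherical applicator: a surface prescription of 20 Gy falls to 7 Gy
#' at 1 cm depth and 2 Gy at 2 cm depth. Expressed as fractions of the
#' surface dose so they are prescription-independent.
#'
#' @return A data frame with columns `depth` (cm from the applicator
#'   surface) and `frac` (fraction of the surface dose).
#' @seealso [fit_radial_dose()]
#' @export
#' @examples
#' ib_anchors_50kv()
ib_anchors_50kv <- function() {
  data.frame(depth = c(0, 1, 2), frac = c(1, 7 / 20, 2 / 20))
}

#' Fit a radial dose model to anchor points
#'
#' Reconstructs the normalized depth-dose curve `f(x)` of a spherical-
#' applicator kV source from a small set of anchor points. The parametric
#' form is inverse square from the source at the sphere centre times a
#' two-parameter attenuation term,
#' \deqn{f(x) = \left(\frac{r_0}{r_0 + x}\right)^2 e^{-a x - b x^2},}
#' where `x` is depth from the applicator surface (cm) and `r0` the
#' applicator radius (cm). With exactly two non-surface anchors the
#' attenuation coefficients `(a, b)` are solved exactly from the 2x2
#' log-linear system, so the model interpolates every anchor; with more
#' anchors a least-squares fit is used.
#'
#' A single-exponential attenuation (`b = 0`) cannot pass through both
#' printed anchors of the 50 kV beam, which is why the quadratic term in
#' the exponent is required.
#'
#' @param anchors Data frame with columns `depth` (cm, one row must be
#'   depth 0) and `frac` (fraction of surface dose) or `dose` (absolute
#'   dose, normalized internally by the surface value). Doses must be
#'   strictly decreasing with depth.
#' @param r0 Applicator radius in cm (2.0 for the 4-cm applicator).
#' @param check_depth,check_max Clinical falloff constraint: the fitted
#'   `f(check_depth)` must be below `check_max` (default: below 10\% of the
#'   prescription at 2.5 cm). A fit violating it is rejected.
#' @return An object of class `radial_dose_model` with elements `r0`, `a`,
#'   `b` (attenuation coefficients, 1/cm and 1/cm^2) and the anchors used.
#' @export
#' @examples
#' m <- fit_radial_dose(ib_anchors_50kv())
#' normalized_dose(m, c(0, 1, 2, 2.5))
fit_radial_dose <- function(anchors, r0 = 2,
                            check_depth = 2.5, check_max = 0.10) {
  anchors <- as.data.frame(anchors)
  if (!"frac" %in% names(anchors)) {
    if (!"dose" %in% names(anchors)) {
      stop("`anchors` needs a `frac` or `dose` column", call. = FALSE)
    }
    surf <- anchors$dose[anchors$depth == 0]
    if (length(surf) != 1L || surf <= 0) {
      stop("`anchors` must contain exactly one positive surface (depth 0) dose",
           call. = FALSE)
    }
    anchors$frac <- anchors$dose / surf
  }
  anchors <- anchors[order(anchors$depth), c("depth", "frac")]
  if (nrow(anchors) < 3L) {
    stop("at least 3 anchors (including depth 0) are required", call. = FALSE)
  }
  if (anchors$depth[1L] != 0) {
    stop("anchors must include the applicator surface (depth 0)", call. = FALSE)
  }
  if (any(anchors$depth < 0) || any(anchors$frac <= 0)) {
    stop("anchor depths must be >= 0 and doses > 0", call. = FALSE)
  }
  if (any(diff(anchors$frac) >= 0)) {
    stop("anchor doses must be strictly decreasing with depth", call. = FALSE)
  }
  if (r0 <= 0) stop("`r0` must be positive", call. = FALSE)

  x <- anchors$depth[-1L]
  # attenuation left after removing the inverse-square component
  y <- log(anchors$frac[-1L]) - 2 * log(r0 / (r0 + x))
  X <- cbind(-x, -x^2)
  coef <- qr.solve(X, y)

  model <- structure(
    list(r0 = r0, a = coef[[1L]], b = coef[[2L]], anchors = anchors),
    class = "radial_dose_model"
  )
  fchk <- normalized_dose(model, check_depth)
  if (fchk >= check_max) {
    stop(sprintf(
      "fitted dose fraction %.4f at depth %.2f cm violates the f(%.2f) < %.2f falloff constraint",
      fchk, check_depth, check_depth, check_max), call. = FALSE)
  }
  model
}

#' Evaluate the normalized depth-dose function
#'
#' @param model A `radial_dose_model`.
#' @param depth Depth(s) from the applicator surface in cm; must be >= 0.
#' @return Fraction(s) of the surface dose, with `f(0) = 1`.
#' @export
normalized_dose <- function(model, depth) {
  stopifnot(inherits(model, "radial_dose_model"))
  if (any(depth < 0)) stop("`depth` must be >= 0", call. = FALSE)
  (model$r0 / (model$r0 + depth))^2 * exp(-model$a * depth - model$b * depth^2)
}

#' Absolute dose at depth for a given surface prescription
#'
#' @inheritParams normalized_dose
#' @param prescription Surface prescription dose in Gy (> 0).
#' @return Dose(s) in Gy: `prescription * f(depth)`.
#' @export
#' @examples
#' m <- fit_radial_dose(ib_anchors_50kv())
#' dose_at_depth(m, 20, c(0, 1, 2))  # 20, 7, 2 Gy
dose_at_depth <- function(model, prescription, depth) {
  if (length(prescription) != 1L || prescription <= 0) {
    stop("`prescription` must be a single positive dose in Gy", call. = FALSE)
  }
  prescription * normalized_dose(model, depth)
}

#' Beam specification for the 50 and 40 kV source settings
#'
#' Treatment time and relative surface dose rate for the two Intrabeam
#' beam energies with the 4-cm applicator. The 50 kV beam delivers a given
#' prescription in 0.5 h; the 40 kV beam needs 0.9 h because its surface
#' dose rate is lower by a factor 1.87.
#'
#' @param label `"50kV"` or `"40kV"`.
#' @return A list of class `beam_spec` with `label`, `T_hours` (delivery
#'   time) and `dose_rate_factor` (surface dose rate relative to 50 kV).
#' @export
#' @examples
#' beam_spec("40kV")$T_hours  # 0.9
beam_spec <- function(label = c("50kV", "40kV")) {
  label <- match.arg(label)
  spec <- switch(label,
    "50kV" = list(label = "50kV", T_hours = 0.5, dose_rate_factor = 1),
    "40kV" = list(label = "40kV", T_hours = 0.9, dose_rate_factor = 1 / 1.87)
  )
  structure(spec, class = "beam_spec")
}

#' Surface dose the 40 kV beam delivers in the 50 kV treatment time
#'
#' If a treatment is stopped after the time the 50 kV beam would need for a
#' given prescription, the slower 40 kV beam has only delivered the
#' prescription scaled by its relative dose rate (1/1.87).
#'
#' @param prescription_50kV Prescription dose (Gy) the 50 kV beam would
#'   deliver at the applicator surface; >= 0.
#' @param beam40 A `beam_spec`, by default `beam_spec("40kV")`.
#' @return Surface dose in Gy delivered by the 40 kV beam.
#' @export
#' @examples
#' forty_kv_delivery(20)  # ~10.70 Gy
forty_kv_delivery <- function(prescription_50kV, beam40 = beam_spec("40kV")) {
  stopifnot(inherits(beam40, "beam_spec"))
  if (any(prescription_50kV < 0)) stop("`prescription_50kV` must be >= 0", call. = FALSE)
  prescription_50kV * beam40$dose_rate_factor
}

#' Perturb a fitted radial dose model for sensitivity analysis
#'
#' Applies a global scale (and optionally seed-reproducible log-normal
#' jitter) to the non-surface anchor doses and refits the model. The
#' surface anchor stays at 1, so `f(0) = 1` is preserved. Used to propagate
#' a dosimetric uncertainty of up to ~10% through downstream EUD and TR
#' results.
#'
#' @param model A `radial_dose_model`.
#' @param scale Multiplicative factor on the non-surface anchor doses,
#'   restricted to `[0.8, 1.2]`.
#' @param jitter_sd Standard deviation of log-normal anchor jitter
#'   (0 disables jitter).
#' @param seed Integer seed making the jitter reproducible; required when
#'   `jitter_sd > 0`. The caller's RNG state is left untouched.
#' @return A refitted `radial_dose_model`.
#' @export
perturb_dose_model <- function(model, scale = 1, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "radial_dose_model"))
  if (length(scale) != 1L || scale < 0.8 || scale > 1.2) {
    stop("`scale` must lie in [0.8, 1.2]", call. = FALSE)
  }
  anchors <- model$anchors
  idx <- anchors$depth > 0
  mult <- rep(scale, sum(idx))
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when `jitter_sd` > 0", call. = FALSE)
    mult <- mult * exp(local_rnorm(seed, sum(idx), sd = jitter_sd))
  }
  anchors$frac[idx] <- anchors$frac[idx] * mult
  fit_radial_dose(anchors, r0 = model$r0)
}

# Draw normal deviates under a private RNG state so callers' streams are
# unaffected.
local_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' @export
print.radial_dose_model <- function(x, ...) {
  cat(sprintf(
    "Radial dose model: f(x) = (r0/(r0+x))^2 exp(-a x - b x^2)\n  r0 = %.3g cm, a = %.6g /cm, b = %.6g /cm^2\n",
    x$r0, x$a, x$b))
  cat(sprintf("  fit to %d anchors; f(2.5 cm) = %.4f\n",
              nrow(x$anchors), normalized_dose(x, 2.5)))
  invisible(x)
}

#' @export
#' @importFrom graphics lines points legend
plot.radial_dose_model <- function(x, xmax = 3, ...) {
  d <- seq(0, xmax, length.out = 301)
  plot(d, normalized_dose(x, d), type = "l", xlab = "depth from applicator surface (cm)",
       ylab = "fraction of surface dose", ...)
  points(x$anchors$depth, x$anchors$frac, pch = 19)
  invisible(x)
}

#' Export fitted dose-model parameters to JSON
#'
#' Writes the applicator radius, attenuation coefficients and anchors of a
#' fitted model as a provenance record.
#'
#' @param model A `radial_dose_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_model <- function(model, path) {
  stopifnot(inherits(model, "radial_dose_model"))
  jsonlite::write_json(
    list(r0 = model$r0, a = model$a, b = model$b, anchors = model$anchors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read dose-model parameters exported by [write_dose_model()]
#'
#' @param path JSON file written by [write_dose_model()].
#' @return A `radial_dose_model`.
#' @export
read_dose_model <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(r0 = spec$r0, a = spec$a, b = spec$b,
                 anchors = as.data.frame(spec$anchors)),
            class = "radial_dose_model")
}
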