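#' MLQ radiosensitivity parameters for the modelled cell lines
#'
#' Loads the packaged parameter table for the five modelled cell types: two
#' breast cancer lines (C1, acutely responding, alpha/beta = 10 Gy; C2,
#' slowly responding, alpha/beta = 3.85 Gy) and three normal tissues (N1
#' radiosensitive, N2 moderately radiosensitive, N3 radioresistant, all
#' with alpha/beta = 3.1 Gy). All lines share the protraction coefficient
#' `delta` = 0.15 /Gy and repair rate `lam` = 0.693 /h (a 1-hour repair
#' half-life).
#'
#' @param path Optional path to an alternative parameter CSV with the same
#'   columns.
#' @return A data frame with columns `label`, `role`, `alpha` (1/Gy),
#'   `beta` (1/Gy^2), `delta` (1/Gy), `lam` (1/h), `alpha_beta` (Gy).
#' @export
#' @examples
#' cell_lines()
cell_lines <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mlq_parameters.csv", package = "iortbio",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "alpha", "beta", "delta", "lam", "alpha_beta")
  if (!all(req %in% names(tab))) {
    stop("parameter table must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Construct or look up an MLQ parameter set
#'
#' Either looks a line up by label in the packaged table ([cell_lines()])
#' or builds a custom parameter set from explicit values.
#'
#' @param label Cell line label (`"C1"`, `"C2"`, `"N1"`, `"N2"`, `"N3"`,
#'   or any label when explicit parameters are given).
#' @param alpha,beta Linear (1/Gy) and quadratic (1/Gy^2) LQ coefficients.
#' @param delta Dose-protraction coefficient (1/Gy).
#' @param lam Sublethal-damage repair rate (1/h).
#' @return A list of class `cell_params` with fields `label`, `alpha`,
#'   `beta`, `delta`, `lam`, `alpha_beta`.
#' @export
#' @examples
#' cell_params("C1")
#' cell_params("custom", alpha = 0.25, beta = 0.04)
cell_params <- function(label, alpha = NULL, beta = NULL,
                        delta = 0.15, lam = 0.693) {
  if (is.null(alpha) || is.null(beta)) {
    tab <- cell_lines()
    row <- tab[tab$label == label, ]
    if (nrow(row) != 1L) {
      stop(sprintf("unknown cell line '%s'; give `alpha` and `beta` explicitly",
                   label), call. = FALSE)
    }
    alpha <- row$alpha; beta <- row$beta; delta <- row$delta; lam <- row$lam
  }
  if (alpha <= 0 || beta <= 0 || delta <= 0 || lam <= 0) {
    stop("`alpha`, `beta`, `delta` and `lam` must all be positive", call. = FALSE)
  }
  structure(list(label = label, alpha = alpha, beta = beta, delta = delta,
                 lam = lam, alpha_beta = alpha / beta),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "MLQ parameters '%s': alpha = %.3g /Gy, beta = %.3g /Gy^2 (alpha/beta = %.3g Gy), delta = %.3g /Gy, lambda = %.3g /h\n",
    x$label, x$alpha, x$beta, x$alpha_beta, x$delta, x$lam))
  invisible(x)
}

#' Residual cancer-cell infiltration profile
#'
#' Density of residual cancer cells (as a fraction of all cells) versus
#' depth from the excision surface. Two shapes are supported:
#' * `half_gaussian`: `f0 * exp(-x^2 / (2 sigma^2))`, truncated to 0 beyond
#'   the infiltration extent 3*sigma;
#' * `linear`: `f0 * (1 - x / extent)`, 0 beyond the extent.
#'
#' @param kind `"half_gaussian"` or `"linear"`.
#' @param extent_mm Infiltration extent in mm (for the half-Gaussian this
#'   is 3 standard deviations, so `sigma = extent_mm / 3`).
#' @param f0 Cancer-cell fraction at the excision surface, in (0, 1].
#' @return A list of class `density_profile` with `kind`, `extent_cm`,
#'   `sigma_cm` (`NA` for linear) and `f0`.
#' @export
#' @examples
#' density_profile("half_gaussian", extent_mm = 6, f0 = 1e-4)
density_profile <- function(kind = c("half_gaussian", "linear"),
                            extent_mm, f0 = 1e-4) {
  kind <- match.arg(kind)
  if (length(extent_mm) != 1L || extent_mm <= 0) {
    stop("`extent_mm` must be a single positive length in mm", call. = FALSE)
  }
  if (length(f0) != 1L || f0 <= 0 || f0 > 1) {
    stop("`f0` must lie in (0, 1]", call. = FALSE)
  }
  extent_cm <- extent_mm / 10
  structure(
    list(kind = kind, extent_cm = extent_cm,
         sigma_cm = if (kind == "half_gaussian") extent_cm / 3 else NA_real_,
         f0 = f0),
    class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  lbl <- if (x$kind == "half_gaussian") {
    sprintf("half-Gaussian (sigma = %.2g mm, cutoff 3 sigma)", x$sigma_cm * 10)
  } else "linear"
  cat(sprintf("Cancer-cell density profile: %s, extent %.2g mm, surface fraction %.3g\n",
              lbl, x$extent_cm * 10, x$f0))
  invisible(x)
}

#' Cancer-cell density fraction at depth
#'
#' @param profile A [density_profile()].
#' @param depth_cm Depth(s) from the excision surface, cm; >= 0.
#' @return Cancer-cell fraction(s), 0 beyond the infiltration extent.
#' @export
density_fraction <- function(profile, depth_cm) {
  stopifnot(inherits(profile, "density_profile"))
  if (any(depth_cm < 0)) stop("`depth_cm` must be >= 0", call. = FALSE)
  out <- switch(profile$kind,
    half_gaussian = profile$f0 * exp(-depth_cm^2 / (2 * profile$sigma_cm^2)),
    linear = profile$f0 * (1 - depth_cm / profile$extent_cm)
  )
  out[depth_cm > profile$extent_cm] <- 0
  pmax(out, 0)
}

#' Normal-cell fraction at depth
#'
#' The complement of the cancer-cell fraction, `1 - f_c(x)`.
#'
#' @inheritParams density_fraction
#' @return Normal-cell fraction(s) in \[0, 1\].
#' @export
normal_fraction <- function(profile, depth_cm) {
  1 - density_fraction(profile, depth_cm)
}

#' Concentric spherical-shell discretization of the infiltrated region
#'
#' Divides the region from the applicator surface to the infiltration
#' extent into concentric spherical shells of equal radial thickness
#' (default 0.5 mm). Shell volumes are exact:
#' `V_i = (4 pi / 3) ((r0 + x_i + h/2)^3 - (r0 + x_i - h/2)^3)` where `x_i`
#' are shell midpoints and `h` the step. If the extent is not a multiple of
#' the step the last shell is truncated so the shells tile exactly
#' `[0, extent]`.
#'
#' @param r0 Applicator radius, cm.
#' @param extent_cm Infiltration extent, cm.
#' @param step_cm Radial shell thickness, cm (default 0.05 cm = 0.5 mm).
#' @return A list of class `shell_grid` with `r0`, `step_cm`, `extent_cm`,
#'   `depth` (shell midpoints, cm), `volume` (cm^3), and shell count `N`.
#' @export
#' @examples
#' g <- build_shell_grid(2, extent_cm = 0.3)
#' g$N  # 6 shells
build_shell_grid <- function(r0 = 2, extent_cm, step_cm = 0.05) {
  if (extent_cm <= 0 || step_cm <= 0) {
    stop("`extent_cm` and `step_cm` must be positive", call. = FALSE)
  }
  edges <- seq(0, extent_cm, by = step_cm)
  if (utils::tail(edges, 1) < extent_cm) edges <- c(edges, extent_cm)
  r <- r0 + edges
  vol <- (4 * pi / 3) * diff(r^3)
  structure(
    list(r0 = r0, step_cm = step_cm, extent_cm = extent_cm,
         depth = (edges[-1L] + edges[-length(edges)]) / 2,
         volume = vol, N = length(vol)),
    class = "shell_grid")
}

#' @export
print.shell_grid <- function(x, ...) {
  cat(sprintf(
    "Spherical shell grid: r0 = %.3g cm, %d shells of %.3g mm over [0, %.3g] mm, total volume %.4g cm^3\n",
    x$r0, x$N, x$step_cm * 10, x$extent_cm * 10, sum(x$volume)))
  invisible(x)
}
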