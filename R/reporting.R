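#' Combine independent relative uncertainties in quadrature
#'
#' Root-sum-square combination of uncorrelated relative uncertainty
#' components, each expressed as a percentage.
#'
#' @param components Numeric vector of positive percentages.
#' @return Total relative uncertainty, percent.
#' @export
#' @examples
#' combine_uncertainties(c(3, 4))  # 5
combine_uncertainties <- function(components) {
  if (length(components) == 0L) {
    stop("`components` must be a non-empty vector of percentages", call. = FALSE)
  }
  if (!is.numeric(components) || any(components <= 0)) {
    stop("all uncertainty components must be positive percentages", call. = FALSE)
  }
  sqrt(sum(components^2))
}

#' Type-B uncertainty budget for the EUD and TR results
#'
#' The default budget combines, in quadrature: cancer-cell density
#' calculation (~3%), shell volume calculation (~3%), applicator dosimetry
#' (~10%), scatter dosimetric correction (~7%), and the radiosensitivity
#' parameters alpha and beta (~20% each), giving a total of about 31%.
#'
#' @param components Data frame with columns `label` and `percent`.
#' @return A list of class `uncertainty_budget` with the component table
#'   and the quadrature `total` (percent).
#' @export
#' @examples
#' uncertainty_budget()$total
uncertainty_budget <- function(components = NULL) {
  if (is.null(components)) {
    components <- data.frame(
      label = c("cancer-cell density calculation", "shell volume calculation",
                "applicator dosimetry", "scatter dosimetric correction",
                "radiosensitivity alpha", "radiosensitivity beta"),
      percent = c(3, 3, 10, 7, 20, 20))
  }
  structure(list(components = components,
                 total = combine_uncertainties(components$percent)),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncorrelated relative uncertainty budget:\n")
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %-38s %5.1f%%\n",
                x$components$label[i], x$components$percent[i]))
  }
  cat(sprintf("  %-38s %5.1f%%\n", "total (quadrature)", x$total))
  invisible(x)
}

# Long -> wide pivot keyed on one row column; values rounded plus
# full-precision companions.
pivot_rounded <- function(df, row, col, value, digits = 2) {
  rows <- sort(unique(df[[row]]))
  cols <- unique(df[[col]])
  out <- data.frame(rows)
  names(out) <- row
  for (cl in cols) {
    v <- vapply(rows, function(r) {
      sel <- df[[row]] == r & df[[col]] == cl
      if (sum(sel) != 1L) NA_real_ else df[[value]][sel]
    }, numeric(1))
    out[[as.character(cl)]] <- round(v, digits)
    out[[paste0(cl, "_full")]] <- v
  }
  out
}

# Filter helper that reports which scenarios are missing from a slice.
slice_or_stop <- function(results, which, ...) {
  sel <- rep(TRUE, nrow(results))
  flt <- list(...)
  for (nm in names(flt)) sel <- sel & results[[nm]] %in% flt[[nm]]
  out <- results[sel & is.na(results$error), , drop = FALSE]
  if (nrow(out) == 0L) {
    stop(sprintf("no completed scenarios available for %s (filters: %s)",
                 which, paste(names(flt), unlist(lapply(flt, paste, collapse = "/")),
                              sep = "=", collapse = ", ")), call. = FALSE)
  }
  out
}

#' Render paper-style result tables and figure data
#'
#' Reshapes a [run_scenario_grid()] result into the canonical table
#' layouts and writes them as CSV. Displayed values are rounded to two
#' decimals with full-precision companion columns (suffix `_full`);
#' comparisons should always use the full-precision values.
#'
#' * `table2`: EUD by prescription x (half-Gaussian extent x cancer line).
#' * `table3`: TR by prescription for every cancer/normal pairing at the
#'   6-mm half-Gaussian profile and 0.01% surface fraction, with per-cancer
#'   and grand averages.
#' * `table4`: averaged TR (over the three normal tissues) by prescription
#'   x (cancer line x surface fraction) at the 3-mm half-Gaussian profile.
#' * `table5`: grand-averaged TR by prescription x half-Gaussian extent at
#'   0.01% surface fraction.
#' * `fig4` / `fig5`: long-format EUD / averaged-TR curves comparing the
#'   half-Gaussian and linear profiles.
#'
#' @param results Data frame from [run_scenario_grid()].
#' @param which One of `"table2"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"fig4"`, `"fig5"`.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param beam Beam label the slice is taken for.
#' @return The rendered data frame, invisibly if written to `dir`.
#' @export
render_tables <- function(results, which = c("table2", "table3", "table4",
                                             "table5", "fig4", "fig5"),
                          dir = NULL, beam = "50kV") {
  which <- match.arg(which)
  f0min <- suppressWarnings(min(results$f0))

  tab <- switch(which,
    table2 = {
      sl <- slice_or_stop(results, which, beam = beam, kind = "half_gaussian",
                          f0 = f0min, normal = results$normal[1])
      sl$column <- sprintf("G_%.1fmm_%s", sl$extent_mm, sl$cancer)
      pivot_rounded(sl, "prescription", "column", "eud")
    },
    table3 = {
      sl <- slice_or_stop(results, which, beam = beam, kind = "half_gaussian",
                          extent_mm = 6, f0 = f0min)
      sl$column <- paste0(sl$cancer, sl$normal)
      wide <- pivot_rounded(sl, "prescription", "column", "tr")
      for (cc in unique(sl$cancer)) {
        full <- wide[, paste0(cc, unique(sl$normal), "_full"), drop = FALSE]
        wide[[paste0(cc, "_avg_full")]] <- rowMeans(full)
        wide[[paste0(cc, "_avg")]] <- round(rowMeans(full), 2)
      }
      allfull <- wide[, paste0(unique(sl$cancer), "_avg_full"), drop = FALSE]
      wide$average_full <- rowMeans(allfull)
      wide$average <- round(wide$average_full, 2)
      wide
    },
    table4 = {
      sl <- slice_or_stop(results, which, beam = beam, kind = "half_gaussian",
                          extent_mm = 3)
      agg <- stats::aggregate(tr ~ prescription + cancer + f0, data = sl, FUN = mean)
      agg$column <- sprintf("%s_f0_%g", agg$cancer, agg$f0)
      pivot_rounded(agg, "prescription", "column", "tr")
    },
    table5 = {
      sl <- slice_or_stop(results, which, beam = beam, kind = "half_gaussian",
                          f0 = f0min)
      agg <- stats::aggregate(tr ~ prescription + extent_mm, data = sl, FUN = mean)
      agg$column <- sprintf("G_%.1fmm", agg$extent_mm)
      pivot_rounded(agg, "prescription", "column", "tr")
    },
    fig4 = {
      sl <- slice_or_stop(results, which, beam = beam, f0 = f0min,
                          normal = results$normal[1])
      sl[order(sl$kind, sl$extent_mm, sl$cancer, sl$prescription),
         c("beam", "kind", "extent_mm", "cancer", "prescription", "eud")]
    },
    fig5 = {
      sl <- slice_or_stop(results, which, beam = beam, f0 = f0min)
      agg <- stats::aggregate(tr ~ beam + kind + extent_mm + prescription,
                              data = sl, FUN = mean)
      names(agg)[names(agg) == "tr"] <- "tr_avg"
      agg[order(agg$kind, agg$extent_mm, agg$prescription), ]
    })

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(tab, file.path(dir, paste0(which, ".csv")),
                     row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Write reproducible test fixtures
#'
#' Emits small plain-text fixtures used by the test-suite and by external
#' checks: the MLQ parameter table, the 50 kV anchor points, a three-shell
#' worked example whose expected values are computed by explicit term-by-
#' term arithmetic (not by the pipeline), and a jittered dose-model
#' variant for sensitivity tests. Byte-identical output for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the jittered dose model.
#' @return Character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  p <- file.path(dir, "mlq_parameters.csv")
  utils::write.csv(cell_lines(), p, row.names = FALSE)
  files <- c(files, p)

  p <- file.path(dir, "anchors_50kv.json")
  jsonlite::write_json(ib_anchors_50kv(), p, digits = NA)
  files <- c(files, p)

  # three-shell worked example: explicit Eq.-style arithmetic, C1 in N1
  grid <- build_shell_grid(2, extent_cm = 0.15, step_cm = 0.05)
  doses <- c(10, 5, 2)
  fc <- c(0.5, 0.25, 0)
  c1 <- cell_params("C1"); n1 <- cell_params("N1"); Th <- 0.5
  sf1 <- exp(-(c1$alpha * doses + c1$beta *
                 protraction_factor(c1$lam * Th + c1$delta * doses) * doses^2))
  w <- grid$volume * fc
  sf_bar <- (sf1[1] * w[1] + sf1[2] * w[2] + sf1[3] * w[3]) / (w[1] + w[2] + w[3])
  eud <- solve_eud(sf_bar, c1, Th)
  sfn <- exp(-(n1$alpha * doses + n1$beta *
                 protraction_factor(n1$lam * Th + n1$delta * doses) * doses^2))
  wn <- grid$volume * (1 - fc)
  sfn_ib <- sum(sfn * wn) / sum(wn)
  sfn_eb <- exp(-(n1$alpha * eud + n1$beta *
                    protraction_factor(n1$lam * Th + n1$delta * eud) * eud^2))
  p <- file.path(dir, "toy_three_shell.json")
  jsonlite::write_json(
    list(r0 = 2, step_cm = 0.05, doses_gy = doses, cancer_fraction = fc,
         shell_volume_cm3 = grid$volume, cancer = "C1", normal = "N1",
         T_hours = Th,
         expected = list(sf_cancer_avg = sf_bar, eud = eud,
                         sf_normal_ib = sfn_ib, sf_normal_eb = sfn_eb,
                         tr = sfn_ib / sfn_eb)),
    p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)

  model <- fit_radial_dose(ib_anchors_50kv())
  pert <- perturb_dose_model(model, scale = 1.05, jitter_sd = 0.03, seed = seed)
  p <- file.path(dir, "dose_model_perturbed.json")
  write_dose_model(pert, p)
  files <- c(files, p)

  files
}
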