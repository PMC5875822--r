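test_that("weighted survival averaging collapses correctly for degenerate inputs", {
  c1 <- cell_params("C1")
  # uniform dose: weights cancel exactly, any profile
  w <- c(2.5, 3.1, 0.4, 9)
  expect_equal(average_survival(rep(14, 4), w, c1, 0.5),
               survival_fraction(14, c1, 0.5), tolerance = 1e-12)
  # single shell equals the survival at that shell's dose
  sc1 <- std_scenario(prescription = 20, extent_mm = 0.5)
  d1 <- dose_at_depth(sc1$dose_model, 20, sc1$grid$depth)
  expect_equal(average_sf_cancer(sc1),
               survival_fraction(d1, cell_params("C1"), 0.5), tolerance = 1e-12)
  # all-zero weights are a degenerate profile
  expect_error(average_survival(c(1, 2), c(0, 0), c1, 0.5), "degenerate")
  expect_error(average_survival(c(1, 2), c(1, -1), c1, 0.5), ">= 0")
  # average lies between the extreme shell survivals
  sc <- std_scenario(prescription = 20, extent_mm = 6)
  sf <- survival_fraction(dose_at_depth(sc$dose_model, 20, sc$grid$depth),
                          cell_params("C1"), 0.5)
  expect_gte(average_sf_cancer(sc), min(sf))
  expect_lte(average_sf_cancer(sc), max(sf))
})

test_that("EUD inversion is a fixed point of the survival equation", {
  for (lbl in c("C1", "C2", "N2")) {
    cell <- cell_params(lbl)
    for (d in c(2, 8, 14, 25)) {
      s <- survival_fraction(d, cell, 0.5)
      expect_equal(solve_eud(s, cell, 0.5), d, tolerance = 1e-6)
    }
  }
  expect_identical(solve_eud(1, cell_params("C1"), 0.5), 0)
  expect_error(solve_eud(0, cell_params("C1"), 0.5), "0, 1")
  expect_error(solve_eud(-0.5, cell_params("C1"), 0.5), "0, 1")
})

test_that("EUD round trip holds to 1e-9 over random survival levels", {
  set.seed(21)
  cells <- list(cell_params("C1"), cell_params("N3"))
  s_draws <- exp(runif(200, log(1e-12), log(0.999)))
  for (s in s_draws) {
    cell <- cells[[sample.int(2, 1)]]
    eud <- solve_eud(s, cell, 0.5)
    expect_equal(survival_fraction(eud, cell, 0.5), s, tolerance = 1e-9)
  }
})

test_that("three-shell hand-arithmetic oracle matches the pipeline to 1e-12", {
  c1 <- cell_params("C1"); n1 <- cell_params("N1"); Th <- 0.5
  grid <- build_shell_grid(2, extent_cm = 0.15, step_cm = 0.05)
  doses <- c(10, 5, 2); fc <- c(0.5, 0.25, 0)

  # explicit term-by-term Eq.-3 arithmetic
  G <- function(th) 2 * (th + exp(-th) - 1) / th^2
  sf <- exp(-(0.3 * doses + 0.03 * G(0.693 * Th + 0.15 * doses) * doses^2))
  w <- grid$volume * fc
  sf_bar_hand <- (sf[1] * w[1] + sf[2] * w[2] + sf[3] * w[3]) /
    (w[1] + w[2] + w[3])
  expect_equal(average_survival(doses, w, c1, Th), sf_bar_hand,
               tolerance = 1e-12)

  # therapeutic ratio by explicit arithmetic on the same toy problem
  eud <- solve_eud(sf_bar_hand, c1, Th)
  sfn <- exp(-(0.366 * doses + 0.118 * G(0.693 * Th + 0.15 * doses) * doses^2))
  wn <- grid$volume * (1 - fc)
  tr_hand <- (sum(sfn * wn) / sum(wn)) /
    exp(-(0.366 * eud + 0.118 * G(0.693 * Th + 0.15 * eud) * eud^2))
  tr_pipe <- average_survival(doses, wn, n1, Th) /
    survival_fraction(eud, n1, Th)
  expect_equal(tr_pipe, tr_hand, tolerance = 1e-12)
})

test_that("the uniform-dose branch equals survival at the EUD and gives TR = 1", {
  sc <- std_scenario(prescription = 15, extent_mm = 6, normal = "N2")
  eud <- solve_eud(average_sf_cancer(sc), sc$cancer, 0.5)
  expect_identical(average_sf_normal(sc, "EB", eud = eud),
                   survival_fraction(eud, cell_params("N2"), 0.5))
  # omitting the EUD recomputes it from the cancer average
  expect_equal(average_sf_normal(sc, "EB"),
               survival_fraction(eud, cell_params("N2"), 0.5),
               tolerance = 1e-9)
  # a uniform field at exactly the EUD spares nothing relative to itself
  n2 <- cell_params("N2")
  w <- sc$grid$volume * normal_fraction(sc$profile, sc$grid$depth)
  tr_uniform <- average_survival(rep(eud, sc$grid$N), w, n2, 0.5) /
    survival_fraction(eud, n2, 0.5)
  expect_equal(tr_uniform, 1, tolerance = 1e-12)
})

test_that("EUD is invariant to the surface density fraction", {
  for (kind in c("half_gaussian", "linear")) {
    euds <- sapply(c(1e-4, 1e-2, 0.1), function(f0) {
      sc <- std_scenario(prescription = 20, extent_mm = 6, kind = kind, f0 = f0)
      solve_eud(average_sf_cancer(sc), sc$cancer, 0.5)
    })
    expect_equal(max(euds) - min(euds), 0, tolerance = 1e-9)
  }
})

test_that("EUD respects the dose bracket and the study monotonicities", {
  m <- ib_model()
  doses <- c(8, 10, 15, 20, 25); extents <- c(1.5, 3, 6, 9, 15)
  eud <- matrix(NA_real_, length(doses), length(extents),
                dimnames = list(doses, extents))
  for (i in seq_along(doses)) {
    for (j in seq_along(extents)) {
      sc <- std_scenario(prescription = doses[i], extent_mm = extents[j],
                         model = m)
      e <- solve_eud(average_sf_cancer(sc), sc$cancer, 0.5)
      eud[i, j] <- e
      expect_lte(e, doses[i])
      # EUD cannot fall below the dose at the deepest infiltrated shell
      expect_gte(e, min(dose_at_depth(m, doses[i], sc$grid$depth)))
    }
  }
  # increasing prescription raises the EUD; deeper infiltration lowers it
  expect_true(all(apply(eud, 2, diff) > 0))
  expect_true(all(apply(eud, 1, diff) < 0))
})

test_that("the two cancer lines give closely agreeing EUDs", {
  # the printed study tables themselves differ by up to ~3% between lines
  for (ext in c(1.5, 6, 15)) {
    for (p in c(8, 20, 25)) {
      e <- sapply(c("C1", "C2"), function(cc) {
        sc <- std_scenario(prescription = p, extent_mm = ext, cancer = cc)
        solve_eud(average_sf_cancer(sc), sc$cancer, 0.5)
      })
      expect_lt(abs(e[["C1"]] / e[["C2"]] - 1), 0.05)
    }
  }
})

test_that("half-Gaussian profiles dominate linear ones in both EUD and TR", {
  for (ext in c(3, 9)) {
    for (p in c(10, 20)) {
      res <- lapply(c("half_gaussian", "linear"), function(k) {
        sc <- std_scenario(prescription = p, extent_mm = ext, kind = k)
        therapeutic_ratio(sc, details = TRUE)
      })
      expect_gte(res[[1]]$eud, res[[2]]$eud - 1e-9)
      expect_gte(res[[1]]$tr, res[[2]]$tr * (1 - 1e-9))
      expect_gte(res[[2]]$tr, 1)  # applicator field always spares normal tissue
    }
  }
})

test_that("scenario grid enumerates the full cross-product and isolates row failures", {
  cfg <- paper_grid_config()
  cfg$beams <- "50kV"
  cfg$prescriptions <- c(10, 20)
  cfg$extents_mm <- c(3, 6)
  cfg$surface_fractions <- c(1e-4, 2)  # second one is invalid on purpose
  res <- run_scenario_grid(cfg)
  expect_equal(nrow(res), 1 * 2 * 2 * 2 * 2 * 2 * 3)
  bad <- res$f0 == 2
  expect_true(all(!is.na(res$error[bad])))
  expect_true(all(is.na(res$error[!bad])))
  expect_true(all(res$tr[!bad] >= 1))
  expect_true(all(res$eud[!bad] <= res$prescription[!bad]))
  # EUD identical across surface fractions and normal tissues within a slice
  ok <- res[!bad, ]
  per <- tapply(ok$eud, interaction(ok$prescription, ok$kind, ok$extent_mm,
                                    ok$cancer), function(v) diff(range(v)))
  expect_true(all(per == 0))
})
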