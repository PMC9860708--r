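test_that("linear trapezoid handles rectangles, degenerate and mixed profiles", {
  expect_equal(auc_linear_trapezoid(c(0, 4), c(5, 5)), 20)
  expect_equal(auc_linear_trapezoid(3, 7), 0)
  expect_equal(auc_linear_trapezoid(c(0, 1, 2), c(0, 10, 5)), 12.5)
  expect_error(auc_linear_trapezoid(c(1, 0), c(1, 2)),
               class = "fmnpk_validation_error")
  expect_error(auc_linear_trapezoid(c(0, 1), c(1, -2)),
               class = "fmnpk_validation_error")
})

test_that("trapezoid AUC converges to quadrature at second order", {
  f <- function(t) 100 * exp(-0.3 * t) - 60 * exp(-1.2 * t)
  exact <- integrate(f, 0, 12, rel.tol = 1e-12)$value
  errs <- vapply(c(25, 50, 100, 200), function(n) {
    tt <- seq(0, 12, length.out = n)
    abs(auc_linear_trapezoid(tt, f(tt)) - exact)
  }, numeric(1))
  order_obs <- log2(errs[-4] / errs[-1])
  expect_true(all(order_obs > 1.8 & order_obs < 2.2))
})

test_that("terminal slope is recovered exactly from log-linear data", {
  tt <- c(2, 4, 8, 12, 24)
  cc <- 100 * exp(-0.1597 * tt)
  lam <- estimate_lambda_z(tt, cc)
  expect_equal(lam$lambda_z, 0.1597, tolerance = 1e-10)
  expect_equal(log(2) / lam$lambda_z, 4.34, tolerance = 1e-2)
  expect_equal(lam$n_points, 4L)  # Tmax point itself is excluded
  expect_equal(lam$r2_adj, 1, tolerance = 1e-10)

  # fewer than 3 usable post-peak points leaves the slope undefined
  und <- estimate_lambda_z(c(1, 2, 4), c(10, 5, 2))
  expect_true(is.na(und$lambda_z))
})

test_that("late terminal samples of a two-exponential decay recover the slow rate", {
  ev <- sort(abs(Re(eigen(fmnpk:::pk_matrix(ref_params))$values)))
  tt <- c(0.5, 24, 30, 36, 48, 60)
  s <- pk_simulate(ref_params, ref_dose, tt)
  lam <- estimate_lambda_z(tt, s$conc_parent)
  expect_equal(lam$lambda_z, ev[1], tolerance = 1e-3)
})

test_that("per-profile NCA satisfies its internal identities", {
  # Vd/F = CL/F * t_half / ln 2, the identity linking the printed per-animal
  # clearance, half-life and volume
  expect_equal(4.60 * 4.34 / 0.693, 28.84, tolerance = 1e-2)

  # monoexponential profile with known clearance: run_nca recovers CL/F
  CL <- 4; V <- 20; D <- 1000
  k <- CL / V
  tt <- exp(seq(log(1e-4), log(60), length.out = 600))
  rows <- dplyr::bind_rows(
    tibble::tibble(ID = "s1", TIME = 0, DVID = 0L, DV = 0, BLQ = 0L,
                   AMT = D, BW = 0.22),
    tibble::tibble(ID = "s1", TIME = tt, DVID = 1L, DV = (D / V) * exp(-k * tt),
                   BLQ = 0L, AMT = 0, BW = 0.22))
  nca <- run_nca(as_pk_dataset(rows, lloq = c(parent = 1e-9, metabolite = 1e-9)))
  expect_equal(nca$CL_F, CL, tolerance = 1e-3)
  expect_equal(nca$Vd_F, V, tolerance = 1e-3)
  expect_equal(nca$lambda_z, k, tolerance = 1e-6)
  expect_true(nca$AUC_inf >= nca$AUC_last)

  # all-BLQ profile: nothing quantifiable
  blq <- tibble::tibble(ID = "s1", TIME = c(0, 1), DVID = c(0L, 1L),
                        DV = c(0, 5), BLQ = c(0L, 1L), AMT = c(100, 0), BW = 0.2)
  expect_error(run_nca(as_pk_dataset(blq)), class = "fmnpk_validation_error")
})

test_that("NCA on dense noise-free simulated profiles matches the closed forms", {
  tt <- exp(seq(log(0.01), log(96), length.out = 1000))
  sim <- pk_simulate(ref_params, ref_dose, tt)
  rows <- dplyr::bind_rows(
    tibble::tibble(ID = "s1", TIME = 0, DVID = 0L, DV = 0, BLQ = 0L,
                   AMT = ref_dose, BW = 0.2217),
    tibble::tibble(ID = "s1", TIME = rep(tt, 2),
                   DVID = rep(c(1L, 2L), each = length(tt)),
                   DV = c(sim$conc_parent, sim$conc_metabolite),
                   BLQ = 0L, AMT = 0, BW = 0.2217))
  nca <- run_nca(as_pk_dataset(rows, lloq = c(parent = 1e-12, metabolite = 1e-12)))
  a <- auc_closed_form(ref_params, ref_dose)
  par_row <- nca[nca$analyte == "parent", ]
  met_row <- nca[nca$analyte == "metabolite", ]
  expect_equal(par_row$AUC_inf, unname(a["parent"]), tolerance = 0.01)
  expect_equal(met_row$AUC_inf, unname(a["metabolite"]), tolerance = 0.01)
  expect_equal(par_row$CL_F, ref_params$CL1 / ref_params$F, tolerance = 0.01)
})

test_that("Cmax ties resolve to the earliest time", {
  tt <- c(0.5, 1, 2, 4, 8)
  cc <- c(3, 10, 10, 5, 1)
  rows <- dplyr::bind_rows(
    tibble::tibble(ID = "s1", TIME = 0, DVID = 0L, DV = 0, BLQ = 0L,
                   AMT = 100, BW = 0.2),
    tibble::tibble(ID = "s1", TIME = tt, DVID = 1L, DV = cc, BLQ = 0L,
                   AMT = 0, BW = 0.2))
  nca <- run_nca(as_pk_dataset(rows, lloq = c(parent = 1e-9, metabolite = 1e-9)))
  expect_equal(nca$Tmax, 1)
  expect_equal(nca$Cmax, 10)
})

test_that("group summaries and fold changes behave", {
  s <- summarize_group(c(10, 10, 10))
  expect_equal(s$sd, 0)
  s1 <- summarize_group(5)
  expect_true(is.na(s1$sd))
  expect_error(summarize_group(numeric(0)), class = "fmnpk_validation_error")

  expect_equal(fold_change(24, 2), 12)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(0, 3), 0)
  expect_error(fold_change(1, 0), class = "fmnpk_validation_error")
})
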