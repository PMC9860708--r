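test_that("pooled -2LL matches closed forms and is permutation invariant", {
  d <- noisefree_dataset(n_subjects = 2)
  n <- nrow(fmnpk:::quantifiable(d))
  # y = f exactly with unit additive sigma: every term reduces to ln(2*pi)
  expect_equal(pk_neg2ll(d, ref_params, add_err(1)), n * log(2 * pi))

  # one observation, y = 2, f = 1, additive sigma = 1
  one <- as_pk_dataset(tibble::tibble(
    ID = "s", TIME = c(0, 1), DVID = c(0L, 1L), DV = c(0, 2),
    BLQ = 0L, AMT = c(100, 0), BW = 0.2), lloq = c(parent = 1e-9, metabolite = 1e-9))
  f1 <- pk_simulate(ref_params, 100, 1)$conc_parent
  expect_equal(pk_neg2ll(one, ref_params, add_err(1)),
               log(2 * pi) + (2 - f1)^2)

  # shuffling rows changes nothing
  study <- simulate_pk_study(n_subjects = 4, error = prop_err(0.2), seed = 11)
  base <- pk_neg2ll(study$data, ref_params, prop_err(0.2))
  set.seed(1)
  shuffled <- as_pk_dataset(study$data[sample(nrow(study$data)), ],
                            lloq = attr(study$data, "lloq"))
  expect_equal(pk_neg2ll(shuffled, ref_params, prop_err(0.2)), base)
})

test_that("proportional and log-additive objectives nearly coincide at moderate CV", {
  study <- simulate_pk_study(n_subjects = 5, error = prop_err(0.2), seed = 21)
  v_prop <- pk_neg2ll(study$data, ref_params, prop_err(0.2))
  v_log <- pk_neg2ll(study$data, ref_params,
                     error_model("log_additive", c(parent = 0.2, metabolite = 0.2)))
  expect_lt(abs(v_prop - v_log) / abs(v_prop), 0.01)
})

test_that("the pooled objective is stationary at truth on noise-free data", {
  d <- noisefree_dataset(n_subjects = 2)
  err <- add_err(0.5)
  obs <- fmnpk:::quantifiable(d)
  doses <- fmnpk:::subject_doses(d)
  free <- c("ka", "V1", "V2", "Vm", "CL1", "CL2", "CLm")
  obj <- function(tr) {
    nat <- unclass(ref_params)
    nat[free] <- exp(tr)
    o <- fmnpk:::predict_obs(obs, doses, do.call(pk_params, nat))
    sum(fmnpk:::neg2ll_contributions(o$DV, o$f, o$analyte, err))
  }
  tr0 <- log(unlist(unclass(ref_params)[free]))
  g <- vapply(seq_along(tr0), function(i) {
    h <- 1e-6
    e <- tr0; e[i] <- e[i] + h
    e2 <- tr0; e2[i] <- e2[i] - h
    (obj(e) - obj(e2)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)), 1e-6)

  fit <- fit_pk_pooled(d, error = err, start = ref_params,
                       fixed = c("F", "Fm", "tlag", "sigma_parent",
                                 "sigma_metabolite"))
  for (nm in free) {
    expect_equal(unname(fit$estimates[nm]), ref_params[[nm]], tolerance = 1e-4)
  }
})

test_that("with all structural parameters fixed, sigma has its analytic optimum", {
  study <- simulate_pk_study(n_subjects = 5, error = prop_err(0.2), seed = 31)
  fit <- fit_pk_pooled(study$data, error = prop_err(0.5), start = ref_params,
                       fixed = c("F", "Fm", "ka", "V1", "V2", "Vm",
                                 "CL1", "CL2", "CLm", "tlag"))
  obs <- predict(fit)
  for (a in c("parent", "metabolite")) {
    r2 <- with(obs[obs$analyte == a, ], ((DV - f) / f)^2)
    expect_equal(unname(fit$estimates[paste0("sigma_", a)]),
                 sqrt(mean(r2)), tolerance = 1e-4)
  }
})

test_that("non-positive predictions under a proportional model are reported", {
  # an observation at t = 0 has a zero prediction (depot-only start)
  d0 <- as_pk_dataset(tibble::tibble(
    ID = "s", TIME = c(0, 0, 1), DVID = c(0L, 1L, 1L), DV = c(0, 3, 5),
    BLQ = 0L, AMT = c(100, 0, 0), BW = 0.2),
    lloq = c(parent = 1e-9, metabolite = 1e-9))
  expect_error(pk_neg2ll(d0, ref_params, prop_err(0.2)),
               class = "fmnpk_numerical_error")
  expect_error(pk_neg2ll(d0, ref_params,
                         error_model("log_additive",
                                     c(parent = 1, metabolite = 1))),
               class = "fmnpk_numerical_error")
  # the additive model tolerates a zero prediction
  expect_true(is.finite(pk_neg2ll(d0, ref_params, add_err(1))))
})

test_that("Laplace objective reduces to the pooled objective at omega = 0", {
  study <- simulate_pk_study(n_subjects = 4, error = prop_err(0.2), seed = 41)
  pooled <- pk_neg2ll(study$data, ref_params, prop_err(0.2))
  lap <- pk_nlme_objective(study$data, ref_params, prop_err(0.2),
                           omega2 = c(V1 = 0, CL1 = 0))
  expect_equal(lap$value, pooled)
  # a variance-zero effect alongside an active one leaves the value intact
  lap1 <- pk_nlme_objective(study$data, ref_params, prop_err(0.2),
                            omega2 = c(V1 = 0.1))
  lap2 <- pk_nlme_objective(study$data, ref_params, prop_err(0.2),
                            omega2 = c(V1 = 0.1, CL1 = 0))
  expect_equal(lap1$value, lap2$value, tolerance = 1e-6)
})

test_that("Laplace marginal likelihood matches a quadrature oracle per subject", {
  study <- simulate_pk_study(n_subjects = 3, error = prop_err(0.2),
                             iiv = c(V1 = 0.18), seed = 51)
  err <- prop_err(0.2)
  om <- 0.18
  lap <- pk_nlme_objective(study$data, ref_params, err, omega2 = c(V1 = om))

  obs_all <- fmnpk:::quantifiable(study$data)
  doses <- fmnpk:::subject_doses(study$data)
  oracle_total <- 0
  for (id in unique(obs_all$ID)) {
    obs_i <- obs_all[obs_all$ID == id, ]
    obs_i$analyte <- c("parent", "metabolite")[obs_i$DVID]
    dose_i <- doses$dose[doses$ID == id]
    nll <- function(eta) {
      p_i <- unclass(ref_params)
      p_i$V1 <- p_i$V1 * exp(eta)
      sim <- pk_simulate(do.call(pk_params, p_i), dose_i,
                         sort(unique(obs_i$TIME)))
      f <- ifelse(obs_i$DVID == 1L,
                  sim$conc_parent[match(obs_i$TIME, sim$time)],
                  sim$conc_metabolite[match(obs_i$TIME, sim$time)])
      sum(fmnpk:::neg2ll_contributions(obs_i$DV, f, obs_i$analyte, err))
    }
    integrand <- Vectorize(function(eta) {
      exp(-0.5 * (nll(eta) + eta^2 / om + log(2 * pi * om)))
    })
    # centre the integrand to avoid underflow
    c0 <- nll(0)
    marg <- integrate(function(e) integrand(e) * exp(c0 / 2), -3, 3,
                      rel.tol = 1e-10)$value
    oracle_total <- oracle_total + (-2 * log(marg) + c0)
  }
  expect_equal(lap$value, oracle_total, tolerance = 5e-3)
})

test_that("a mixed-effects fit recovers an IIV variance of realistic size", {
  study <- simulate_pk_study(n_subjects = 24, error = prop_err(0.2),
                             iiv = c(V1 = 0.18), seed = 61)
  fit <- fit_pk_nlme(study$data, error = prop_err(0.2), start = ref_params,
                     omega2 = c(V1 = 0.08),
                     fixed = c("F", "Fm", "tlag", "ka", "V2", "CL2", "CLm",
                               "Vm", "sigma_parent", "sigma_metabolite"))
  expect_true(fit$converged)
  om_hat <- unname(fit$omega2["V1"])
  expect_gt(om_hat, 0.09)
  expect_lt(om_hat, 0.36)
  expect_equal(unname(fit$estimates["V1"]), ref_params$V1, tolerance = 0.25)
  # empirical Bayes modes centre near zero
  expect_lt(abs(mean(fit$eta_modes$V1)), 0.2)
})

test_that("a richer nested model never fits worse than its restriction", {
  study <- simulate_pk_study(n_subjects = 5, error = prop_err(0.25), seed = 71)
  small <- fit_pk_pooled(study$data, error = prop_err(0.2), start = ref_params,
                         fixed = c("F", "Fm", "tlag", "V2", "CL2"))
  large <- fit_pk_pooled(study$data, error = prop_err(0.2), start = ref_params,
                         fixed = c("F", "Fm", "tlag"))
  expect_lte(large$neg2ll, small$neg2ll + 1e-4)
})
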