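test_that("parameter validation enforces ranges", {
  expect_error(pk_params(F = 1.2, Fm = 0.5, ka = 1, V1 = 1, V2 = 1, Vm = 1,
                         CL1 = 1, CL2 = 1, CLm = 1),
               class = "fmnpk_validation_error")
  expect_error(pk_params(F = 0.5, Fm = 0.5, ka = -1, V1 = 1, V2 = 1, Vm = 1,
                         CL1 = 1, CL2 = 1, CLm = 1),
               class = "fmnpk_validation_error")
})

test_that("the right-hand side reproduces hand-computed fluxes", {
  p <- ref_params
  expect_equal(unname(pk_rhs(c(0, 0, 0, 0), p)), rep(0, 4))

  d <- pk_rhs(c(100, 0, 0, 0), p)
  expect_equal(unname(d[["A_depot"]]), -7.12 * 100)
  expect_equal(unname(d[["A1"]]), 7.12 * 100)

  # parent central amount equal to V1 means C1 = 1 nmol/L, so the
  # metabolite-formation flux is Fm * CL1 * 1
  d2 <- pk_rhs(c(0, p$V1, 0, 0), p)
  expect_equal(unname(d2[["Am"]]), 0.89 * 19.85)
})

test_that("degenerate simulations behave: no dose absorbed, t = 0", {
  p0 <- pk_params(F = 0, Fm = 0.89, ka = 7.12, V1 = 25.04, V2 = 48.31,
                  Vm = 10.46, CL1 = 19.85, CL2 = 38.68, CLm = 41.54)
  s <- pk_simulate(p0, ref_dose, study_schedule)
  expect_true(all(s$conc_parent == 0) && all(s$conc_metabolite == 0))

  s0 <- pk_simulate(ref_params, ref_dose, c(0, 1))
  expect_equal(s0$conc_parent[1], 0)
  expect_equal(s0$conc_metabolite[1], 0)
})

test_that("closed-form AUC identities hold and match quadrature of the curves", {
  a <- auc_closed_form(ref_params, ref_dose)
  expect_equal(unname(a["parent"]), 0.31 * ref_dose / 19.85)
  expect_equal(unname(a["metabolite"]), 0.89 * 0.31 * ref_dose / 41.54)

  curve_at <- function(t, what) {
    o <- order(t)
    out <- numeric(length(t))
    out[o] <- pk_simulate(ref_params, ref_dose, t[o])[[what]]
    out
  }
  q_par <- integrate(curve_at, 0, Inf, what = "conc_parent",
                     rel.tol = 1e-10)$value
  q_met <- integrate(curve_at, 0, Inf, what = "conc_metabolite",
                     rel.tol = 1e-10)$value
  expect_equal(q_par, unname(a["parent"]), tolerance = 1e-7)
  expect_equal(q_met, unname(a["metabolite"]), tolerance = 1e-7)

  # unit identity and no-conversion limit
  pu <- pk_params(F = 1, Fm = 1, ka = 1, V1 = 1, V2 = 1, Vm = 1,
                  CL1 = 3, CL2 = 1, CLm = 1)
  expect_equal(unname(auc_closed_form(pu, 3)["parent"]), 1)
  pf <- pk_params(F = 0.5, Fm = 1e-12, ka = 1, V1 = 1, V2 = 1, Vm = 1,
                  CL1 = 3, CL2 = 1, CLm = 1)
  expect_equal(unname(auc_closed_form(pf, 3)["metabolite"]), 0, tolerance = 1e-11)
})

test_that("closed form and stiff ODE integrator agree to 1e-8 relative", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_params()
    s1 <- pk_simulate(p, ref_dose, study_schedule)
    s2 <- pk_simulate(p, ref_dose, study_schedule, method = "ode")
    scale_p <- max(s1$conc_parent)
    scale_m <- max(s1$conc_metabolite)
    expect_lt(max(abs(s1$conc_parent - s2$conc_parent)) / scale_p, 1e-8)
    expect_lt(max(abs(s1$conc_metabolite - s2$conc_metabolite)) / scale_m, 1e-8)
  }
})

test_that("matrix-exponential fallback handles eigenvalue degeneracy", {
  # ka chosen to collide exactly with the metabolite elimination rate
  p <- pk_params(F = 0.5, Fm = 0.8, ka = 4, V1 = 10, V2 = 20, Vm = 10,
                 CL1 = 10, CL2 = 15, CLm = 40)
  s1 <- pk_simulate(p, 1000, study_schedule)
  s2 <- pk_simulate(p, 1000, study_schedule, method = "ode")
  expect_equal(s1$conc_parent, s2$conc_parent, tolerance = 1e-8)
  expect_equal(s1$conc_metabolite, s2$conc_metabolite, tolerance = 1e-8)
})

test_that("mass balance is conserved along the trajectory", {
  tt <- c(0.1, 0.5, 1, 2, 6, 12, 24, 48)
  for (p in list(ref_params, {set.seed(7); random_params()})) {
    tr <- fmnpk:::simulate_with_cumulative(p, ref_dose, tt)
    total <- tr$A_depot + tr$A1 + tr$A2 + tr$cum_elim
    expect_lt(max(abs(total - p$F * ref_dose)) / (p$F * ref_dose), 1e-8)
    # formed metabolite is the fraction Fm of parent elimination, and splits
    # into circulating amount plus eliminated metabolite
    expect_lt(max(abs(tr$cum_formed - p$Fm * tr$cum_elim)) /
                max(tr$cum_formed), 1e-8)
    expect_lt(max(abs(tr$Am + tr$cum_met_elim - tr$cum_formed)) /
                max(tr$cum_formed), 1e-8)
  }
})

test_that("concentrations are non-negative and the parent curve decays to zero", {
  set.seed(55)
  for (i in 1:20) {
    p <- random_params()
    s <- pk_simulate(p, ref_dose, c(study_schedule, 100, 300))
    expect_true(all(s$conc_parent >= 0) && all(s$conc_metabolite >= 0))
    expect_lt(s$conc_parent[length(s$time)], 1e-3 * max(s$conc_parent))
  }
})

test_that("terminal log-slope equals the slowest system eigenvalue", {
  ev <- eigen(fmnpk:::pk_matrix(ref_params))$values
  lam_min <- min(abs(Re(ev)))
  tt <- c(60, 70)
  s <- pk_simulate(ref_params, ref_dose, tt)
  slope <- diff(log(s$conc_parent)) / diff(tt)
  expect_equal(-slope, lam_min, tolerance = 1e-6)
})

test_that("absorption lag shifts the profile in time", {
  p_lag <- pk_params(F = 0.31, Fm = 0.89, ka = 7.12, V1 = 25.04, V2 = 48.31,
                     Vm = 10.46, CL1 = 19.85, CL2 = 38.68, CLm = 41.54,
                     tlag = 0.25)
  s_lag <- pk_simulate(p_lag, ref_dose, c(0.1, 0.2, 0.5 + 0.25, 2 + 0.25))
  s_ref <- pk_simulate(ref_params, ref_dose, c(0.5, 2))
  expect_equal(s_lag$conc_parent[1:2], c(0, 0))
  expect_equal(s_lag$conc_parent[3:4], s_ref$conc_parent, tolerance = 1e-10)
})

test_that("Michaelis-Menten variant approaches the linear model for large Km", {
  # Vmax/Km -> CL1 as Km grows: the saturable flux linearises
  Km <- 1e6
  s_mm <- pk_simulate(ref_params, ref_dose, study_schedule,
                      elimination = "michaelis_menten",
                      Vmax = ref_params$CL1 * Km, Km = Km)
  s_lin <- pk_simulate(ref_params, ref_dose, study_schedule)
  expect_equal(s_mm$conc_parent, s_lin$conc_parent, tolerance = 1e-3)
  # and genuinely saturates (slower decline) at low Km
  s_sat <- pk_simulate(ref_params, ref_dose, study_schedule,
                       elimination = "michaelis_menten",
                       Vmax = ref_params$CL1 * 20, Km = 20)
  expect_gt(s_sat$conc_parent[5], s_lin$conc_parent[5])
})
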