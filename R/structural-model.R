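#' Structural parameters of the parent-metabolite model
#'
#' The disposition model is a two-compartment model for the parent compound
#' with first-order absorption from a depot, coupled to a one-compartment
#' metabolite. A fraction `F` of the oral dose reaches the depot; parent drug
#' is cleared from the central compartment with total clearance `CL1`, of
#' which a fraction `Fm` forms the observed metabolite (1:1 molar
#' stoichiometry); the metabolite is eliminated with clearance `CLm`.
#' `CL2` is the inter-compartmental (distributional) clearance between the
#' parent central (`V1`) and peripheral (`V2`) volumes. An optional
#' absorption lag `tlag` shifts the depot input in time.
#'
#' @param F Fraction of the dose absorbed, in `[0, 1]`.
#' @param Fm Fraction of parent clearance forming the metabolite, in `[0, 1]`.
#' @param ka First-order absorption rate constant, 1/h.
#' @param V1,V2,Vm Parent central, parent peripheral and metabolite volumes
#'   of distribution, L.
#' @param CL1,CL2,CLm Parent total, inter-compartmental and metabolite
#'   clearances, L/h.
#' @param tlag Absorption lag time, h (default 0).
#' @return A named `pk_params` list.
#' @export
#' @examples
#' pk_params(F = 0.31, Fm = 0.89, ka = 7.12, V1 = 25.04, V2 = 48.31,
#'           Vm = 10.46, CL1 = 19.85, CL2 = 38.68, CLm = 41.54)
pk_params <- function(F, Fm, ka, V1, V2, Vm, CL1, CL2, CLm, tlag = 0) {
  p <- list(F = F, Fm = Fm, ka = ka, V1 = V1, V2 = V2, Vm = Vm,
            CL1 = CL1, CL2 = CL2, CLm = CLm, tlag = tlag)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1)))) {
    abort("All structural parameters must be finite scalars.",
          class = "fmnpk_validation_error")
  }
  if (p$F < 0 || p$F > 1 || p$Fm < 0 || p$Fm > 1) {
    abort("`F` and `Fm` must lie in [0, 1].", class = "fmnpk_validation_error")
  }
  pos <- c("ka", "V1", "V2", "Vm", "CL1", "CL2", "CLm")
  if (any(unlist(p[pos]) <= 0)) {
    abort("Rate constants, volumes and clearances must be positive.",
          class = "fmnpk_validation_error")
  }
  if (p$tlag < 0) {
    abort("`tlag` must be non-negative.", class = "fmnpk_validation_error")
  }
  structure(p, class = "pk_params")
}

#' Reference parameter set for the solid-dispersion study arm
#'
#' Published final-model estimates for 20 mg/kg oral formononetin given as a
#' solid dispersion in rats; used as the default truth of the synthetic
#' study generator and as a convenient starting point for fits.
#'
#' @return A [pk_params()] object.
#' @export
fmn_reference_params <- function() {
  pk_params(F = 0.31, Fm = 0.89, ka = 7.12, V1 = 25.04, V2 = 48.31,
            Vm = 10.46, CL1 = 19.85, CL2 = 38.68, CLm = 41.54)
}

# System matrix of the linear compartmental ODE, state order
# (depot, parent central, parent peripheral, metabolite), amounts in nmol.
pk_matrix <- function(params) {
  p <- params
  k10 <- p$CL1 / p$V1
  k12 <- p$CL2 / p$V1
  k21 <- p$CL2 / p$V2
  km  <- p$CLm / p$Vm
  matrix(c(
    -p$ka,        0,            0,     0,
     p$ka,      -(k10 + k12),  k21,    0,
     0,           k12,        -k21,    0,
     0,           p$Fm * k10,   0,    -km
  ), nrow = 4, byrow = TRUE)
}

#' Right-hand side of the compartmental ODE system
#'
#' Amount derivatives (nmol/h) for state
#' `(A_depot, A1, A2, Am)`:
#' \deqn{dA_{depot}/dt = -k_a A_{depot}}
#' \deqn{dA_1/dt = k_a A_{depot} - (CL_1/V_1) A_1 - (CL_2/V_1) A_1 + (CL_2/V_2) A_2}
#' \deqn{dA_2/dt = (CL_2/V_1) A_1 - (CL_2/V_2) A_2}
#' \deqn{dA_m/dt = F_m (CL_1/V_1) A_1 - (CL_m/V_m) A_m}
#' The total parent elimination flux is `(CL1/V1) A1`, of which the fraction
#' `Fm` enters the metabolite compartment; the remainder leaves the system.
#'
#' With `elimination = "michaelis_menten"` the linear parent elimination term
#' `(CL1/V1) A1` is replaced by the saturable flux
#' `Vmax * A1 / (Km * V1 + A1)` (i.e. `Vmax * C1 / (Km + C1)`).
#'
#' @param state Named or positional numeric of length 4:
#'   `A_depot, A1, A2, Am` (nmol).
#' @param params A [pk_params()] object.
#' @param elimination `"linear"` (default) or `"michaelis_menten"`.
#' @param Vmax,Km Saturable-elimination parameters (nmol/h and nmol/L),
#'   required for the Michaelis-Menten variant.
#' @return Named numeric of the four derivatives, nmol/h.
#' @export
pk_rhs <- function(state, params, elimination = c("linear", "michaelis_menten"),
                   Vmax = NULL, Km = NULL) {
  elimination <- match.arg(elimination)
  s <- unname(as.numeric(state))
  p <- params
  k12 <- p$CL2 / p$V1
  k21 <- p$CL2 / p$V2
  elim_flux <- if (elimination == "linear") {
    (p$CL1 / p$V1) * s[2]
  } else {
    if (is.null(Vmax) || is.null(Km)) {
      abort("Michaelis-Menten elimination needs `Vmax` and `Km`.",
            class = "fmnpk_validation_error")
    }
    Vmax * s[2] / (Km * p$V1 + s[2])
  }
  c(A_depot = -p$ka * s[1],
    A1 = p$ka * s[1] - elim_flux - k12 * s[2] + k21 * s[3],
    A2 = k12 * s[2] - k21 * s[3],
    Am = p$Fm * elim_flux - (p$CLm / p$Vm) * s[4])
}

#' Simulate plasma concentrations under the parent-metabolite model
#'
#' Solves the compartmental system for a single oral dose with initial
#' condition `A_depot(tlag) = F * dose_amount` (all other compartments
#' empty) and returns parent and metabolite plasma concentrations
#' `C_parent = A1/V1` and `C_metabolite = Am/Vm`.
#'
#' The linear model is solved in closed form by eigen-decomposition of the
#' constant system matrix; when eigenvalues are (near-)degenerate the solver
#' falls back to a scaling-and-squaring matrix exponential, so degeneracy is
#' not a failure mode. A stiff-capable numeric integrator
#' (`method = "ode"`, [deSolve::lsoda()] at rtol 1e-10 / atol 1e-12) is kept
#' available as an independent oracle and is the only path for the
#' Michaelis-Menten variant.
#'
#' @inheritParams pk_rhs
#' @param params A [pk_params()] object.
#' @param dose_amount Oral dose, nmol.
#' @param times Sorted non-negative observation times, h.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @return A tibble with columns `time`, `conc_parent`, `conc_metabolite`
#'   (nmol/L).
#' @export
#' @examples
#' sim <- pk_simulate(fmn_reference_params(), dose_amount = 16529,
#'                    times = c(0.08, 0.16, 0.33, 0.5, 1, 2, 4, 8, 12, 24))
#' sim
pk_simulate <- function(params, dose_amount, times,
                        method = c("closed_form", "ode"),
                        elimination = c("linear", "michaelis_menten"),
                        Vmax = NULL, Km = NULL) {
  method <- match.arg(method)
  elimination <- match.arg(elimination)
  if (is.unsorted(times) || any(times < 0)) {
    abort("`times` must be sorted and non-negative.",
          class = "fmnpk_validation_error")
  }
  if (dose_amount < 0) {
    abort("`dose_amount` must be non-negative.", class = "fmnpk_validation_error")
  }
  if (elimination == "michaelis_menten") method <- "ode"

  # absorption lag: the system starts at tlag; earlier times are all-zero
  t_eff <- pmax(times - params$tlag, 0)
  x0 <- c(params$F * dose_amount, 0, 0, 0)

  states <- if (method == "closed_form") {
    solve_linear(pk_matrix(params), x0, t_eff)
  } else {
    solve_ode(params, x0, t_eff, elimination, Vmax, Km)
  }
  # numerical negatives from roundoff are clamped
  states[states < 0 & states > -1e-9 * max(abs(x0), 1)] <- 0
  tibble(time = times,
         conc_parent = states[, 2] / params$V1,
         conc_metabolite = states[, 4] / params$Vm)
}

# Fast internal path: closed-form concentrations without tibble/validation
# overhead, for the optimizer hot loops. `p` is a plain named list.
simulate_conc <- function(p, dose_amount, times) {
  t_eff <- if (p$tlag > 0) pmax(times - p$tlag, 0) else times
  states <- solve_linear(pk_matrix(p), c(p$F * dose_amount, 0, 0, 0), t_eff)
  list(parent = pmax(states[, 2], 0) / p$V1,
       metabolite = pmax(states[, 4], 0) / p$Vm)
}

# Closed-form solution x(t) = V exp(L t) V^-1 x0 of x' = A x, with a matrix
# exponential fallback when the eigensystem is degenerate/ill-conditioned.
solve_linear <- function(A, x0, times) {
  e <- eigen(A)
  ok <- all(abs(Im(e$values)) < 1e-10)
  if (ok) {
    lam <- Re(e$values)
    gap <- min(abs(diff(sort(lam))))
    scale <- max(abs(lam), 1)
    V <- Re(e$vectors)
    ok <- gap > 1e-8 * scale && rcond(V) > 1e-10
  }
  if (ok) {
    w <- solve(V, x0)
    out <- t(vapply(times, function(t) as.numeric(V %*% (w * exp(lam * t))),
                    numeric(4)))
  } else {
    out <- t(vapply(times, function(t) as.numeric(expm_pade(A * t) %*% x0),
                    numeric(4)))
  }
  out
}

# Scaling-and-squaring matrix exponential (Pade order 6); 4x4 only, so a
# compact local implementation is cheaper than pulling in heavier machinery.
expm_pade <- function(M) {
  n <- nrow(M)
  j <- max(0, ceiling(log2(max(norm(M, "I"), 1e-300))) + 1)
  Ms <- M / 2^j
  c_ <- 1
  X <- diag(n)
  N <- diag(n); D <- diag(n)
  q <- 6
  for (k in seq_len(q)) {
    c_ <- c_ * (q - k + 1) / (k * (2 * q - k + 1))
    X <- Ms %*% X
    N <- N + c_ * X
    D <- D + (-1)^k * c_ * X
  }
  E <- solve(D, N)
  for (k in seq_len(j)) E <- E %*% E
  E
}

solve_ode <- function(params, x0, times, elimination, Vmax, Km) {
  t_out <- sort(unique(c(0, times)))
  deriv <- function(t, y, parms) list(pk_rhs(y, params, elimination, Vmax, Km))
  sol <- deSolve::lsoda(y = x0, times = t_out, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  idx <- match(times, t_out)
  unname(as.matrix(sol[idx, -1, drop = FALSE]))
}

# ODE solve augmented with cumulative parent-elimination,
# metabolite-formation and metabolite-elimination fluxes; used for
# mass-balance verification.
simulate_with_cumulative <- function(params, dose_amount, times) {
  x0 <- c(params$F * dose_amount, 0, 0, 0, 0, 0, 0)
  deriv <- function(t, y, parms) {
    d <- pk_rhs(y[1:4], params)
    elim <- (params$CL1 / params$V1) * y[2]
    met_elim <- (params$CLm / params$Vm) * y[4]
    list(c(d, elim, params$Fm * elim, met_elim))
  }
  t_out <- sort(unique(c(0, pmax(times - params$tlag, 0))))
  sol <- deSolve::lsoda(y = x0, times = t_out, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out <- as.matrix(sol[match(pmax(times - params$tlag, 0), t_out), -1, drop = FALSE])
  colnames(out) <- c("A_depot", "A1", "A2", "Am",
                     "cum_elim", "cum_formed", "cum_met_elim")
  tibble::as_tibble(out) |> dplyr::mutate(time = times, .before = 1)
}

#' Closed-form total exposure under the parent-metabolite model
#'
#' Steady mass balance of the linear system gives the total areas under the
#' concentration-time curves on `[0, Inf)`:
#' `AUC_parent = F * D / CL1` and `AUC_metabolite = Fm * F * D / CLm`.
#'
#' @param params A [pk_params()] object.
#' @param dose_amount Oral dose, nmol (> 0).
#' @return Named numeric `c(parent =, metabolite =)` in h*nmol/L.
#' @export
#' @examples
#' auc_closed_form(fmn_reference_params(), 16529)
auc_closed_form <- function(params, dose_amount) {
  if (dose_amount <= 0) {
    abort("`dose_amount` must be positive.", class = "fmnpk_validation_error")
  }
  c(parent = params$F * dose_amount / params$CL1,
    metabolite = params$Fm * params$F * dose_amount / params$CLm)
}
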