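STRUCTURAL_NAMES <- c("F", "Fm", "ka", "V1", "V2", "Vm", "CL1", "CL2", "CLm")

#' Residual-error models
#'
#' Intra-individual (residual) variability of an observation y around the
#' model prediction f is described by one of four variance models, with a
#' separate sigma per analyte:
#'
#' * `additive`: `y = f + sigma * eps`, variance `g = sigma^2`
#' * `proportional`: `y = f (1 + sigma * eps)`, variance `g = sigma^2 f^2`
#' * `log_additive`: `log y = log f + sigma * eps`
#' * `additive_plus_proportional`: `g = sigma_add^2 + sigma_prop^2 f^2`
#'
#' For the simple kinds `sigma` is named `c(parent =, metabolite =)`;
#' the combined kind takes `c(prop_parent =, add_parent =, prop_metabolite =,
#' add_metabolite =)`.
#'
#' @param kind Error-model kind, see above.
#' @param sigma Named positive numeric of sigma parameters.
#' @return An `error_model` object.
#' @export
#' @examples
#' error_model("proportional", c(parent = 0.2, metabolite = 0.2))
error_model <- function(kind = c("proportional", "additive", "log_additive",
                                 "additive_plus_proportional"),
                        sigma) {
  kind <- match.arg(kind)
  want <- if (kind == "additive_plus_proportional") {
    c("prop_parent", "add_parent", "prop_metabolite", "add_metabolite")
  } else {
    c("parent", "metabolite")
  }
  if (!is.numeric(sigma) || !setequal(names(sigma), want) || any(sigma <= 0)) {
    abort(paste0("`sigma` must be positive and named: ",
                 paste(want, collapse = ", ")),
          class = "fmnpk_validation_error")
  }
  structure(list(kind = kind, sigma = sigma[want]), class = "error_model")
}

# Residual variance g(f) per observation; `analyte` is "parent"/"metabolite".
error_variance <- function(error, f, analyte) {
  s <- error$sigma
  switch(error$kind,
    additive = s[analyte]^2 + 0 * f,
    proportional = s[analyte]^2 * f^2,
    log_additive = s[analyte]^2 + 0 * f,
    additive_plus_proportional =
      s[paste0("add_", analyte)]^2 + s[paste0("prop_", analyte)]^2 * f^2
  )
}

# Model predictions for quantifiable observations under shared parameters.
# Subjects sharing a dose amount share one closed-form solve.
predict_obs <- function(obs, doses, params) {
  obs$dose <- doses$dose[match(obs$ID, doses$ID)]
  obs$analyte <- c("parent", "metabolite")[obs$DVID]
  f <- numeric(nrow(obs))
  for (d in unique(obs$dose)) {
    sel <- which(obs$dose == d)
    tt <- sort(unique(obs$TIME[sel]))
    sim <- simulate_conc(params, d, tt)
    i <- match(obs$TIME[sel], tt)
    f[sel] <- ifelse(obs$DVID[sel] == 1L, sim$parent[i], sim$metabolite[i])
  }
  obs$f <- f
  obs
}

neg2ll_contributions <- function(y, f, analyte, error, id = NULL, time = NULL) {
  g <- error_variance(error, f, analyte)
  if (error$kind %in% c("proportional", "log_additive", "additive_plus_proportional")) {
    bad <- which(f <= 0 & (error$kind != "additive_plus_proportional" | g <= 0))
    if (error$kind == "log_additive") bad <- union(bad, which(f <= 0))
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "Non-positive model prediction under %s error model (subject %s, t = %s h, %s).",
        error$kind,
        if (is.null(id)) "?" else id[i],
        if (is.null(time)) "?" else format(time[i]),
        analyte[i]), class = "fmnpk_numerical_error")
    }
  }
  if (error$kind == "log_additive") {
    if (any(y <= 0)) {
      abort("Log-additive error model requires positive observations.",
            class = "fmnpk_validation_error")
    }
    # Gaussian on the log scale, reported on the observation scale: the
    # change-of-variables term 2 ln y keeps the objective directly
    # comparable with the proportional model (to first order in the CV the
    # two coincide).
    res2 <- (log(y) - log(f))^2
    log(2 * pi * g) + res2 / g + 2 * log(y)
  } else {
    log(2 * pi * g) + (y - f)^2 / g
  }
}

#' Pooled -2 log-likelihood
#'
#' The naive-pooled objective: all observations are treated as coming from
#' one set of structural parameters (no inter-individual variability), and
#' \deqn{-2LL = \sum_{obs} [\ln(2\pi g) + (y - f)^2 / g]}
#' with the residual variance `g` given by the [error_model()]. For the
#' log-additive kind the residual is taken on the log scale.
#' BLQ records are excluded.
#'
#' @param data A [as_pk_dataset()] tibble.
#' @param params A [pk_params()] object.
#' @param error An [error_model()].
#' @return The scalar -2LL.
#' @export
pk_neg2ll <- function(data, params, error) {
  obs <- quantifiable(data)
  if (nrow(obs) == 0) {
    abort("No quantifiable observations.", class = "fmnpk_validation_error")
  }
  obs <- predict_obs(obs, subject_doses(data), params)
  sum(neg2ll_contributions(obs$DV, obs$f, obs$analyte, error,
                           id = obs$ID, time = obs$TIME))
}

## ---- parameter transforms ----------------------------------------------
# Positive parameters are optimized on the log scale, fractions on the logit
# scale, which keeps the optimizer unconstrained and the estimates in range.

is_fraction <- function(name) name %in% c("F", "Fm")

to_transformed <- function(x, name) {
  ifelse(is_fraction(name), qlogis(x), log(x))
}

from_transformed <- function(x, name) {
  ifelse(is_fraction(name), plogis(x), exp(x))
}

# d(natural)/d(transformed), for delta-method standard errors
transform_jacobian <- function(nat, name) {
  ifelse(is_fraction(name), nat * (1 - nat), nat)
}

full_param_vector <- function(start, error) {
  c(unlist(start[STRUCTURAL_NAMES]),
    tlag = start$tlag,
    setNames(as.numeric(error$sigma), paste0("sigma_", names(error$sigma))))
}

split_param_vector <- function(nat, error_kind) {
  sig_idx <- startsWith(names(nat), "sigma_")
  sigma <- setNames(as.numeric(nat[sig_idx]),
                    sub("^sigma_", "", names(nat)[sig_idx]))
  params <- do.call(pk_params, as.list(nat[!sig_idx]))
  list(params = params, error = error_model(error_kind, sigma))
}

#' Fit the parent-metabolite model by pooled maximum likelihood
#'
#' Minimises [pk_neg2ll()] over the non-fixed parameters with a quasi-Newton
#' optimizer ([stats::nlminb()], numeric gradients). Positive parameters are
#' optimized on the log scale and the fractions `F` and `Fm` on the logit
#' scale; sigma parameters are bounded below at 1e-6 on the transformed
#' scale. Standard errors (reported as CV% = 100 SE / estimate) come from
#' the inverse observed information at the optimum.
#'
#' With oral data on parent and metabolite only, `F` is confounded with the
#' scale of `V1`, `V2`, `CL1`, `CL2`, and `Fm` with that of `Vm`, `CLm`;
#' fixing `F` and `Fm` (the default) removes the flat directions.
#'
#' @param data A [as_pk_dataset()] tibble.
#' @param error An [error_model()]; its sigmas are starting values.
#' @param start A [pk_params()] object of starting values.
#' @param fixed Character vector of parameter names held at their starting
#'   values (structural names, `"tlag"`, or `"sigma_<analyte>"`).
#' @param n_starts Number of optimizer starts; starts beyond the first are
#'   jittered on the transformed scale (SD `jitter_sd`).
#' @param jitter_sd Jitter SD for multi-start.
#' @param control Passed to [stats::nlminb()].
#' @return A `pk_fit` object; see [tidy.pk_fit()] and [glance.pk_fit()].
#' @export
#' @examples
#' study <- simulate_pk_study(n_subjects = 5, seed = 42,
#'   error = error_model("proportional", c(parent = 0.2, metabolite = 0.2)))
#' fit <- fit_pk_pooled(study$data,
#'   error = error_model("proportional", c(parent = 0.3, metabolite = 0.3)),
#'   start = fmn_reference_params())
#' glance(fit)
fit_pk_pooled <- function(data, error, start = fmn_reference_params(),
                          fixed = c("F", "Fm", "tlag"),
                          n_starts = 1, jitter_sd = 0.2,
                          control = list(rel.tol = 1e-8, iter.max = 500,
                                         eval.max = 2000)) {
  if (!"tlag" %in% fixed && start$tlag <= 0) {
    abort("Estimating `tlag` requires a positive starting value.",
          class = "fmnpk_validation_error")
  }
  nat_full <- full_param_vector(start, error)
  unknown <- setdiff(fixed, names(nat_full))
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter(s) in `fixed`: ",
                 paste(unknown, collapse = ", ")),
          class = "fmnpk_validation_error")
  }
  free <- setdiff(names(nat_full), fixed)
  obs <- quantifiable(data)
  doses <- subject_doses(data)

  objective <- function(tr) {
    nat <- nat_full
    nat[free] <- from_transformed(tr, free)
    pe <- split_param_vector(nat, error$kind)
    val <- tryCatch({
      o <- predict_obs(obs, doses, pe$params)
      sum(neg2ll_contributions(o$DV, o$f, o$analyte, pe$error,
                               id = o$ID, time = o$TIME))
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  tr0 <- to_transformed(nat_full[free], free)
  lower <- rep(-Inf, length(free))
  lower[startsWith(free, "sigma_")] <- log(1e-6)
  starts <- list(tr0)
  if (n_starts > 1) {
    starts <- c(starts, lapply(seq_len(n_starts - 1), function(i) {
      tr0 + rnorm(length(tr0), sd = jitter_sd)
    }))
  }
  fits <- lapply(starts, function(s) {
    nlminb(s, objective, lower = lower, control = control)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]

  nat_hat <- nat_full
  nat_hat[free] <- from_transformed(best$par, free)
  pe <- split_param_vector(nat_hat, error$kind)

  cv <- setNames(rep(NA_real_, length(nat_full)), names(nat_full))
  vcov_tr <- NULL
  se_nat <- cv
  H <- tryCatch(optimHess(best$par, objective), error = function(e) NULL)
  if (!is.null(H)) {
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
      vcov_tr <- vc
      se_tr <- sqrt(diag(vc))
      jac <- transform_jacobian(nat_hat[free], free)
      se_nat[free] <- se_tr * abs(jac)
      cv[free] <- 100 * se_nat[free] / abs(nat_hat[free])
    }
  }

  structure(list(
    estimates = nat_hat,
    params = pe$params,
    error = pe$error,
    fixed = fixed,
    free = free,
    cv_percent = cv,
    se = se_nat,
    vcov_trans = vcov_tr,
    neg2ll = best$objective,
    n_params = length(free),
    n_obs = nrow(obs),
    aic = aic(best$objective, length(free)),
    bic = bic(best$objective, length(free), nrow(obs)),
    converged = best$convergence == 0,
    message = best$message,
    iterations = best$iterations,
    start = start,
    data = data
  ), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> pooled maximum likelihood\n")
  cat(sprintf("  -2LL %.2f | AIC %.2f | BIC %.2f | %d parameter(s), %d obs | %s\n",
              x$neg2ll, x$aic, x$bic, x$n_params, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Predicted concentrations for the observations behind a fit
#'
#' @param object A `pk_fit` or `pk_nlme_fit`.
#' @param ... Unused.
#' @return The quantifiable observation rows with `analyte`, prediction `f`
#'   and the standardized residual `(y - f) / sqrt(g)`.
#' @export
predict.pk_fit <- function(object, ...) {
  obs <- predict_obs(quantifiable(object$data), subject_doses(object$data),
                     object$params)
  g <- error_variance(object$error, obs$f, obs$analyte)
  obs$residual_std <- if (object$error$kind == "log_additive") {
    (log(obs$DV) - log(obs$f)) / sqrt(g)
  } else {
    (obs$DV - obs$f) / sqrt(g)
  }
  as_tibble(obs)
}

## ---- Laplace-approximate NLME ------------------------------------------

#' Marginal -2 log-likelihood of the mixed-effects model (Laplace)
#'
#' Inter-individual variability enters as `P_i = P_tv * exp(eta_i)` with
#' `eta_i ~ N(0, omega^2)`, independent across parameters (diagonal omega
#' only). Each subject's marginal likelihood integral over eta is
#' approximated by the Laplace method at the mode of the joint density:
#' \deqn{-2LL_i = j(\hat\eta) - q \ln(2\pi) + \ln\det(H/2)}
#' where `j` is the joint -2 log-density and `H` its Hessian at the mode.
#' Variance components below 1e-10 are treated as structurally zero (the
#' corresponding eta is dropped), so with all-zero omega the objective
#' reduces exactly to [pk_neg2ll()].
#'
#' @param data A [as_pk_dataset()] tibble.
#' @param params Fixed-effect (typical-value) [pk_params()].
#' @param error An [error_model()].
#' @param omega2 Named non-negative numeric of IIV variances, names among
#'   the structural parameters.
#' @param eta_start Optional list of per-subject starting modes.
#' @return A list: `value` (total -2LL), `eta_modes` (tibble), `n_fallback`
#'   (subjects whose Hessian needed the eta = 0 fallback).
#' @export
pk_nlme_objective <- function(data, params, error, omega2, eta_start = NULL) {
  bad <- setdiff(names(omega2), STRUCTURAL_NAMES)
  if (length(bad) > 0 || any(omega2 < 0)) {
    abort("`omega2` must be non-negative and named after structural parameters.",
          class = "fmnpk_validation_error")
  }
  active <- names(omega2)[omega2 > 1e-10]
  obs_all <- quantifiable(data)
  doses <- subject_doses(data)
  ids <- unique(obs_all$ID)

  if (length(active) == 0) {
    val <- pk_neg2ll(data, params, error)
    return(list(value = val,
                eta_modes = tibble(ID = ids),
                n_fallback = 0L))
  }
  om <- omega2[active]
  q <- length(active)

  subj_joint <- function(eta, obs_i, dose_i, tt, idx) {
    p_i <- params
    for (k in seq_along(active)) {
      p_i[[active[k]]] <- params[[active[k]]] * exp(eta[k])
    }
    if (p_i$F > 1 || p_i$Fm > 1) return(1e10)
    nll <- tryCatch({
      sim <- simulate_conc(p_i, dose_i, tt)
      f <- ifelse(obs_i$DVID == 1L, sim$parent[idx], sim$metabolite[idx])
      sum(neg2ll_contributions(obs_i$DV, f, obs_i$analyte, error))
    }, error = function(e) NA_real_)
    if (!is.finite(nll)) return(1e10)
    nll + sum(eta^2 / om) + sum(log(2 * pi * om))
  }

  total <- 0
  n_fallback <- 0L
  modes <- matrix(0, nrow = length(ids), ncol = q,
                  dimnames = list(NULL, active))
  for (s in seq_along(ids)) {
    obs_i <- obs_all[obs_all$ID == ids[s], ]
    obs_i$analyte <- c("parent", "metabolite")[obs_i$DVID]
    dose_i <- doses$dose[doses$ID == ids[s]]
    tt <- sort(unique(obs_i$TIME))
    idx <- match(obs_i$TIME, tt)
    fn <- function(eta) subj_joint(eta, obs_i, dose_i, tt, idx)
    e0 <- if (!is.null(eta_start) && !is.null(eta_start[[as.character(ids[s])]])) {
      eta_start[[as.character(ids[s])]]
    } else rep(0, q)
    inner <- nlminb(e0, fn, control = list(rel.tol = 1e-12, abs.tol = 1e-20))
    eta_hat <- inner$par
    H <- tryCatch(optimHess(eta_hat, fn), error = function(e) NULL)
    ld <- if (!is.null(H)) {
      dt <- determinant(H / 2, logarithm = TRUE)
      if (dt$sign > 0) as.numeric(dt$modulus) else NULL
    } else NULL
    if (is.null(ld)) {
      # first-order fallback at eta = 0
      n_fallback <- n_fallback + 1L
      eta_hat <- rep(0, q)
      H0 <- tryCatch(optimHess(eta_hat, fn), error = function(e) NULL)
      dt0 <- if (!is.null(H0)) determinant(H0 / 2, logarithm = TRUE) else NULL
      ld <- if (!is.null(dt0) && dt0$sign > 0) as.numeric(dt0$modulus) else {
        sum(log(1 / om))  # prior curvature only
      }
      total <- total + fn(eta_hat) - q * log(2 * pi) + ld
    } else {
      total <- total + inner$objective - q * log(2 * pi) + ld
    }
    modes[s, ] <- eta_hat
  }
  list(value = total,
       eta_modes = dplyr::bind_cols(tibble(ID = ids), as_tibble(modes)),
       n_fallback = n_fallback)
}

#' Fit the mixed-effects model by Laplace approximation
#'
#' Minimises the Laplace marginal -2LL of [pk_nlme_objective()] over the
#' non-fixed fixed effects, the residual sigmas and the IIV variances
#' (diagonal omega^2, log-transformed). Empirical Bayes eta modes are
#' returned for the final estimates.
#'
#' @inheritParams fit_pk_pooled
#' @param omega2 Named positive numeric of starting IIV variances; the names
#'   define which parameters carry random effects. Entries listed in `fixed`
#'   as `"omega2_<name>"` are held fixed.
#' @return A `pk_nlme_fit` object.
#' @export
fit_pk_nlme <- function(data, error, start = fmn_reference_params(),
                        omega2,
                        fixed = c("F", "Fm", "tlag"),
                        control = list(rel.tol = 1e-7, iter.max = 200,
                                       eval.max = 1000)) {
  if (length(omega2) == 0 || is.null(names(omega2)) || any(omega2 <= 0)) {
    abort("`omega2` must be a named positive numeric (starting variances).",
          class = "fmnpk_validation_error")
  }
  if (dplyr::n_distinct(data$ID) < 2) {
    abort("Mixed-effects estimation needs at least 2 subjects.",
          class = "fmnpk_validation_error")
  }
  nat_full <- c(full_param_vector(start, error),
                setNames(as.numeric(omega2), paste0("omega2_", names(omega2))))
  free <- setdiff(names(nat_full), fixed)
  objective <- function(tr) {
    nat <- nat_full
    nat[free] <- exp(tr)  # omega2 and sigma are positive; fractions stay fixed
    nat[free][is_fraction(free)] <- plogis(tr[is_fraction(free)])
    om_idx <- startsWith(names(nat), "omega2_")
    pe <- tryCatch(split_param_vector(nat[!om_idx], error$kind),
                   error = function(e) NULL)
    if (is.null(pe)) return(1e10)
    om <- setNames(as.numeric(nat[om_idx]), sub("^omega2_", "", names(nat)[om_idx]))
    res <- tryCatch(
      pk_nlme_objective(data, pe$params, pe$error, om),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) return(1e10)
    res$value
  }

  tr0 <- ifelse(is_fraction(free), qlogis(nat_full[free]), log(nat_full[free]))
  lower <- rep(-Inf, length(free))
  lower[startsWith(free, "sigma_")] <- log(1e-6)
  lower[startsWith(free, "omega2_")] <- log(1e-8)
  opt <- nlminb(tr0, objective, lower = lower, control = control)

  nat_hat <- nat_full
  nat_hat[free] <- exp(opt$par)
  nat_hat[free][is_fraction(free)] <- plogis(opt$par[is_fraction(free)])
  om_idx <- startsWith(names(nat_hat), "omega2_")
  pe <- split_param_vector(nat_hat[!om_idx], error$kind)
  om_hat <- setNames(as.numeric(nat_hat[om_idx]),
                     sub("^omega2_", "", names(nat_hat)[om_idx]))
  final <- pk_nlme_objective(data, pe$params, pe$error, om_hat)

  cv <- setNames(rep(NA_real_, length(nat_full)), names(nat_full))
  H <- tryCatch(optimHess(opt$par, objective), error = function(e) NULL)
  if (!is.null(H)) {
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
      se_tr <- sqrt(diag(vc))
      jac <- ifelse(is_fraction(free),
                    nat_hat[free] * (1 - nat_hat[free]), nat_hat[free])
      cv[free] <- 100 * se_tr * abs(jac) / abs(nat_hat[free])
    }
  }
  n_obs <- nrow(quantifiable(data))
  structure(list(
    estimates = nat_hat,
    params = pe$params,
    error = pe$error,
    omega2 = om_hat,
    fixed = fixed,
    free = free,
    cv_percent = cv,
    eta_modes = final$eta_modes,
    n_fallback = final$n_fallback,
    neg2ll = opt$objective,
    n_params = length(free),
    n_obs = n_obs,
    aic = aic(opt$objective, length(free)),
    bic = bic(opt$objective, length(free), n_obs),
    converged = opt$convergence == 0,
    message = opt$message,
    start = start,
    data = data
  ), class = c("pk_nlme_fit", "pk_fit"))
}

#' @export
print.pk_nlme_fit <- function(x, ...) {
  cat("<pk_nlme_fit> Laplace-approximate mixed effects\n")
  cat(sprintf("  -2LL %.2f | AIC %.2f | BIC %.2f | %d parameter(s), %d obs | %s\n",
              x$neg2ll, x$aic, x$bic, x$n_params, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x), n = Inf)
  invisible(x)
}
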