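#' Information criteria
#'
#' `aic()` and `bic()` penalise the -2 log-likelihood for model size:
#' `AIC = -2LL + 2 p` and `BIC = -2LL + p ln(n)`, with `p` the number of
#' estimated parameters and `n` the number of included observations.
#'
#' @param neg2ll -2 log-likelihood.
#' @param n_params Number of estimated parameters (>= 0).
#' @param n_obs Number of observations (>= 1).
#' @return The criterion value.
#' @export
#' @examples
#' aic(603.86, 5)        # 613.86
#' bic(603.86, 5, 41)    # 622.43
aic <- function(neg2ll, n_params) {
  if (any(n_params < 0)) {
    abort("`n_params` must be non-negative.", class = "fmnpk_validation_error")
  }
  neg2ll + 2 * n_params
}

#' @rdname aic
#' @export
bic <- function(neg2ll, n_params, n_obs) {
  if (any(n_params < 0)) {
    abort("`n_params` must be non-negative.", class = "fmnpk_validation_error")
  }
  if (any(n_obs < 1)) {
    abort("`n_obs` must be at least 1.", class = "fmnpk_validation_error")
  }
  neg2ll + n_params * log(n_obs)
}

#' Likelihood-ratio decision rule for nested models
#'
#' When one parameter separates two nested models, the -2LL difference is
#' compared to chi-squared(df = 1) quantiles: adding a parameter is accepted
#' if the -2LL decrease exceeds the 95% quantile (3.84); removing a
#' parameter is accepted if the -2LL increase stays below the 99% quantile
#' (6.63).
#'
#' @param delta_neg2ll `(-2LL of the smaller model) - (-2LL of the larger
#'   model)`, i.e. the decrease gained by the extra parameter (>= 0 at a
#'   common optimum).
#' @param direction `"add_parameter"` or `"remove_parameter"`.
#' @return `TRUE` if the move (addition or removal) is accepted.
#' @export
#' @examples
#' nested_decision(4.0, "add_parameter")     # TRUE
#' nested_decision(3.0, "add_parameter")     # FALSE
#' nested_decision(5.0, "remove_parameter")  # TRUE: increase < 6.63
nested_decision <- function(delta_neg2ll,
                            direction = c("add_parameter", "remove_parameter")) {
  direction <- match.arg(direction)
  th <- lrt_thresholds()
  if (direction == "add_parameter") {
    delta_neg2ll > th[["add"]]
  } else {
    delta_neg2ll < th[["remove"]]
  }
}

#' @rdname nested_decision
#' @return `lrt_thresholds()` returns the two chi-squared(1) quantiles used
#'   by the rule, `c(add = qchisq(.95, 1), remove = qchisq(.99, 1))`.
#' @export
lrt_thresholds <- function() {
  c(add = qchisq(0.95, df = 1), remove = qchisq(0.99, df = 1))
}

#' Model-comparison table
#'
#' Assembles fitted models into the usual development table: -2LL, AIC, BIC
#' and number of estimated parameters per candidate, ordered as given.
#'
#' @param fits Named list of `pk_fit` / `pk_nlme_fit` objects; names are the
#'   model ids.
#' @param descriptions Optional character vector of model descriptions.
#' @return A tibble with columns `model`, `description`, `neg2LL`, `AIC`,
#'   `BIC`, `n_params`, `n_obs`, `converged`.
#' @export
compare_models <- function(fits, descriptions = NULL) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    abort("`fits` must be a fully named list.", class = "fmnpk_validation_error")
  }
  if (is.null(descriptions)) descriptions <- names(fits)
  purrr::map2_dfr(fits, descriptions, function(f, d) {
    tibble(description = d, neg2LL = f$neg2ll, AIC = f$aic, BIC = f$bic,
           n_params = f$n_params, n_obs = f$n_obs, converged = f$converged)
  }, .id = "model")
}

#' Subject-resampling bootstrap confidence intervals
#'
#' Generates `B` bootstrap datasets by resampling subjects with replacement
#' (keeping the original subject count — the subject is the exchangeable
#' unit), refits the model on each starting from the original estimates, and
#' summarises every estimated parameter by its median and 2.5%/97.5%
#' percentiles over the converged replicates. Replicates that fail to
#' converge are dropped and counted, not retried. The whole procedure is a
#' pure function of `(data, fit, B, seed)`.
#'
#' @param fit A `pk_fit` from [fit_pk_pooled()] (the refit reuses its error
#'   model, fixed-parameter set and estimates as starting values).
#' @param B Number of bootstrap replicates (study default 1000; desk-scale
#'   runs use ~200).
#' @param seed Integer seed controlling the resampling.
#' @return A `pk_bootstrap` tibble with columns `term`, `median`,
#'   `ci_lower`, `ci_upper`; attributes `B`, `n_failed`, `seed`.
#' @export
pk_bootstrap <- function(fit, B = 1000, seed = 1) {
  if (B < 1) abort("`B` must be >= 1.", class = "fmnpk_validation_error")
  data <- fit$data
  ids <- unique(data$ID)
  n <- length(ids)
  set.seed(as.integer(seed))
  draws <- matrix(sample(ids, n * B, replace = TRUE), nrow = n)

  start_hat <- do.call(pk_params, as.list(
    fit$estimates[c(STRUCTURAL_NAMES, "tlag")]))
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    pieces <- purrr::imap(draws[, b], function(id, k) {
      rows <- data[data$ID == id, ]
      rows$ID <- paste0("bs", k)
      rows
    })
    bdata <- as_pk_dataset(dplyr::bind_rows(pieces), lloq = attr(data, "lloq"))
    refit <- tryCatch(
      fit_pk_pooled(bdata, error = fit$error, start = start_hat,
                    fixed = fit$fixed),
      error = function(e) NULL)
    if (is.null(refit) || !refit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[b]] <- refit$estimates[fit$free]
  }
  kept <- purrr::compact(reps)
  if (length(kept) == 0) {
    abort("All bootstrap replicates failed to converge.",
          class = "fmnpk_numerical_error")
  }
  mat <- do.call(rbind, kept)
  out <- tibble(
    term = colnames(mat),
    median = apply(mat, 2, median),
    ci_lower = apply(mat, 2, quantile, probs = 0.025),
    ci_upper = apply(mat, 2, quantile, probs = 0.975)
  )
  structure(out, B = B, n_failed = n_failed, seed = as.integer(seed),
            class = c("pk_bootstrap", class(out)))
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("<pk_bootstrap> %d replicate(s), %d failed, seed %d\n",
              attr(x, "B"), attr(x, "n_failed"), attr(x, "seed")))
  NextMethod()
}
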