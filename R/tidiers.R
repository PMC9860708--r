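#' Tidy a fitted PK model
#'
#' One row per model parameter with its estimate, precision (CV%) and
#' whether it was held fixed; NLME fits additionally carry the IIV
#' variances as `omega2_*` terms.
#'
#' @param x A `pk_fit` or `pk_nlme_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `cv_percent`, `fixed`.
#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    cv_percent = unname(x$cv_percent[names(x$estimates)]),
    fixed = names(x$estimates) %in% x$fixed
  )
}

#' Model-level summary of a fitted PK model
#'
#' @param x A `pk_fit` or `pk_nlme_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `neg2LL`, `AIC`, `BIC`, `n_params`, `n_obs`,
#'   `converged`.
#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble(neg2LL = x$neg2ll, AIC = x$aic, BIC = x$bic,
         n_params = x$n_params, n_obs = x$n_obs, converged = x$converged)
}

#' Tidy a bootstrap result
#'
#' @param x A `pk_bootstrap`.
#' @param ... Unused.
#' @return The underlying tibble (`term`, `median`, `ci_lower`, `ci_upper`).
#' @method tidy pk_bootstrap
#' @export
tidy.pk_bootstrap <- function(x, ...) {
  as_tibble(x)
}
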