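#' Linear trapezoidal AUC
#'
#' Area under a concentration-time profile by the linear trapezoidal rule,
#' `sum (t[i+1] - t[i]) * (c[i] + c[i+1]) / 2`. A single point has zero area.
#'
#' @param times Strictly increasing sampling times, h.
#' @param conc Non-negative concentrations, nmol/L.
#' @return AUC in h*nmol/L.
#' @export
#' @examples
#' auc_linear_trapezoid(c(0, 1, 2), c(0, 10, 5))  # 12.5
auc_linear_trapezoid <- function(times, conc) {
  if (length(times) != length(conc) || length(times) < 1) {
    abort("`times` and `conc` must have equal length >= 1.",
          class = "fmnpk_validation_error")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.", class = "fmnpk_validation_error")
  }
  check_nonneg(conc, "conc")
  if (length(times) == 1) return(0)
  sum(diff(times) * (head(conc, -1) + tail(conc, -1)) / 2)
}

#' Terminal log-linear slope
#'
#' Estimates the terminal elimination rate constant `lambda_z` as minus the
#' slope of the best log-linear regression over terminal points strictly
#' after Tmax. Candidate point sets are the last 3, 4, ... up to all
#' post-Tmax positive concentrations; the set maximising the adjusted R^2 is
#' selected (ties within 1e-4 go to the larger set). Fewer than 3 usable
#' points, or a non-negative slope, leave `lambda_z` undefined (`NA`), which
#' propagates to half-life, AUCinf, Vd/F and CL/F.
#'
#' @param times Sampling times, h.
#' @param conc Concentrations, nmol/L.
#' @return A list with `lambda_z` (1/h), `n_points`, `r2_adj`.
#' @export
estimate_lambda_z <- function(times, conc) {
  undefined <- list(lambda_z = NA_real_, n_points = NA_integer_, r2_adj = NA_real_)
  keep <- is.finite(conc) & conc > 0
  times <- times[keep]; conc <- conc[keep]
  if (length(times) < 2) return(undefined)
  i_max <- which(conc == max(conc))[1]          # earliest time on ties
  cand <- seq_along(times) > i_max
  t_c <- times[cand]; c_c <- conc[cand]
  n <- length(t_c)
  if (n < 3) return(undefined)

  best <- undefined
  for (k in 3:n) {
    idx <- (n - k + 1):n
    fit <- lm(log(c_c[idx]) ~ t_c[idx])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    # noise-free profiles fit perfectly; summary.lm warns about that
    r2a <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.na(best$r2_adj) || r2a > best$r2_adj + 1e-4 ||
        (abs(r2a - best$r2_adj) <= 1e-4 && k > best$n_points)) {
      best <- list(lambda_z = -slope, n_points = as.integer(k), r2_adj = r2a)
    }
  }
  best
}

# NCA on one (times, conc) profile of quantifiable points.
nca_profile <- function(times, conc, dose_amount) {
  if (length(times) == 0) {
    abort("No quantifiable observations in profile.", class = "fmnpk_validation_error")
  }
  ord <- order(times)
  times <- times[ord]; conc <- conc[ord]
  i_max <- which(conc == max(conc))[1]
  lam <- estimate_lambda_z(times, conc)
  auc_last <- auc_linear_trapezoid(times, conc)
  c_last <- tail(conc[conc > 0], 1)
  c_last <- if (length(c_last) == 0) 0 else c_last
  auc_inf <- if (is.na(lam$lambda_z)) NA_real_ else auc_last + c_last / lam$lambda_z
  tibble(
    Cmax = conc[i_max],
    Tmax = times[i_max],
    lambda_z = lam$lambda_z,
    t_half = log(2) / lam$lambda_z,
    AUC_last = auc_last,
    AUC_inf = auc_inf,
    Vd_F = dose_amount / (lam$lambda_z * auc_inf),
    CL_F = dose_amount / auc_inf,
    n_lambda_points = lam$n_points,
    r2_adj = lam$r2_adj
  )
}

#' Non-compartmental analysis of a PK dataset
#'
#' Per subject and analyte: Cmax and Tmax from the observed points (earliest
#' time on ties), AUC to the last quantifiable point by the linear
#' trapezoidal rule, terminal slope by [estimate_lambda_z()],
#' `t1/2 = ln 2 / lambda_z`, `AUCinf = AUClast + Clast / lambda_z`,
#' `CL/F = dose / AUCinf` and `Vd/F = dose / (lambda_z * AUCinf)`.
#' Apparent clearance and volume are reported for the parent analyte only
#' (the metabolite dose is not administered). BLQ records are excluded.
#'
#' @param data A [as_pk_dataset()] tibble.
#' @return A tibble with one row per subject x analyte and the columns of
#'   the NCA parameter set; undefined terminal-phase quantities are `NA`.
#' @export
#' @examples
#' study <- simulate_pk_study(seed = 1)
#' run_nca(study$data)
run_nca <- function(data) {
  doses <- subject_doses(data)
  obs <- quantifiable(data)
  if (nrow(obs) == 0) {
    abort("Dataset has no quantifiable observations.",
          class = "fmnpk_validation_error")
  }
  tab <- pk_analytes()
  obs |>
    dplyr::mutate(analyte = tab$analyte[match(.data$DVID, tab$dvid)]) |>
    dplyr::group_by(.data$ID, .data$analyte) |>
    dplyr::group_modify(function(d, key) {
      dose <- doses$dose[doses$ID == key$ID[1]]
      res <- nca_profile(d$TIME, d$DV, dose)
      if (key$analyte != "parent") {
        res$Vd_F <- NA_real_
        res$CL_F <- NA_real_
      }
      res
    }) |>
    dplyr::ungroup()
}

#' Group summary of NCA parameters
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' NCA parameter across subjects, per analyte, ignoring undefined entries —
#' matching the usual study-report summary rows.
#'
#' @param nca A tibble from [run_nca()].
#' @return A long tibble with columns `analyte`, `parameter`, `n`, `mean`, `sd`.
#' @export
summarize_nca <- function(nca) {
  nca |>
    tidyr::pivot_longer(-c("ID", "analyte"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$analyte, .data$parameter) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value[is.finite(.data$value)]),
      sd = if (sum(is.finite(.data$value)) > 1) sd(.data$value[is.finite(.data$value)]) else NA_real_,
      .groups = "drop"
    )
}

#' Mean and sample standard deviation of a group of values
#'
#' @param values Numeric vector, `n >= 1`.
#' @return A tibble with columns `n`, `mean`, `sd` (`sd` is `NA` for n = 1).
#' @export
#' @examples
#' summarize_group(c(1195.61, 775.35, 2886.70, 876.75, 980.87))
summarize_group <- function(values) {
  if (length(values) < 1) {
    abort("`values` must be non-empty.", class = "fmnpk_validation_error")
  }
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) > 1) sd(values) else NA_real_)
}

#' Ratio of two group means
#'
#' Fold change `mean_a / mean_b`, as used to compare exposure between
#' formulation groups.
#'
#' @param mean_a,mean_b Group means; `mean_b` must be positive.
#' @return The ratio.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_b <= 0) {
    abort("`mean_b` must be positive.", class = "fmnpk_validation_error")
  }
  mean_a / mean_b
}
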