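#' Weighted calibration-curve fit
#'
#' Fits the calibration line (peak-area ratio of analyte to internal
#' standard versus nominal concentration) by weighted least squares with
#' weights `1/x^2`, the weighting that equalises relative error across a
#' wide calibration range. r^2 is computed on the weighted fit (weighted
#' residual and total sums of squares about the weighted mean).
#'
#' @param nominal Nominal concentrations, ng/mL (> 0), length >= 3.
#' @param response Peak-area response ratios.
#' @param weights Regression weights; default `1/nominal^2`.
#' @return A `pk_calibration` object with `slope`, `intercept`, `r_squared`,
#'   `weighting`, `n`.
#' @export
#' @examples
#' x <- c(2, 5, 10, 50, 100, 200)
#' fit_calibration_wls(x, 0.053 * x + 0.051)
fit_calibration_wls <- function(nominal, response, weights = 1 / nominal^2) {
  if (length(nominal) != length(response) || length(nominal) < 3) {
    abort("Need >= 3 calibration points of equal length.",
          class = "fmnpk_validation_error")
  }
  if (any(nominal <= 0)) {
    abort("`nominal` concentrations must be positive.",
          class = "fmnpk_validation_error")
  }
  fit <- lm(response ~ nominal, weights = weights)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    weighting = if (identical(weights, 1 / nominal^2)) "1/x^2" else "custom",
    n = length(nominal)
  ), class = "pk_calibration")
}

#' @export
print.pk_calibration <- function(x, ...) {
  cat(sprintf("<pk_calibration> y = %.4g x + %.4g (r^2 = %.4f, %d levels, weights %s)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$weighting))
  invisible(x)
}

#' Back-calculate concentration from a calibration curve
#'
#' @param curve A `pk_calibration`.
#' @param response Response ratio(s).
#' @return Concentration(s), ng/mL.
#' @export
back_calculate <- function(curve, response) {
  (response - curve$intercept) / curve$slope
}

#' Accuracy of a measured concentration
#'
#' `100 * measured / nominal`, the relative-recovery convention of
#' bioanalytical method validation.
#'
#' @param measured Measured (back-calculated) concentration, ng/mL.
#' @param nominal Nominal concentration, ng/mL (> 0).
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy_percent(166.67, 160)  # 104.17
accuracy_percent <- function(measured, nominal) {
  if (any(nominal <= 0)) {
    abort("`nominal` must be positive.", class = "fmnpk_validation_error")
  }
  100 * measured / nominal
}

#' Precision as percent coefficient of variation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values Replicate measurements, `n >= 2`, non-zero mean.
#' @return CV in percent.
#' @export
precision_cv <- function(values) {
  if (length(values) < 2) {
    abort("`values` must have n >= 2.", class = "fmnpk_validation_error")
  }
  m <- mean(values)
  if (m == 0) {
    abort("Mean of `values` is zero; CV undefined.",
          class = "fmnpk_validation_error")
  }
  100 * sd(values) / m
}

#' QC accuracy/precision table
#'
#' Summarises replicate QC measurements per compound and nominal level into
#' the standard validation-table cells: mean measured concentration,
#' precision (%CV) and accuracy (%).
#'
#' @param data Tibble with columns `compound`, `nominal` (ng/mL) and
#'   `measured` (ng/mL), one row per replicate.
#' @return Tibble with one row per compound x level.
#' @export
qc_table <- function(data) {
  data |>
    dplyr::group_by(.data$compound, .data$nominal) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_measured = mean(.data$measured),
      precision_cv = precision_cv(.data$measured),
      accuracy = accuracy_percent(mean(.data$measured), .data$nominal[1]),
      .groups = "drop"
    )
}

#' Plasma protein binding from an ultrafiltration assay
#'
#' `binding % = 100 * (C_total - C_UF) / C_total`, where `C_total` is the
#' concentration in the plasma reservoir and `C_UF` the free concentration
#' in the ultrafiltrate. An ultrafiltrate concentration above total is
#' physically inconsistent (nonspecific-binding artefacts); it is reported
#' as negative binding with a warning rather than silently clipped.
#'
#' @param c_total Total plasma concentration, ng/mL (> 0).
#' @param c_uf Ultrafiltrate concentration, ng/mL (>= 0).
#' @return Binding in percent.
#' @export
#' @examples
#' protein_binding_percent(100, 11.56)  # 88.44
protein_binding_percent <- function(c_total, c_uf) {
  if (any(c_total <= 0)) {
    abort("`c_total` must be positive.", class = "fmnpk_validation_error")
  }
  if (any(c_uf < 0)) {
    abort("`c_uf` must be non-negative.", class = "fmnpk_validation_error")
  }
  if (any(c_uf > c_total)) {
    warn("`c_uf` exceeds `c_total` for some samples; negative binding reported.")
  }
  100 * (c_total - c_uf) / c_total
}

#' Protein-binding summary table
#'
#' Per compound and concentration level: mean binding percent, SD and
#' replicate count, the layout of a standard binding-assay report.
#'
#' @param data Tibble with columns `compound`, `nominal` (ng/mL), `c_total`,
#'   `c_uf`, one row per replicate.
#' @return Summary tibble.
#' @export
binding_summary <- function(data) {
  data |>
    dplyr::mutate(binding = protein_binding_percent(.data$c_total, .data$c_uf)) |>
    dplyr::group_by(.data$compound, .data$nominal) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_binding = mean(.data$binding),
      sd_binding = if (dplyr::n() > 1) sd(.data$binding) else NA_real_,
      .groups = "drop"
    )
}
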