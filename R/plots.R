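#' Concentration-time plot of a PK dataset
#'
#' Semi-log spaghetti plot of the quantifiable observations, one line per
#' subject, faceted by analyte. BLQ records are omitted.
#'
#' @param data A [as_pk_dataset()] tibble.
#' @param log_y Plot concentration on a log axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_concentration_time <- function(data, log_y = TRUE) {
  obs <- quantifiable(data)
  obs$analyte <- factor(c("parent (FMN)", "metabolite (DZN)")[obs$DVID],
                        levels = c("parent (FMN)", "metabolite (DZN)"))
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$TIME, y = .data$DV,
                                         group = .data$ID, colour = .data$ID)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (nmol/L)", colour = "Subject") +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Goodness-of-fit plots for a fitted model
#'
#' `type = "obs_pred"` draws observed versus predicted concentrations with
#' the identity line; `type = "residuals"` draws standardized residuals
#' versus predictions with a zero reference. Both facet by analyte.
#'
#' @param object A `pk_fit` or `pk_nlme_fit`.
#' @param type `"obs_pred"` or `"residuals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, type = c("obs_pred", "residuals"), ...) {
  type <- match.arg(type)
  d <- predict(object)
  d$analyte <- factor(c("parent (FMN)", "metabolite (DZN)")[d$DVID],
                      levels = c("parent (FMN)", "metabolite (DZN)"))
  if (type == "obs_pred") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$f, y = .data$DV)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free") +
      ggplot2::labs(x = "Predicted (nmol/L)", y = "Observed (nmol/L)") +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$f, y = .data$residual_std)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_x") +
      ggplot2::labs(x = "Predicted (nmol/L)", y = "Standardized residual") +
      ggplot2::theme_bw()
  }
}

#' Simulated-study overlay plot
#'
#' The noise-free generating curves overlaid on the simulated observations.
#'
#' @param object A `pk_simulated_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pk_simulated_study
#' @export
autoplot.pk_simulated_study <- function(object, ...) {
  doses <- subject_doses(object$data)
  tt <- seq(0, max(object$design$schedule), length.out = 200)[-1]
  curve <- pk_simulate(object$truth, mean(doses$dose), tt) |>
    tidyr::pivot_longer(-"time", names_to = "analyte", values_to = "conc") |>
    dplyr::mutate(analyte = ifelse(.data$analyte == "conc_parent",
                                   "parent (FMN)", "metabolite (DZN)"),
                  analyte = factor(.data$analyte,
                                   levels = c("parent (FMN)", "metabolite (DZN)")))
  plot_concentration_time(object$data) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$time, y = .data$conc),
                       inherit.aes = FALSE, linewidth = 0.8, colour = "black")
}
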