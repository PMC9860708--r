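#' Run the full analysis workflow
#'
#' Wires the pipeline end to end the way the study analysis proceeds:
#' simulate (or accept) a dataset, run NCA, fit the candidate residual-error
#' models by pooled maximum likelihood, assemble the model-comparison table,
#' keep the configured final model and bootstrap its parameters. Every
#' random draw is governed by `config$seed`, so outputs are a pure function
#' of `(data, config)`.
#'
#' @param config A [pk_config()].
#' @param data Optional [as_pk_dataset()] tibble; when `NULL` and
#'   `"simulate"` is among the stages, a dataset is simulated from the
#'   config truth.
#' @param out_dir Optional directory; when given, each produced table is
#'   also written there as CSV (`dataset.csv`, `nca.csv`, `nca_summary.csv`,
#'   `model_comparison.csv`, `final_fit.csv`, `bootstrap.csv`).
#' @param error_kinds Residual-error kinds fitted in the comparison stage.
#' @return A `pk_workflow` list with elements `data`, `nca`, `nca_summary`,
#'   `comparison`, `fits`, `final_fit`, `bootstrap`, `config`, `paths`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pk_config(seed = 7, n_boot = 10)
#' wf <- run_pk_workflow(cfg)
#' wf$comparison
#' }
run_pk_workflow <- function(config = pk_config(), data = NULL, out_dir = NULL,
                            error_kinds = c("proportional", "additive",
                                            "log_additive")) {
  stages <- config$stages
  paths <- character()
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, paste0(name, ".csv"))
      readr::write_csv(as_tibble(tbl), p, progress = FALSE)
      paths[[name]] <<- p
    }
  }

  if (is.null(data)) {
    if (!"simulate" %in% stages) {
      abort("No dataset supplied and \"simulate\" is not among the stages.",
            class = "fmnpk_validation_error")
    }
    study <- simulate_pk_study(
      n_subjects = config$n_subjects, dose_mg_per_kg = config$dose_mg_per_kg,
      body_weight_kg = config$body_weight_kg, schedule = config$schedule,
      truth = do.call(pk_params, config$truth), iiv = config$iiv,
      error = error_model(config$error_kind, config$sigma),
      lloq_ngml = config$lloq_ngml, seed = config$seed)
    data <- study$data
  }
  emit(data, "dataset")
  out <- list(data = data, config = config, paths = NULL)
  if (identical(stages, "simulate")) {
    out$paths <- paths
    return(structure(out, class = "pk_workflow"))
  }

  if ("nca" %in% stages) {
    out$nca <- run_nca(data)
    out$nca_summary <- summarize_nca(out$nca)
    emit(out$nca, "nca")
    emit(out$nca_summary, "nca_summary")
  }

  if (any(c("fit", "compare", "bootstrap") %in% stages)) {
    start <- do.call(pk_params, config$init)
    sigma_start <- config$sigma
    fits <- list()
    for (kind in error_kinds) {
      sig <- if (kind == "additive_plus_proportional") {
        c(prop_parent = unname(sigma_start["parent"]),
          add_parent = 1, prop_metabolite = unname(sigma_start["metabolite"]),
          add_metabolite = 1)
      } else sigma_start
      fits[[kind]] <- tryCatch(
        fit_pk_pooled(data, error = error_model(kind, sig), start = start,
                      fixed = config$fixed),
        error = function(e) NULL)
    }
    fits <- purrr::compact(fits)
    if (length(fits) == 0) {
      abort("Workflow stage 'fit' failed: no candidate model could be fitted.",
            class = "fmnpk_numerical_error")
    }
    out$fits <- fits
    if ("compare" %in% stages) {
      out$comparison <- compare_models(
        fits, descriptions = paste(names(fits), "residual error"))
      emit(out$comparison, "model_comparison")
    }
    final_kind <- if (config$error_kind %in% names(fits)) config$error_kind
                  else names(fits)[1]
    out$final_fit <- fits[[final_kind]]
    emit(tidy(out$final_fit), "final_fit")

    if ("bootstrap" %in% stages) {
      out$bootstrap <- pk_bootstrap(out$final_fit, B = config$n_boot,
                                    seed = config$seed)
      emit(out$bootstrap, "bootstrap")
    }
  }
  out$paths <- paths
  structure(out, class = "pk_workflow")
}

#' @export
print.pk_workflow <- function(x, ...) {
  cat("<pk_workflow>\n")
  cat("  stages run:", paste(x$config$stages, collapse = ", "), "\n")
  if (!is.null(x$final_fit)) {
    cat(sprintf("  final model: %s error, -2LL %.2f\n",
                x$final_fit$error$kind, x$final_fit$neg2ll))
  }
  if (length(x$paths) > 0) {
    cat("  artifacts:", paste(unlist(x$paths), collapse = ", "), "\n")
  }
  invisible(x)
}
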