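#' Run configuration
#'
#' A run configuration bundles everything a reproducible analysis run needs:
#' the study design used when simulating, the error-model and IIV choices,
#' starting values and the fixed-parameter set for estimation, the seed and
#' the bootstrap replicate count. Configurations round-trip through JSON via
#' [read_pk_config()] / [write_pk_config()].
#'
#' @param seed Integer seed for every random draw of the run.
#' @param n_subjects,dose_mg_per_kg,body_weight_kg,schedule,lloq_ngml Study
#'   design, see [simulate_pk_study()].
#' @param truth Named list/vector of generating structural parameters
#'   (defaults to the published final-model estimates).
#' @param iiv Named non-negative numeric of IIV variances for simulation.
#' @param error_kind Residual error-model kind, see [error_model()].
#' @param sigma Named residual sigmas (generator truth and fit start).
#' @param init Named list of structural starting values for estimation.
#' @param fixed Parameters held fixed during estimation.
#' @param n_boot Bootstrap replicate count.
#' @param stages Which workflow stages to run, in order; a subset of
#'   `c("simulate", "nca", "fit", "compare", "bootstrap")`.
#' @return A `pk_config` list.
#' @export
pk_config <- function(seed = 1,
                      n_subjects = 5,
                      dose_mg_per_kg = 20,
                      body_weight_kg = 0.2217,
                      schedule = c(0.08, 0.16, 0.33, 0.5, 1, 2, 4, 8, 12, 24),
                      lloq_ngml = 2,
                      truth = unclass(fmn_reference_params()),
                      iiv = c(),
                      error_kind = "proportional",
                      sigma = c(parent = 0.2, metabolite = 0.2),
                      init = unclass(fmn_reference_params()),
                      fixed = c("F", "Fm", "tlag"),
                      n_boot = 200,
                      stages = c("simulate", "nca", "fit", "compare", "bootstrap")) {
  if (length(seed) != 1 || !is.finite(seed) || seed != as.integer(seed)) {
    abort("`seed` must be a single integer.", class = "fmnpk_validation_error")
  }
  for (nm in c("truth", "init")) {
    v <- get(nm)
    if (anyDuplicated(names(v)) > 0) {
      abort(paste0("Duplicate parameter names in `", nm, "`."),
            class = "fmnpk_validation_error")
    }
  }
  if (anyDuplicated(names(sigma)) > 0 || anyDuplicated(names(iiv)) > 0) {
    abort("Duplicate names in `sigma` or `iiv`.", class = "fmnpk_validation_error")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(
    seed = as.integer(seed), n_subjects = n_subjects,
    dose_mg_per_kg = dose_mg_per_kg, body_weight_kg = body_weight_kg,
    schedule = schedule, lloq_ngml = lloq_ngml,
    truth = as.list(truth), iiv = unlist(iiv),
    error_kind = error_kind, sigma = unlist(sigma),
    init = as.list(init), fixed = fixed, n_boot = n_boot, stages = stages
  ), class = "pk_config")
}

#' Read or write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pk_config()` returns a validated [pk_config()];
#'   `write_pk_config()` returns `path` invisibly.
#' @export
read_pk_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(
                    paste0("Failed to parse config JSON: ", conditionMessage(e)),
                    class = "fmnpk_format_error"))
  known <- names(formals(pk_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "fmnpk_format_error")
  }
  do.call(pk_config, raw)
}

#' @param config A [pk_config()].
#' @rdname read_pk_config
#' @export
write_pk_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
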