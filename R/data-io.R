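#' Construct a validated PK dataset
#'
#' A PK dataset is a tibble with one row per dosing or observation record,
#' in the conventional population-PK column layout:
#'
#' * `ID` — subject identifier (unique per animal)
#' * `TIME` — time after first dose, h
#' * `DVID` — observation type: 1 = parent (FMN), 2 = metabolite (DZN); 0 on
#'   dose rows
#' * `DV` — observed concentration, nmol/L (0 on dose rows); BLQ rows carry
#'   the LLOQ, not a measured value
#' * `BLQ` — 1 if the observation is below the lower limit of quantification
#' * `AMT` — dose amount in nmol on dose rows, 0 otherwise
#' * `BW` — body weight, kg (constant within subject)
#'
#' `as_pk_dataset()` validates the layout and the invariants (non-negative
#' times and concentrations, consistent body weight within subject, sorted
#' observation times within analyte) and attaches the per-analyte LLOQ in
#' nmol/L as an attribute.
#'
#' @param data A data frame in the layout above.
#' @param lloq Named numeric, lower limit of quantification in nmol/L for
#'   `parent` and `metabolite`. Default: 2 ng/mL converted per analyte.
#' @return A `pk_dataset` tibble.
#' @export
as_pk_dataset <- function(data, lloq = default_lloq()) {
  required <- c("ID", "TIME", "DVID", "DV", "BLQ", "AMT", "BW")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("Dataset is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "fmnpk_format_error")
  }
  data <- as_tibble(data)[required]
  if (!is.numeric(lloq) || length(lloq) != 2 ||
      !setequal(names(lloq), c("parent", "metabolite")) || any(lloq <= 0)) {
    abort("`lloq` must be a positive named numeric with entries 'parent' and 'metabolite'.",
          class = "fmnpk_validation_error")
  }

  bad_time <- which(!is.finite(data$TIME) | data$TIME < 0)
  if (length(bad_time) > 0) {
    abort(paste0("Negative or non-finite TIME at row(s): ",
                 paste(head(bad_time, 5), collapse = ", ")),
          class = "fmnpk_validation_error")
  }
  obs <- data$AMT == 0
  bad_dv <- which(obs & (!is.finite(data$DV) | data$DV < 0))
  if (length(bad_dv) > 0) {
    abort(paste0("Negative or non-finite DV at row(s): ",
                 paste(head(bad_dv, 5), collapse = ", ")),
          class = "fmnpk_validation_error")
  }
  if (!all(data$DVID[obs] %in% c(1L, 2L))) {
    abort("Observation rows must have DVID 1 (parent) or 2 (metabolite).",
          class = "fmnpk_validation_error")
  }
  if (!all(data$BLQ %in% c(0L, 1L))) {
    abort("BLQ must be 0 or 1.", class = "fmnpk_validation_error")
  }
  if (any(data$BW <= 0)) {
    abort("Body weight must be positive.", class = "fmnpk_validation_error")
  }

  bw_per_id <- dplyr::summarise(dplyr::group_by(data, .data$ID),
                                n_bw = dplyr::n_distinct(.data$BW))
  conflict <- bw_per_id$ID[bw_per_id$n_bw > 1]
  if (length(conflict) > 0) {
    abort(paste0("Conflicting body weights within subject id(s): ",
                 paste(conflict, collapse = ", ")),
          class = "fmnpk_validation_error")
  }

  data <- dplyr::arrange(data, .data$ID, .data$DVID, .data$TIME)
  structure(data,
            lloq = lloq[c("parent", "metabolite")],
            class = c("pk_dataset", class(as_tibble(data))))
}

default_lloq <- function(lloq_ngml = 2) {
  c(parent = ngml_to_nmoll(lloq_ngml, "parent"),
    metabolite = ngml_to_nmoll(lloq_ngml, "metabolite"))
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_sub <- dplyr::n_distinct(x$ID)
  n_obs <- sum(x$AMT == 0)
  cat(sprintf("<pk_dataset> %d subject(s), %d observation row(s)\n", n_sub, n_obs))
  cat(sprintf("  LLOQ: parent %.3f, metabolite %.3f nmol/L\n",
              attr(x, "lloq")[["parent"]], attr(x, "lloq")[["metabolite"]]))
  NextMethod()
}

#' Read and write PK dataset CSV files
#'
#' The on-disk format is a comma-delimited UTF-8 CSV with '.' decimal
#' separator and the required header `ID,TIME,DVID,DV,BLQ,AMT,BW` (see
#' [as_pk_dataset()] for column semantics). Writing and re-reading a dataset
#' preserves every field.
#'
#' @param path File path.
#' @param lloq Per-analyte LLOQ in nmol/L, as in [as_pk_dataset()].
#' @return `read_pk_dataset()` returns a validated `pk_dataset`;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path, lloq = default_lloq()) {
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      ID = readr::col_character(),
                      TIME = readr::col_double(),
                      DVID = readr::col_integer(),
                      DV = readr::col_double(),
                      BLQ = readr::col_integer(),
                      AMT = readr::col_double(),
                      BW = readr::col_double()
                    )),
    error = function(e) abort(paste0("Failed to read dataset CSV: ", conditionMessage(e)),
                              class = "fmnpk_format_error")
  )
  if (nrow(readr::problems(data)) > 0) {
    abort("Dataset CSV has malformed cells (see readr::problems()).",
          class = "fmnpk_format_error")
  }
  as_pk_dataset(data, lloq = lloq)
}

#' @param data A `pk_dataset` (or compatible data frame).
#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

# Observation rows above the LLOQ, the records that enter NCA and estimation.
quantifiable <- function(data) {
  dplyr::filter(as_tibble(data), .data$AMT == 0, .data$BLQ == 0)
}

# One row per subject: id, body weight, total administered amount (nmol).
subject_doses <- function(data) {
  data |>
    as_tibble() |>
    dplyr::group_by(.data$ID) |>
    dplyr::summarise(BW = .data$BW[1], dose = sum(.data$AMT), .groups = "drop")
}
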