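#' Analytes quantified in the study
#'
#' The study follows two analytes in rat plasma after a single oral dose of
#' formononetin: the parent compound itself (FMN) and its principal metabolite
#' daidzein (DZN). Concentrations are handled internally in molar units
#' (nmol/L) so that the 1:1 stoichiometry of the metabolic conversion gives a
#' clean mass balance; molecular weights are the standard chemical constants.
#'
#' @format A tibble with one row per analyte and columns
#'   \describe{
#'     \item{analyte}{`"parent"` or `"metabolite"`}
#'     \item{compound}{compound name}
#'     \item{dvid}{integer observation code used in dataset files (1 = parent,
#'       2 = metabolite)}
#'     \item{mw}{molecular weight, g/mol}
#'   }
#' @export
#' @examples
#' pk_analytes()
pk_analytes <- function() {
  tibble::tibble(
    analyte  = c("parent", "metabolite"),
    compound = c("formononetin", "daidzein"),
    dvid     = c(1L, 2L),
    mw       = c(268.26, 254.24)
  )
}

# Resolve user-supplied analyte labels ("parent", "metabolite", compound
# names, or the FMN/DZN shorthand) to the canonical label.
match_analyte <- function(analyte) {
  lut <- c(
    parent = "parent", metabolite = "metabolite",
    formononetin = "parent", daidzein = "metabolite",
    fmn = "parent", dzn = "metabolite"
  )
  key <- lut[tolower(as.character(analyte))]
  if (anyNA(key)) {
    bad <- unique(analyte[is.na(key)])
    abort(
      paste0("Unknown analyte: ", paste(bad, collapse = ", "),
             ". Expected \"parent\" (FMN) or \"metabolite\" (DZN)."),
      class = "fmnpk_validation_error"
    )
  }
  unname(key)
}

#' Molecular weight of an analyte
#'
#' @param analyte Character vector; `"parent"`/`"FMN"` or
#'   `"metabolite"`/`"DZN"` (case-insensitive).
#' @return Molecular weight(s) in g/mol.
#' @export
analyte_mw <- function(analyte) {
  tab <- pk_analytes()
  tab$mw[match(match_analyte(analyte), tab$analyte)]
}

#' Convert concentrations between ng/mL and nmol/L
#'
#' Bioanalytical calibration is carried out in mass units (ng/mL) while all
#' pharmacokinetic work is molar (nmol/L). The two conversions are exact
#' inverses: `nmol/L = ng/mL * 1000 / MW`.
#'
#' @param x Concentration vector (non-negative).
#' @param analyte Analyte label, see [analyte_mw()].
#' @return Converted concentration vector.
#' @export
#' @examples
#' ngml_to_nmoll(2, "parent")     # LLOQ of 2 ng/mL in molar units
#' nmoll_to_ngml(7.455, "FMN")
ngml_to_nmoll <- function(x, analyte) {
  check_nonneg(x, "x")
  x * 1000 / analyte_mw(analyte)
}

#' @rdname ngml_to_nmoll
#' @export
nmoll_to_ngml <- function(x, analyte) {
  check_nonneg(x, "x")
  x * analyte_mw(analyte) / 1000
}

#' Convert a weight-normalised dose to a molar amount
#'
#' Doses are administered per kilogram of body weight (mg/kg); the model and
#' the NCA work with molar amounts, so
#' `nmol = mg/kg * kg * 1e6 / MW`.
#'
#' @param dose_mg_per_kg Dose in mg per kg body weight (> 0).
#' @param body_weight_kg Body weight in kg (> 0).
#' @param analyte Analyte label giving the molecular weight.
#' @return Dose amount in nmol.
#' @export
#' @examples
#' dose_in_nmol(20, 0.2217, "parent")  # ~16,529 nmol
dose_in_nmol <- function(dose_mg_per_kg, body_weight_kg, analyte = "parent") {
  if (any(!is.finite(dose_mg_per_kg)) || any(dose_mg_per_kg <= 0)) {
    abort("`dose_mg_per_kg` must be positive.", class = "fmnpk_validation_error")
  }
  if (any(!is.finite(body_weight_kg)) || any(body_weight_kg <= 0)) {
    abort("`body_weight_kg` must be positive.", class = "fmnpk_validation_error")
  }
  dose_mg_per_kg * body_weight_kg * 1e6 / analyte_mw(analyte)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(paste0("`", name, "` must be finite and non-negative."),
          class = "fmnpk_validation_error")
  }
  invisible(x)
}
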