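#' Reference LASSO coefficients for ERG-predictive phosphosites
#'
#' A published set of 13 phosphosites selected as predictive of ERG
#' transcription-factor activity in lung adenocarcinoma, with their signed
#' LASSO coefficients and (where known) the annotated upstream kinase.
#' Bundled as a worked example for sign-partitioned phosphorylation
#' scoring.
#'
#' @return tibble `protein`, `site`, `coefficient`, `kinase`, plus a
#'   canonical `site_id` column (`PROTEIN_RESIDUEPOS`).
#' @export
erg_coefficient_table <- function() {
  path <- system.file("extdata", "erg_phospho_coefficients.tsv",
                      package = "tfacts", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein = "c", site = "c", coefficient = "d", kinase = "c"),
    na = "NA", progress = FALSE)
  df$site_id <- normalize_site_id(paste0(df$protein, "_", df$site))
  df
}

#' Build a phospho model object from a coefficient table
#'
#' Wraps externally supplied site coefficients (e.g.
#' [erg_coefficient_table()]) as a fitted `tfa_phospho_model` so they can
#' be fed to [phospho_scores()].
#'
#' @param tf TF id the coefficients refer to.
#' @param coefficients named numeric vector site_id -> coefficient.
#' @return a `tfa_phospho_model` with status `"fitted"`.
#' @export
coefficient_model <- function(tf, coefficients) {
  if (length(coefficients) == 0 || is.null(names(coefficients))) {
    abort("coefficient_model: need a named, non-empty coefficient vector")
  }
  names(coefficients) <- normalize_site_id(names(coefficients))
  structure(
    list(tf = tf, status = "fitted", selected = coefficients[coefficients != 0],
         lambda_chosen = NA_real_, eligible_sites = names(coefficients),
         split = NULL, r2_test = NA_real_, seed = NA_integer_,
         lambda_rule = NA_character_, standardize = NA),
    class = "tfa_phospho_model")
}
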