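#' Published BCR-ABL inhibitor prediction tables
#'
#' Curated training (21 compounds) and test (38 compounds) tables for a
#' quantitative BCR-ABL pharmacophore model: experimental IC50 (micromolar),
#' model-predicted IC50, fit value, signed error factor, and the three-level
#' activity scales.  These tables are the desk-scale reference against which
#' the package's quantitative layer (calibration, prediction, error factors,
#' scales, correlation) is checked.
#'
#' @param which `"training"` or `"test"`.
#' @return Tibble with columns `compound`, `exp_ic50`, `pred_ic50`, `fit`,
#'   `error`, `exp_scale`, `pred_scale`.
#' @export
bcrabl_reference_table <- function(which = c("training", "test")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("bcrabl_%s_predictions.csv", which),
                      package = "pharmscreen")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(compound = "character")))
}
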