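#' Published seven-predictor tolerance model
#'
#' The unstandardized coefficients of the published multiple-regression
#' model predicting the comprehensive salt-tolerance score from seven
#' seedling traits: Y = 0.6895 - 0.0012 SNC + 0.1242 RNIL + 0.0057 RWC +
#' 0.0516 RGR - 0.0023 RKC - 0.0202 Sen - 0.0010 RNC (reported R^2 =
#' 0.962). Shipped as a plain-text fixture so predictions can be verified
#' against the published verification panel.
#'
#' @return A [tolerance_model()] whose diagnostics carry the published
#'   coefficient table.
#' @export
reference_tolerance_model <- function() {
  path <- system.file("extdata", "tolerance_model_coefficients.csv",
                      package = "salttol", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  const <- tab$B[tab$term == "(Constant)"]
  co <- stats::setNames(tab$B[tab$term != "(Constant)"],
                        tab$term[tab$term != "(Constant)"])
  tolerance_model(const, co,
                  diagnostics = list(r_squared = 0.962,
                                     coefficient_table = tab))
}

#' Published 15-genotype verification panel
#'
#' Three genotypes per tolerance grade with the seven predictor trait
#' values, the comprehensive D value, and the Y value printed for the
#' published model; used to verify [predict_tolerance()].
#'
#' @return Data frame with columns `category`, `genotype_id`, the seven
#'   predictors, `D` and `Y`.
#' @export
verification_panel <- function() {
  path <- system.file("extdata", "verification_panel.csv",
                      package = "salttol", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Published core-representativeness reference table
#'
#' Per-trait representativeness metrics reported for the published
#' 64-of-318 mini-core collection: CR%, VR%, VD%, MD%, Shannon-Weaver
#' indices of the core and entire sets, and p-values of the distribution
#' comparisons. Used to verify the package's metric definitions (in
#' particular the VD = (VR - 100)/VR x 100 identity) and the summary
#' arithmetic.
#'
#' @return Data frame, one row per trait.
#' @export
core_validation_reference <- function() {
  path <- system.file("extdata", "core_validation_reference.csv",
                      package = "salttol", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}
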