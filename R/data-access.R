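#' Published cancer-type-specific classifier islands
#'
#' The CpG islands selected as consensus cancer-type classifiers in the
#' multi-cancer plasma study this package's pipeline follows, with their
#' printed sizes, model coefficients, gene annotation and genomic
#' location class. Useful as a real-coordinate fixture for the interval
#' arithmetic and as an example marker panel.
#'
#' @return Data frame with columns `region`, `size_bp`, `coefficient`,
#'   `gene`, `location`, `cancer_type`.
#' @export
classifier_islands <- function() {
  path <- system.file("extdata", "classifier_islands.tsv",
                      package = "methcap", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
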