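#' Bundled reference metric tables
#'
#' Two small reference tables ship with the package, taken from a published
#' large-scale survey of binding-site waters in homologous protein-ligand
#' crystal pairs. They serve as worked-example inputs for the ranking and
#' model-comparison logic and as internal-consistency fixtures in the test
#' suite; they are not produced by this package's own computations.
#'
#' `referenceCombinationMetrics()` returns the model-averaged metrics of all
#' 63 combinations of the six features (letters A-F: atom density, mobility,
#' temperature B-factor, atomic hydrophilicity, atomic hydrophobicity,
#' SASA). `referenceModelMetrics()` returns per-classifier metrics on the
#' full six-feature combination, including the reported average-performance
#' column.
#'
#' @return data.frame (see above).
#' @examples
#' head(referenceCombinationMetrics())
#' selectBestCombination(referenceCombinationMetrics())$winner
#' @name referenceMetrics
NULL

#' @rdname referenceMetrics
#' @export
referenceCombinationMetrics <- function() {
  utils::read.delim(system.file("extdata", "reference_combination_metrics.tsv",
                                package = "conswat"),
                    stringsAsFactors = FALSE)
}

#' @rdname referenceMetrics
#' @export
referenceModelMetrics <- function() {
  utils::read.delim(system.file("extdata", "reference_model_metrics.tsv",
                                package = "conswat"),
                    stringsAsFactors = FALSE)
}
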