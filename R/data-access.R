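#' Published predictor-vs-rubric concordance counts
#'
#' The published cross-tabulation of MitoTip-style pathogenicity
#' predictions against Yarham-style rubric classifications for 271 human
#' mt-tRNA variants, shipped as input data (the external predictor's
#' labels are an input to this pipeline, never computed by it). Rows are
#' predictor labels (including "no score"), columns rubric
#' classifications; column totals are 113 definitely / 2 probably /
#' 56 possibly / 100 neutral.
#'
#' @param path optional alternative TSV (same shape)
#' @return integer matrix with prediction rownames and classification
#'   colnames
#' @export
predictor_rubric_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "predictor_rubric_counts.tsv",
                        package = "mttrnacomp", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
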