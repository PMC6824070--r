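#' Write stage result tables deterministically
#'
#' Writes each element of `results` (a named list of data.frames) as a TSV
#' plus a machine-readable JSON mirror. Column order is preserved; rows are
#' sorted by `gene`, then `position`, then `species` (whichever of those
#' columns exist), so re-writing the same input is byte-identical.
#' Percentages should already be formatted to 2 decimals by the producing
#' stage; the decimal separator is always '.'.
#'
#' @param results named list of data.frames
#' @param out_dir output directory (created if absent)
#' @return invisible character vector of written file paths
#' @export
write_result_tables <- function(results, out_dir) {
  if (!is.list(results) || is.null(names(results)) || any(names(results) == ""))
    stop("results must be a fully named list of data.frames")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]], stringsAsFactors = FALSE)
    df <- sort_result_rows(df)
    tsv <- file.path(out_dir, paste0(nm, ".tsv"))
    jsn <- file.path(out_dir, paste0(nm, ".json"))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "")
    jsonlite::write_json(df, jsn, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, tsv, jsn)
  }
  invisible(paths)
}

sort_result_rows <- function(df) {
  keys <- intersect(c("gene", "position", "species"), names(df))
  if (length(keys) == 0L || nrow(df) < 2L) return(df)
  df[do.call(order, df[keys]), , drop = FALSE]
}

#' Format a percentage to two decimals
#' @param x numeric vector in [0, 100]
#' @return character vector like "97.78"
#' @export
format_pct <- function(x) formatC(x, format = "f", digits = 2)
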