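#' Quality-control a species alignment
#'
#' Applies the two sequence-quality filters used throughout this pipeline:
#'
#' 1. Length filter: any non-reference row whose ungapped length differs
#'    from the ungapped reference length by more than `length_tolerance`
#'    nucleotides is removed - unless `trim_policy = "trim-ends"` and the
#'    excess is entirely terminal overhang relative to the reference's
#'    first/last non-gap column, in which case the overhang is replaced by
#'    gaps, the row is kept, and its id recorded in `trimmed_ids`.
#' 2. Unknown-base filter: any remaining row with at least `max_unknown`
#'    'N' characters (counted on the retained, possibly trimmed sequence)
#'    is removed.
#'
#' The thresholds follow the strict conventions ">5" for length and
#' ">=5" for N. The reference row is never removed. Columns left all-gap
#' by removals are deleted. Both criteria are row-local, so filter order
#' cannot change the surviving id set.
#'
#' @param alignment a [species_alignment()]
#' @param length_tolerance max allowed ungapped length difference (default 5);
#'   `Inf` disables the filter
#' @param max_unknown minimum N count triggering removal (default 5);
#'   `Inf` disables the filter
#' @param trim_policy `"trim-ends"` (default) to rescue pure terminal
#'   overhangs, `"remove"` to drop every length outlier
#' @return list with `alignment` (filtered) and `report` (a `qc_report`:
#'   species_id, gene_id, n_before, n_after, removed_ids_length,
#'   removed_ids_n, trimmed_ids; counts exclude the reference row)
#' @export
apply_qc <- function(alignment, length_tolerance = 5, max_unknown = 5,
                     trim_policy = c("trim-ends", "remove")) {
  trim_policy <- match.arg(trim_policy)
  ref <- reference_seq(alignment)
  ref_len <- ungapped_length(ref)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  ref_nongap <- which(ref_chars != "-")
  first_col <- ref_nongap[1]; last_col <- ref_nongap[length(ref_nongap)]

  ids <- alignment$ids
  seqs <- alignment$seqs
  is_ref <- ids == alignment$reference_row_id
  n_before <- sum(!is_ref)

  removed_len <- character(0); trimmed <- character(0)
  for (i in which(!is_ref)) {
    diff <- abs(ungapped_length(seqs[i]) - ref_len)
    if (diff <= length_tolerance) next
    if (trim_policy == "trim-ends") {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pre <- seq_len(first_col - 1L)
      post <- if (last_col < length(chars)) (last_col + 1L):length(chars) else integer(0)
      overhang <- c(pre[chars[pre] != "-"], post[chars[post] != "-"])
      if (length(overhang)) {
        chars2 <- chars
        chars2[overhang] <- "-"
        trimmed_seq <- paste(chars2, collapse = "")
        if (abs(ungapped_length(trimmed_seq) - ref_len) <= length_tolerance) {
          seqs[i] <- trimmed_seq
          trimmed <- c(trimmed, ids[i])
          next
        }
      }
    }
    removed_len <- c(removed_len, ids[i])
  }

  keep <- !(ids %in% removed_len)
  removed_n <- character(0)
  if (is.finite(max_unknown) || max_unknown <= .Machine$integer.max) {
    for (i in which(keep & !is_ref)) {
      if (count_char(seqs[i], "N") >= max_unknown) {
        removed_n <- c(removed_n, ids[i])
        keep[i] <- FALSE
      }
    }
  }

  out <- species_alignment(alignment$species_id, alignment$gene_id,
                           ids[keep], seqs[keep], alignment$reference_row_id)
  out <- drop_allgap_columns(out)
  n_after <- n_rows(out) - 1L
  if (n_after == 0L)
    warning("QC reduced ", alignment$species_id, "/", alignment$gene_id,
            " to the reference row only")

  report <- structure(
    list(species_id = alignment$species_id, gene_id = alignment$gene_id,
         n_before = n_before, n_after = n_after,
         removed_ids_length = removed_len, removed_ids_n = removed_n,
         trimmed_ids = trimmed),
    class = "qc_report")
  stopifnot(n_after == n_before - length(removed_len) - length(removed_n))
  list(alignment = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s / %s: %d -> %d (length-removed %d, N-removed %d, trimmed %d)\n",
              x$species_id, x$gene_id, x$n_before, x$n_after,
              length(x$removed_ids_length), length(x$removed_ids_n),
              length(x$trimmed_ids)))
  invisible(x)
}

#' Tabulate QC reports per species
#'
#' @param reports list of `qc_report` objects
#' @return data.frame with columns species, gene, n_before, n_after,
#'   n_removed_length, n_removed_n, n_trimmed
#' @export
qc_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(species = r$species_id, gene = r$gene_id,
               n_before = r$n_before, n_after = r$n_after,
               n_removed_length = length(r$removed_ids_length),
               n_removed_n = length(r$removed_ids_n),
               n_trimmed = length(r$trimmed_ids),
               stringsAsFactors = FALSE)
  }))
}
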