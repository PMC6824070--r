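#' Detect polymorphic columns of a species alignment
#'
#' A column is polymorphic when at least two distinct A/C/G/T bases occur
#' among the non-reference rows and the minor-allele count (rows not
#' carrying the column's majority base) is at least `min_minor`. Gaps and
#' N do not count as alleles. The reference row is excluded throughout.
#'
#' @param alignment a QC'd [species_alignment()]
#' @param min_minor minimum minor-allele count (default 1)
#' @return increasing integer vector of 0-based column indices (possibly
#'   empty)
#' @export
polymorphic_columns <- function(alignment, min_minor = 1L) {
  rows <- nonref_seqs(alignment)
  if (length(rows) == 0L) return(integer(0))
  m <- seq_matrix(rows)
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    tab <- table(factor(m[, j], levels = DNA_BASES))
    tab <- tab[tab > 0L]
    if (length(tab) < 2L) next
    if (sum(tab) - max(tab) >= min_minor) out <- c(out, j - 1L)
  }
  out
}

#' Enumerate clades over polymorphic columns
#'
#' Groups non-reference rows by their exact base string (haplotype) over
#' the given 0-based columns, in ascending column order. Rows with a gap
#' or N at any clade-defining column cannot be assigned a fully observed
#' haplotype; they are set aside and reported, never silently dropped.
#' With an empty column set all assignable rows form a single clade.
#' Clades are sorted by descending frequency, ties broken by haplotype
#' lexicographic order.
#'
#' @param alignment a QC'd [species_alignment()]
#' @param columns integer vector of 0-based polymorphic columns
#' @param focal optional list(column = 0-based column, allele = base);
#'   the focal column must be among `columns` (unless `columns` is
#'   empty, in which case the fixed base at the focal column decides
#'   `carries_focal`)
#' @return object of class `clade_set`: `clades` (list of clade objects
#'   with haplotype, frequency, member_ids, carries_focal) and
#'   `set_aside_ids`
#' @export
enumerate_clades <- function(alignment, columns, focal = NULL) {
  columns <- sort(as.integer(columns))
  rows <- nonref_seqs(alignment)
  if (!is.null(focal)) {
    focal$column <- as.integer(focal$column)
    if (length(columns) > 0L && !focal$column %in% columns)
      stop("focal column ", focal$column, " is not a clade-defining column")
  }
  if (length(columns) == 0L) {
    hap <- rep("", length(rows))
    observed <- rep(TRUE, length(rows))
  } else {
    m <- seq_matrix(rows)[, columns + 1L, drop = FALSE]
    observed <- apply(m, 1L, function(r) all(r %in% DNA_BASES))
    hap <- apply(m, 1L, paste, collapse = "")
  }
  assign_ids <- names(rows)[observed]
  haps <- hap[observed]
  groups <- split(assign_ids, haps)
  freq <- lengths(groups)
  ord <- order(-freq, names(groups))
  groups <- groups[ord]

  focal_in_hap <- function(h, ids) {
    if (is.null(focal)) return(NA)
    if (length(columns) == 0L) {
      # no polymorphic columns: the focal base is fixed; read it off a member
      b <- substr(rows[[ids[1]]], focal$column + 1L, focal$column + 1L)
      return(identical(b, focal$allele))
    }
    k <- match(focal$column, columns)
    substr(h, k, k) == focal$allele
  }
  clades <- lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    h <- names(groups)[i]
    list(haplotype = h, frequency = length(ids), member_ids = ids,
         carries_focal = focal_in_hap(h, ids))
  })
  structure(list(clades = clades, columns = columns,
                 set_aside_ids = names(rows)[!observed],
                 species_id = alignment$species_id,
                 gene_id = alignment$gene_id),
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat(sprintf("<clade_set> %s / %s: %d clades over %d columns (%d rows set aside)\n",
              x$species_id, x$gene_id, length(x$clades), length(x$columns),
              length(x$set_aside_ids)))
  for (cl in x$clades)
    cat(sprintf("  %-12s n=%-4d%s\n",
                if (nzchar(cl$haplotype)) cl$haplotype else "(invariant)",
                cl$frequency,
                if (isTRUE(cl$carries_focal)) "  * focal" else ""))
  invisible(x)
}

#' Flatten a clade set into a data.frame
#' @param x a `clade_set`
#' @return data.frame with haplotype, frequency, carries_focal
#' @export
clade_table <- function(x) {
  data.frame(
    species = x$species_id, gene = x$gene_id,
    haplotype = vapply(x$clades, `[[`, character(1), "haplotype"),
    frequency = vapply(x$clades, `[[`, integer(1), "frequency"),
    carries_focal = vapply(x$clades, function(cl)
      isTRUE(cl$carries_focal), logical(1)),
    stringsAsFactors = FALSE)
}
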