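#' Call a catalogued variant in one species alignment
#'
#' Maps the variant to its alignment column (molecule-sense local index,
#' gap-adjusted against the reference row) and tallies the bases of every
#' non-reference row at that column. Alleles are compared on the molecule
#' sense: for reverse-sense genes both alleles are complemented together
#' by [to_molecule_position()], and alignments are stored in molecule
#' orientation.
#'
#' Status rules (n_nongap = n_sequences - count_gap):
#' * `monomorphic` - the alternate allele is carried by every non-gap row
#'   (`count_alt == n_nongap >= 1`), i.e. present ubiquitously across all
#'   sequences of the species;
#' * `polymorphic` - carried by some but not all (`0 < count_alt < n_nongap`);
#' * `absent` - `count_alt == 0`.
#'
#' Gaps at the column are excluded from the denominator; third alleles and
#' N count as `count_other` and never make the queried substitution
#' polymorphic on their own. A species with no non-gap base at the column
#' is called `absent` with a warning.
#'
#' @param alignment a QC'd [species_alignment()]
#' @param variant a [variant_record()]
#' @param gene the matching [gene_model()]
#' @return object of class `species_variant_call`: species_id, variant,
#'   column (0-based), n_sequences, count_ref, count_alt, count_other,
#'   count_gap, n_nongap, status, carrier_ids
#' @export
call_variant <- function(alignment, variant, gene) {
  if (variant$gene_id != alignment$gene_id)
    stop("variant gene '", variant$gene_id,
         "' does not match alignment gene '", alignment$gene_id, "'")
  mp <- to_molecule_position(variant, gene)
  col <- alignment_column(alignment, mp$local_index)
  rows <- nonref_seqs(alignment)
  bases <- substr(rows, col + 1L, col + 1L)
  n <- length(bases)
  count_gap <- sum(bases == "-")
  count_ref <- sum(bases == mp$molecule_ref_base)
  count_alt <- sum(bases == mp$molecule_alt_base)
  count_other <- n - count_gap - count_ref - count_alt
  n_nongap <- n - count_gap
  status <- if (count_alt == 0L) "absent"
            else if (count_alt == n_nongap) "monomorphic"
            else "polymorphic"
  if (n_nongap == 0L)
    warning("no non-gap base at column ", col, " for ",
            alignment$species_id, "/", alignment$gene_id)
  structure(
    list(species_id = alignment$species_id, variant = variant,
         column = col, n_sequences = n,
         count_ref = count_ref, count_alt = count_alt,
         count_other = count_other, count_gap = count_gap,
         n_nongap = n_nongap, status = status,
         carrier_ids = names(bases)[bases == mp$molecule_alt_base]),
    class = "species_variant_call")
}

#' @export
print.species_variant_call <- function(x, ...) {
  cat(sprintf("<call> m.%d%s>%s in %s: %s (%d/%d)\n",
              x$variant$rcrs_position, x$variant$ref_allele,
              x$variant$alt_allele, x$species_id, x$status,
              x$count_alt, x$n_nongap))
  invisible(x)
}

#' Aggregate one variant's calls across species
#'
#' A variant is listed as monomorphic for every species where its status
#' is monomorphic and as polymorphic for every species where it is
#' polymorphic; a variant can appear in both lists (for different
#' species), as in the cross-species summary tables this mirrors.
#'
#' @param calls list of `species_variant_call` objects for one variant,
#'   one per species
#' @return object of class `variant_xspecies_summary`: variant,
#'   monomorphic_species, polymorphic_species (data.frame species,
#'   count_alt, n_nongap), n_species_with_allele, display strings like
#'   "speciesX (9/94)"
#' @export
summarize_calls <- function(calls) {
  stopifnot(length(calls) >= 1L)
  sp <- vapply(calls, `[[`, character(1), "species_id")
  if (anyDuplicated(sp))
    stop("duplicate species in calls: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  key <- vapply(calls, function(cl)
    paste(cl$variant$rcrs_position, cl$variant$ref_allele,
          cl$variant$alt_allele), character(1))
  if (length(unique(key)) != 1L)
    stop("summarize_calls expects calls for a single variant")
  status <- vapply(calls, `[[`, character(1), "status")
  mono <- sort(sp[status == "monomorphic"])
  poly_idx <- which(status == "polymorphic")
  poly <- data.frame(
    species = sp[poly_idx],
    count_alt = vapply(calls[poly_idx], `[[`, integer(1), "count_alt"),
    n_nongap = vapply(calls[poly_idx], `[[`, integer(1), "n_nongap"),
    stringsAsFactors = FALSE)
  poly <- poly[order(poly$species), , drop = FALSE]
  rownames(poly) <- NULL
  structure(
    list(variant = calls[[1]]$variant,
         monomorphic_species = mono,
         polymorphic_species = poly,
         n_species_with_allele = length(mono) + nrow(poly),
         polymorphic_display =
           sprintf("%s (%d/%d)", poly$species, poly$count_alt, poly$n_nongap)),
    class = "variant_xspecies_summary")
}

#' @export
print.variant_xspecies_summary <- function(x, ...) {
  v <- x$variant
  cat(sprintf("<summary> m.%d%s>%s: monomorphic in %d species, polymorphic in %d\n",
              v$rcrs_position, v$ref_allele, v$alt_allele,
              length(x$monomorphic_species), nrow(x$polymorphic_species)))
  if (length(x$monomorphic_species))
    cat("  monomorphic:", paste(x$monomorphic_species, collapse = ", "), "\n")
  if (length(x$polymorphic_display))
    cat("  polymorphic:", paste(x$polymorphic_display, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten variant calls into a data.frame
#'
#' @param calls list of `species_variant_call` objects
#' @return data.frame, one row per call
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(gene = cl$variant$gene_id, position = cl$variant$rcrs_position,
               ref = cl$variant$ref_allele, alt = cl$variant$alt_allele,
               species = cl$species_id, column = cl$column,
               n_sequences = cl$n_sequences, count_ref = cl$count_ref,
               count_alt = cl$count_alt, count_other = cl$count_other,
               count_gap = cl$count_gap, n_nongap = cl$n_nongap,
               status = cl$status, stringsAsFactors = FALSE)
  }))
}
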