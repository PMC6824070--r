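#' Map an rCRS variant to a molecule-local position
#'
#' Converts a reference-strand (rCRS-numbered) substitution into the
#' coordinate system of the tRNA molecule itself. For genes whose molecule
#' sense equals the reference strand, the local index is
#' `pos - rcrs_start + 1` and the alleles carry over unchanged. For genes
#' encoded on the opposite strand the local index is
#' `rcrs_end - pos + 1` and both alleles are complemented (U is
#' represented as T internally), e.g. m.5650G>A in mt-tRNA-Ala is a C>T
#' (C>U) change in the molecule.
#'
#' @param variant a [variant_record()]
#' @param gene the matching [gene_model()]
#' @return list of class `molecule_position`: gene_id, local_index
#'   (1-based, 5'->3' along the molecule), molecule_ref_base,
#'   molecule_alt_base
#' @export
to_molecule_position <- function(variant, gene) {
  if (variant$gene_id != gene$gene_id)
    stop("variant gene '", variant$gene_id, "' does not match gene model '",
         gene$gene_id, "'")
  pos <- variant$rcrs_position
  if (pos < gene$rcrs_start || pos > gene$rcrs_end)
    stop("position ", pos, " outside gene span ", gene$rcrs_start, "..",
         gene$rcrs_end)
  if (gene$molecule_sense_is_reference_strand) {
    idx <- pos - gene$rcrs_start + 1L
    ref <- variant$ref_allele; alt <- variant$alt_allele
  } else {
    idx <- gene$rcrs_end - pos + 1L
    ref <- complement_base(variant$ref_allele)
    alt <- complement_base(variant$alt_allele)
  }
  structure(list(gene_id = gene$gene_id, local_index = idx,
                 molecule_ref_base = ref, molecule_alt_base = alt),
            class = "molecule_position")
}

#' Molecule-local index back to an rCRS position
#'
#' Inverse of the positional part of [to_molecule_position()].
#'
#' @param local_index 1-based molecule position
#' @param gene a [gene_model()]
#' @return 1-based rCRS position
#' @export
local_to_rcrs <- function(local_index, gene) {
  local_index <- as.integer(local_index)
  stopifnot(all(local_index >= 1L), all(local_index <= gene_length(gene)))
  if (gene$molecule_sense_is_reference_strand)
    gene$rcrs_start + local_index - 1L
  else
    gene$rcrs_end - local_index + 1L
}

#' Locate a molecule-local position in an alignment
#'
#' Returns the 0-based alignment column holding the `local_index`-th
#' non-gap character of the human reference row, i.e. adjusts the variant
#' position for gaps in the reference sequence.
#'
#' @param alignment a [species_alignment()]
#' @param local_index 1-based index along the ungapped reference row
#' @return 0-based column index
#' @export
alignment_column <- function(alignment, local_index) {
  local_index <- as.integer(local_index)
  stopifnot(length(local_index) == 1L, local_index >= 1L)
  ref <- strsplit(reference_seq(alignment), "", fixed = TRUE)[[1]]
  nongap <- which(ref != "-")
  if (length(nongap) < local_index)
    stop("reference row has only ", length(nongap),
         " non-gap characters; local index ", local_index, " requested")
  nongap[local_index] - 1L
}
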