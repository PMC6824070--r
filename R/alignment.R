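#' Species alignment container
#'
#' One species-gene multiple sequence alignment with an embedded human
#' reference (rCRS-derived) row. Sequences are stored in tRNA molecule
#' orientation, upper case, over the alphabet {A,C,G,T,N,-}.
#'
#' @param species_id species label
#' @param gene_id gene label
#' @param ids character vector of sequence identifiers (unique)
#' @param seqs character vector of aligned sequences, same length as `ids`,
#'   all of equal width
#' @param reference_row_id id of the human reference row; must occur in `ids`
#' @return an object of class `species_alignment`
#' @export
species_alignment <- function(species_id, gene_id, ids, seqs, reference_row_id) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(seqs) == 0L || any(widths < 1L))
    stop("alignment must contain at least one non-empty sequence")
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != stats::median(widths)]
    stop("ragged alignment; offending ids: ", paste(bad, collapse = ", "))
  }
  if (sum(ids == reference_row_id) != 1L)
    stop("reference row '", reference_row_id, "' not found exactly once")
  structure(
    list(species_id = as.character(species_id),
         gene_id = as.character(gene_id),
         ids = ids, seqs = seqs,
         reference_row_id = as.character(reference_row_id)),
    class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> %s / %s: %d rows x %d columns (reference: %s)\n",
              x$species_id, x$gene_id, length(x$ids), nchar(x$seqs[1]),
              x$reference_row_id))
  invisible(x)
}

#' Number of alignment rows / columns
#' @param x a `species_alignment`
#' @return integer count
#' @export
n_rows <- function(x) length(x$ids)

#' @rdname n_rows
#' @export
n_cols <- function(x) nchar(x$seqs[1])

#' Reference row sequence of an alignment
#' @param x a `species_alignment`
#' @return the aligned reference sequence string
#' @export
reference_seq <- function(x) x$seqs[x$ids == x$reference_row_id]

#' Non-reference rows of an alignment
#' @param x a `species_alignment`
#' @return named character vector of aligned sequences (names = ids)
#' @export
nonref_seqs <- function(x) {
  keep <- x$ids != x$reference_row_id
  setNames(x$seqs[keep], x$ids[keep])
}

#' Read an aligned FASTA file into a species alignment
#'
#' Gaps must be '-' ('.' is rejected). Case is normalised to upper and U
#' to T; any residual character outside {A,C,G,T,N,-} is mapped to N with
#' a warning.
#'
#' @param path path to an aligned FASTA file
#' @param reference_row_id id of the human reference row within the file
#' @param species_id,gene_id labels; defaults are parsed from a
#'   `<species>__<gene>.fasta` file name
#' @return a [species_alignment()]
#' @export
read_alignment <- function(path, reference_row_id,
                           species_id = NULL, gene_id = NULL) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("'.' gap characters are not accepted (use '-'): ", path)
  seqs <- vapply(seqs, normalize_seq, character(1), USE.NAMES = FALSE)
  odd <- vapply(seqs, function(s) length(nonstandard_chars(s)) > 0L, logical(1))
  if (any(odd)) {
    warning("mapping non-ACGTN characters to N in: ",
            paste(ids[odd], collapse = ", "))
    seqs <- vapply(seqs, function(s) {
      gsub("[^ACGTN-]", "N", s)
    }, character(1), USE.NAMES = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment in ", path, "; offending ids: ",
         paste(ids[widths != stats::median(widths)], collapse = ", "))
  if (!reference_row_id %in% ids)
    stop("reference row '", reference_row_id, "' missing from ", path)
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "__", fixed = TRUE)[[1]]
  if (is.null(species_id)) species_id <- parts[1]
  if (is.null(gene_id)) gene_id <- if (length(parts) > 1) parts[2] else base
  species_alignment(species_id, gene_id, ids, seqs, reference_row_id)
}

#' Write a species alignment as aligned FASTA
#'
#' @param x a `species_alignment`
#' @param path output path; conventionally `<species>__<gene>.fasta`
#' @return `path`, invisibly
#' @export
write_alignment <- function(x, path) {
  set <- Biostrings::BStringSet(setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# drop columns that are all-gap across every row
drop_allgap_columns <- function(x) {
  m <- seq_matrix(x$seqs)
  keep <- colSums(m != "-") > 0L
  if (all(keep)) return(x)
  seqs <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  species_alignment(x$species_id, x$gene_id, x$ids, seqs, x$reference_row_id)
}
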