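EVIDENCE_FIELDS <- c("n_independent_reports", "heteroplasmy_observed",
                     "segregates_with_phenotype", "biochemical_defect",
                     "single_fibre_evidence", "cybrid_evidence",
                     "conservation_index_pct")

NO_SCORE <- "no score"

#' Read a candidate variant table
#'
#' Reads a TSV of candidate disease-associated mt-tRNA substitutions.
#' Required columns: `position`, `ref`, `alt`, `gene`. Optional columns:
#' `disease`, the rubric evidence fields
#' (`n_independent_reports`, `heteroplasmy_observed`,
#' `segregates_with_phenotype`, `biochemical_defect`,
#' `single_fibre_evidence`, `cybrid_evidence`, `conservation_index_pct`)
#' and an external predictor label (`predictor_label`). Missing evidence
#' fields default to "unknown"; a missing predictor label becomes the
#' sentinel `"no score"`.
#'
#' Rows with `ref == alt` or a non-ACGT allele are rejected with a warning
#' and counted, never silently dropped: `nrow(input) == nrow(records) +
#' n_rejected`.
#'
#' @param path path to the TSV (header required)
#' @return list with `records` (data.frame in file order, one row per
#'   accepted variant), `n_rejected`, and `rejections` (data.frame of
#'   offending rows with a reason column)
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such variant table: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  req <- c("position", "ref", "alt", "gene")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  raw$position <- as.integer(raw$position)
  raw$ref <- toupper(chartr("U", "T", raw$ref))
  raw$alt <- toupper(chartr("U", "T", raw$alt))

  reason <- rep(NA_character_, nrow(raw))
  bad_allele <- !(raw$ref %in% DNA_BASES) | !(raw$alt %in% DNA_BASES)
  reason[bad_allele] <- "non-ACGT allele"
  same <- !bad_allele & raw$ref == raw$alt
  reason[same] <- "ref == alt"
  keep <- is.na(reason)
  if (any(!keep))
    warning(sum(!keep), " variant row(s) rejected (",
            paste(unique(reason[!keep]), collapse = "; "), ")")

  rec <- raw[keep, , drop = FALSE]
  if (!"disease" %in% names(rec)) rec$disease <- ""
  for (f in EVIDENCE_FIELDS) {
    if (!f %in% names(rec)) rec[[f]] <- "unknown"
    rec[[f]][is.na(rec[[f]]) | rec[[f]] == ""] <- "unknown"
  }
  if (!"predictor_label" %in% names(rec)) rec$predictor_label <- NO_SCORE
  rec$predictor_label[is.na(rec$predictor_label) | rec$predictor_label == ""] <- NO_SCORE
  rownames(rec) <- NULL

  rejections <- raw[!keep, req, drop = FALSE]
  if (nrow(rejections)) rejections$reason <- reason[!keep]
  else rejections$reason <- character(0)
  rownames(rejections) <- NULL

  list(records = rec, n_rejected = sum(!keep), rejections = rejections)
}

#' Construct a single variant record
#'
#' @param rcrs_position 1-based rCRS position
#' @param ref_allele,alt_allele reference-strand alleles (must differ)
#' @param gene_id gene label
#' @param disease_label free-text disease association
#' @return an object of class `variant_record`
#' @export
variant_record <- function(rcrs_position, ref_allele, alt_allele, gene_id,
                           disease_label = "") {
  ref_allele <- toupper(chartr("U", "T", ref_allele))
  alt_allele <- toupper(chartr("U", "T", alt_allele))
  if (!ref_allele %in% DNA_BASES || !alt_allele %in% DNA_BASES)
    stop("alleles must be A, C, G or T")
  if (ref_allele == alt_allele) stop("ref and alt alleles must differ")
  structure(
    list(rcrs_position = as.integer(rcrs_position),
         ref_allele = ref_allele, alt_allele = alt_allele,
         gene_id = as.character(gene_id),
         disease_label = as.character(disease_label)),
    class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant> m.%d%s>%s (%s)%s\n", x$rcrs_position, x$ref_allele,
              x$alt_allele, x$gene_id,
              if (nzchar(x$disease_label)) paste0(" - ", x$disease_label) else ""))
  invisible(x)
}

# variant_record from one row of a parsed variant table
variant_from_row <- function(row) {
  variant_record(row$position, row$ref, row$alt, row$gene,
                 if (!is.null(row$disease)) row$disease else "")
}
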