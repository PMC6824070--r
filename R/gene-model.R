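#' Gene model for a mitochondrial tRNA gene
#'
#' Describes where a gene sits on the rCRS (1-based inclusive span) and
#' whether the mature tRNA molecule reads in the same sense as the
#' reference strand. Human mt-tRNA genes on the opposite strand (e.g.
#' mt-tRNA-Ala) have `molecule_sense_is_reference_strand = FALSE`: their
#' molecule sequence is the reverse complement of the rCRS segment, and a
#' reference-strand variant such as m.5650G>A corresponds to a C>U change
#' in the molecule itself.
#'
#' @param gene_id gene label
#' @param rcrs_start,rcrs_end 1-based inclusive rCRS span (55-100 nt)
#' @param molecule_sense_is_reference_strand logical strand flag
#' @param anticodon_canonical_positions canonical anticodon triple
#'   (default 34:36)
#' @return an object of class `gene_model`
#' @export
gene_model <- function(gene_id, rcrs_start, rcrs_end,
                       molecule_sense_is_reference_strand,
                       anticodon_canonical_positions = c(34L, 35L, 36L)) {
  rcrs_start <- as.integer(rcrs_start); rcrs_end <- as.integer(rcrs_end)
  if (!(1L <= rcrs_start && rcrs_start <= rcrs_end && rcrs_end <= 16569L))
    stop("gene span must satisfy 1 <= start <= end <= 16569")
  len <- rcrs_end - rcrs_start + 1L
  if (len < 55L || len > 100L)
    stop("gene length ", len, " outside the tRNA range 55-100 nt")
  structure(
    list(gene_id = as.character(gene_id),
         rcrs_start = rcrs_start, rcrs_end = rcrs_end,
         molecule_sense_is_reference_strand =
           isTRUE(molecule_sense_is_reference_strand),
         anticodon_canonical_positions =
           as.integer(anticodon_canonical_positions)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: rCRS %d..%d (%d nt), molecule sense %s reference strand\n",
              x$gene_id, x$rcrs_start, x$rcrs_end, gene_length(x),
              if (x$molecule_sense_is_reference_strand) "==" else "!="))
  invisible(x)
}

#' Gene length in nucleotides
#' @param gene a `gene_model`
#' @return integer length
#' @export
gene_length <- function(gene) gene$rcrs_end - gene$rcrs_start + 1L

#' The 22 human mitochondrial tRNA gene models
#'
#' rCRS (NC_012920) coordinates and strand sense for all 22 human mt-tRNA
#' genes, shipped as package data (JSON under `extdata`). Eight genes
#' (Gln, Ala, Asn, Cys, Tyr, Ser1, Glu, Pro) are encoded opposite to the
#' reference strand.
#'
#' @param path optional path to an alternative gene model JSON/YAML config
#' @return named list of [gene_model()] objects keyed by gene id
#' @export
human_gene_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "human_mt_trna_genes.json",
                        package = "mttrnacomp", mustWork = TRUE)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw, function(g) {
    gene_model(g$gene_id, g$start, g$end, isTRUE(g$molecule_sense_is_reference_strand),
               if (!is.null(g$anticodon)) unlist(g$anticodon) else c(34L, 35L, 36L))
  })
  setNames(out, vapply(out, `[[`, character(1), "gene_id"))
}
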