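# in-code fixtures shared across the suite

# build a species_alignment from named sequence strings (first id that
# equals `ref` becomes the reference row)
make_aln <- function(seqs, species = "spX", gene = "gX", ref = "rCRS") {
  if (is.null(names(seqs))) names(seqs) <- c(ref, paste0("s", seq_along(seqs)[-1]))
  species_alignment(species, gene, names(seqs), unname(seqs), ref)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# random alignment: reference + n rows mutated from it at rate p
random_aln <- function(n = 10, len = 40, p = 0.1, species = "spX", gene = "gX") {
  ref <- strsplit(random_seq(len), "")[[1]]
  rows <- replicate(n, {
    r <- ref
    hit <- runif(len) < p
    r[hit] <- sample(c("A", "C", "G", "T", "-", "N"), sum(hit), replace = TRUE)
    paste(r, collapse = "")
  })
  make_aln(c(rCRS = paste(ref, collapse = ""),
             setNames(rows, sprintf("s%03d", seq_len(n)))),
           species = species, gene = gene)
}

# simple forward-sense gene model starting at rCRS position `start`
fwd_gene <- function(len = 40, gene = "gX", start = 1001L) {
  # gene_model enforces tRNA lengths; pad the span to >= 55 is not
  # possible for arbitrary len, so tests use len in 55..100
  gene_model(gene, start, start + len - 1L, TRUE)
}

rev_gene <- function(len = 40, gene = "gX", start = 1001L) {
  gene_model(gene, start, start + len - 1L, FALSE)
}

# independent linear-scan oracle: 0-based column of the k-th non-gap
# character of the reference row
column_oracle <- function(ref_row, k) {
  chars <- strsplit(ref_row, "")[[1]]
  seen <- 0L
  for (j in seq_along(chars)) {
    if (chars[j] != "-") {
      seen <- seen + 1L
      if (seen == k) return(j - 1L)
    }
  }
  stop("reference too short")
}

# independent per-column tally over raw strings
tally_oracle <- function(aln, col0, base) {
  rows <- aln$seqs[aln$ids != aln$reference_row_id]
  chars <- vapply(rows, function(s) substr(s, col0 + 1, col0 + 1), character(1))
  sum(chars == base)
}

# branch-and-bound exhaustive minimum spanning tree weight over a
# complete graph given a distance matrix (small n only)
exhaustive_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1) return(0)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], w = d[idx])
  best <- Inf
  recurse <- function(k, parent, n_used, weight) {
    if (weight >= best) return()
    if (n_used == n - 1) { best <<- min(best, weight); return() }
    if (k > nrow(edges)) return()
    # prune: not enough edges left
    if (nrow(edges) - k + 1 < (n - 1) - n_used) return()
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) {
      p2 <- parent; p2[ri] <- rj
      recurse(k + 1, p2, n_used + 1, weight + edges$w[k])
    }
    recurse(k + 1, parent, n_used, weight)
  }
  recurse(1, seq_len(n), 0, 0)
  best
}

# tiny simulated dataset helper
small_sim <- function(seed = 11, ...) {
  p <- simulation_params(n_species = 3, n_genes = 2,
                         sequences_per_species = c(12, 20), seed = seed, ...)
  d <- tempfile(paste0("sim", seed, "_"))
  truth <- simulate_dataset(p, d)
  list(dir = d, truth = truth, params = p)
}
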