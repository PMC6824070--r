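hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# all pairwise Hamming distances between haplotype strings
hamming_matrix <- function(haps) {
  n <- length(haps)
  d <- matrix(0L, n, n)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- hamming(haps[i], haps[j])
  }
  d
}

#' Build a haplotype minimum-spanning network over clades
#'
#' A reproducible stand-in for median-joining network software: Kruskal's
#' minimum spanning tree under Hamming distance between clade haplotypes
#' (ties broken by lexicographic haplotype order, so the result is
#' deterministic), plus every non-tree edge whose distance equals the
#' maximum edge weight on the tree path between its endpoints - i.e. all
#' edges belonging to some minimum spanning tree are retained.
#'
#' @param clades a `clade_set` from [enumerate_clades()], or a list of
#'   clade objects with `haplotype` fields (at least one; haplotypes
#'   pairwise distinct, equal length)
#' @return object of class `haplotype_network`: `nodes` (data.frame
#'   haplotype, frequency, carries_focal), `edges` (data.frame from, to,
#'   distance, in_mst; from/to are 1-based node indices), `connected`
#' @export
build_network <- function(clades) {
  if (inherits(clades, "clade_set")) clades <- clades$clades
  stopifnot(length(clades) >= 1L)
  haps <- vapply(clades, `[[`, character(1), "haplotype")
  if (anyDuplicated(haps)) stop("clade haplotypes must be distinct")
  n <- length(haps)
  nodes <- data.frame(
    haplotype = haps,
    frequency = vapply(clades, function(cl)
      if (!is.null(cl$frequency)) as.integer(cl$frequency) else NA_integer_,
      integer(1)),
    carries_focal = vapply(clades, function(cl)
      isTRUE(cl$carries_focal), logical(1)),
    stringsAsFactors = FALSE)

  if (n == 1L) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        distance = integer(0), in_mst = logical(0))
    return(structure(list(nodes = nodes, edges = edges, connected = TRUE),
                     class = "haplotype_network"))
  }

  d <- hamming_matrix(haps)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  cand <- data.frame(from = idx[, 1], to = idx[, 2],
                     distance = d[idx])
  # deterministic Kruskal: weight, then lexicographic haplotype order
  ord <- order(cand$distance, haps[cand$from], haps[cand$to])
  cand <- cand[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  in_mst <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ri <- find(cand$from[k]); rj <- find(cand$to[k])
    if (ri != rj) { parent[ri] <- rj; in_mst[k] <- TRUE }
  }
  tree <- cand[in_mst, , drop = FALSE]

  # max edge weight on the tree path between every pair (n is small)
  adj <- lapply(seq_len(n), function(i) {
    rows <- tree[tree$from == i | tree$to == i, , drop = FALSE]
    data.frame(nb = ifelse(rows$from == i, rows$to, rows$from),
               w = rows$distance)
  })
  path_max <- matrix(0L, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- list(list(node = s, mx = 0L))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(adj[[cur$node]]))) {
        nb <- adj[[cur$node]]$nb[r]
        if (seen[nb]) next
        seen[nb] <- TRUE
        mx <- max(cur$mx, adj[[cur$node]]$w[r])
        path_max[s, nb] <- mx
        queue[[length(queue) + 1L]] <- list(node = nb, mx = mx)
      }
    }
  }
  keep_extra <- !in_mst & cand$distance == path_max[cbind(cand$from, cand$to)]
  edges <- cand[in_mst | keep_extra, , drop = FALSE]
  edges$in_mst <- in_mst[in_mst | keep_extra]
  edges <- edges[order(edges$distance, haps[edges$from], haps[edges$to]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, connected = TRUE),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes, %d edges (%d in MST)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_mst)))
  invisible(x)
}

#' Total MST weight of a haplotype network
#' @param network a `haplotype_network`
#' @return sum of tree-edge Hamming distances
#' @export
mst_weight <- function(network) sum(network$edges$distance[network$edges$in_mst])

#' Export a haplotype network as plain text
#'
#' Writes a node table and an edge list (TSV) usable by external network
#' tools.
#'
#' @param network a `haplotype_network`
#' @param nodes_path,edges_path output TSV paths
#' @return invisible character vector of the two paths
#' @export
write_network <- function(network, nodes_path, edges_path) {
  utils::write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edges <- network$edges
  edges$from_haplotype <- network$nodes$haplotype[edges$from]
  edges$to_haplotype <- network$nodes$haplotype[edges$to]
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
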