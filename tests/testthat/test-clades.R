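test_that("invariant alignments have no polymorphic columns", {
  aln <- make_aln(c(rCRS = "ACGTACGT", s1 = "ACGTACGT", s2 = "ACGTACGT"))
  expect_identical(polymorphic_columns(aln), integer(0))
})

test_that("polymorphic columns match brute-force per-column counting", {
  set.seed(63)
  for (rep in 1:15) {
    aln <- random_aln(n = sample(5:40, 1), len = 30, p = 0.2)
    for (mm in c(1L, 2L, 5L)) {
      got <- polymorphic_columns(aln, min_minor = mm)
      rows <- aln$seqs[aln$ids != "rCRS"]
      want <- integer(0)
      for (j in seq_len(30)) {
        bases <- vapply(rows, function(s) substr(s, j, j), character(1))
        bases <- bases[bases %in% c("A", "C", "G", "T")]
        tab <- sort(table(bases), decreasing = TRUE)
        if (length(tab) >= 2 && sum(tab) - tab[1] >= mm)
          want <- c(want, j - 1L)
      }
      expect_identical(got, want)
    }
  }
})

test_that("clade enumeration groups haplotypes with deterministic ordering", {
  rows <- c(rCRS = "AAAA",
            a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",   # hap AA at cols 0,2
            b1 = "GAAA", b2 = "GAAA",                # hap GA
            c1 = "GAGA")                             # hap GG
  aln <- make_aln(rows)
  cols <- c(0L, 2L)
  cs <- enumerate_clades(aln, cols, focal = list(column = 0L, allele = "G"))
  expect_equal(vapply(cs$clades, `[[`, integer(1), "frequency"), c(3L, 2L, 1L))
  expect_equal(vapply(cs$clades, `[[`, character(1), "haplotype"),
               c("AA", "GA", "GG"))
  expect_equal(vapply(cs$clades, `[[`, logical(1), "carries_focal"),
               c(FALSE, TRUE, TRUE))
  # focal column must be clade-defining
  expect_error(enumerate_clades(aln, cols, focal = list(column = 1L, allele = "A")),
               "focal")
  # rows with gap/N at a clade column are set aside, never dropped silently
  rows2 <- c(rows, d1 = "-AAA")
  cs2 <- enumerate_clades(make_aln(rows2), cols)
  expect_identical(cs2$set_aside_ids, "d1")
  expect_equal(sum(vapply(cs2$clades, `[[`, integer(1), "frequency")), 6L)
})

test_that("no polymorphic columns yields a single clade with the fixed base", {
  aln <- make_aln(c(rCRS = "ACGT", s1 = "ACGT", s2 = "ACGT"))
  cs <- enumerate_clades(aln, integer(0), focal = list(column = 1L, allele = "C"))
  expect_length(cs$clades, 1L)
  expect_equal(cs$clades[[1]]$frequency, 2L)
  expect_true(cs$clades[[1]]$carries_focal)
})

test_that("clade grouping equals brute-force haplotype grouping on random data", {
  set.seed(67)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    aln <- random_aln(n = n, len = 25, p = 0.15)
    cols <- polymorphic_columns(aln)
    if (length(cols) == 0) next
    cs <- enumerate_clades(aln, cols)
    rows <- aln$seqs[aln$ids != "rCRS"]
    haps <- vapply(rows, function(s)
      paste(vapply(cols + 1, function(j) substr(s, j, j), character(1)),
            collapse = ""), character(1))
    ok <- !grepl("[^ACGT]", haps)
    tab <- table(haps[ok])
    expect_equal(length(cs$clades), length(tab))
    got <- setNames(vapply(cs$clades, `[[`, integer(1), "frequency"),
                    vapply(cs$clades, `[[`, character(1), "haplotype"))
    expect_equal(got[order(names(got))], c(tab[order(names(tab))]))
    expect_equal(sum(got) + length(cs$set_aside_ids), n)
    # clade count bound
    expect_lte(length(cs$clades), n)
  }
})

test_that("nine planted haplotypes with one focal carrier are recovered", {
  # sheep-lysine-like fixture: 9 distinct haplotypes over 4 columns,
  # exactly one carrying the focal allele
  set.seed(71)
  base <- strsplit(strrep("ACGT", 10), "")[[1]]
  cols <- c(5L, 12L, 20L, 30L)        # 1-based local sites
  haps <- c("AAAA", "AAAG", "AAGA", "AGAA", "GAAA", "AAGG", "AGGA", "GGAA",
            "CAAA")                    # only the last has C at site 5
  sizes <- c(30, 20, 12, 10, 8, 6, 4, 3, 1)
  rows <- list()
  for (h in seq_along(haps)) for (i in seq_len(sizes[h])) {
    r <- base
    r[cols] <- strsplit(haps[h], "")[[1]]
    rows[[sprintf("h%d_%02d", h, i)]] <- paste(r, collapse = "")
  }
  r0 <- base; r0[cols] <- c("A", "A", "A", "A")
  aln <- make_aln(c(rCRS = paste(r0, collapse = ""), unlist(rows)),
                  species = "sheep", gene = "gK")
  pc <- polymorphic_columns(aln)
  expect_setequal(pc, cols - 1L)
  cs <- enumerate_clades(aln, pc, focal = list(column = 4L, allele = "C"))
  expect_length(cs$clades, 9L)
  expect_equal(sum(vapply(cs$clades, `[[`, logical(1), "carries_focal")), 1L)
  expect_equal(cs$clades[[1]]$frequency, 30L)
})

test_that("three-haplotype chain builds the expected path network", {
  clades <- list(list(haplotype = "AA", frequency = 3),
                 list(haplotype = "AG", frequency = 2),
                 list(haplotype = "GG", frequency = 1))
  net <- build_network(clades)
  expect_equal(nrow(net$nodes), 3L)
  mstE <- net$edges[net$edges$in_mst, ]
  expect_equal(nrow(mstE), 2L)
  expect_equal(mst_weight(net), 2)
  pairs <- vapply(seq_len(nrow(mstE)), function(k)
    paste(sort(net$nodes$haplotype[c(mstE$from[k], mstE$to[k])]),
          collapse = "-"), character(1))
  expect_setequal(pairs, c("AA-AG", "AG-GG"))
  # single clade: one node, no edges
  net1 <- build_network(list(list(haplotype = "A", frequency = 5)))
  expect_equal(nrow(net1$edges), 0L)
  expect_true(net1$connected)
})

test_that("network MST weight equals exhaustive spanning-tree search (<= 8 clades)", {
  set.seed(73)
  for (n in c(3, 4, 5, 6, 7, 8)) {
    for (rep in 1:3) {
      width <- sample(4:7, 1)
      haps <- character(0)
      while (length(haps) < n)
        haps <- unique(c(haps, random_seq(width)))
      clades <- lapply(haps, function(h) list(haplotype = h, frequency = 1))
      net <- build_network(clades)
      d <- matrix(0L, n, n)
      for (i in 1:n) for (j in 1:n)
        d[i, j] <- sum(strsplit(haps[i], "")[[1]] != strsplit(haps[j], "")[[1]])
      expect_equal(mst_weight(net), exhaustive_mst_weight(d))
      # independent implementation cross-check
      gr <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                weighted = TRUE)
      expect_equal(mst_weight(net),
                   sum(igraph::E(igraph::mst(gr))$weight))
      # the network spans all nodes and includes the MST
      comp <- igraph::components(igraph::graph_from_data_frame(
        net$edges[, c("from", "to")], directed = FALSE,
        vertices = data.frame(name = seq_len(n))))
      expect_equal(comp$no, 1L)
      # every retained non-tree edge ties the cycle-maximal tree edge
      expect_true(all(net$edges$distance >= 1))
    }
  }
})

test_that("planted clade structure is recovered exactly on noise-free data", {
  sim <- small_sim(seed = 79, n_gap_columns = 0,
                   qc_noise = list(n_remove_length = 0L, n_trim_length = 0L,
                                   n_n_rich = 0L))
  for (key in names(sim$truth$clades)) {
    ct <- sim$truth$clades[[key]]
    aln <- read_alignment(file.path(sim$dir, "alignments",
                                    paste0(key, ".fasta")), "rCRS")
    cols <- polymorphic_columns(aln)
    # truth columns are molecule-local; map via the reference row
    want_cols <- sort(vapply(unlist(ct$local_columns), function(li)
      alignment_column(aln, li), integer(1)))
    expect_identical(cols, want_cols)
    cs <- enumerate_clades(aln, cols)
    expect_equal(length(cs$clades), ct$n_clades)
    # membership agrees with the truth assignment
    for (cl in cs$clades) {
      truth_haps <- unlist(ct$assignment[cl$member_ids])
      expect_length(unique(truth_haps), 1L)
    }
  }
})
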