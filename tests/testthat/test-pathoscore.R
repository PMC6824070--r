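test_that("conservation index is the matching fraction to 2 decimals", {
  set.seed(2)
  # 45 non-reference panel rows, 44 matching the rCRS base at the site
  len <- 60L
  ref <- strsplit(random_seq(len), "")[[1]]
  site <- 30L
  ref[site] <- "G"
  rows <- vapply(1:45, function(i) {
    r <- ref
    if (i == 1) r[site] <- "A"
    paste(r, collapse = "")
  }, character(1))
  panel <- make_aln(c(rCRS = paste(ref, collapse = ""),
                      setNames(rows, sprintf("p%02d", 1:45))),
                    species = "panel", gene = "gC")
  g <- gene_model("gC", 9001, 9060, TRUE)
  v <- variant_record(9030, "G", "A", "gC")
  expect_equal(conservation_index(panel, v, g), 97.78)
  # all matching
  rows2 <- rep(paste(ref, collapse = ""), 10)
  panel2 <- make_aln(c(rCRS = paste(ref, collapse = ""),
                       setNames(rows2, sprintf("q%02d", 1:10))),
                     species = "panel", gene = "gC")
  expect_equal(conservation_index(panel2, v, g), 100)
  # gapped rows leave the denominator
  rows3 <- c(rows[1:4], sub(sprintf("^(.{%d}).", site - 1), "\\1-", rows[5]))
  panel3 <- make_aln(c(rCRS = paste(ref, collapse = ""),
                       setNames(rows3, sprintf("r%02d", 1:5))),
                     species = "panel", gene = "gC")
  expect_equal(conservation_index(panel3, v, g), round(100 * 3 / 4, 2))
})

test_that("conservation index equals an independent tally on random panels", {
  set.seed(43)
  g <- gene_model("gC", 9001, 9060, TRUE)
  for (rep in 1:15) {
    panel <- random_aln(n = sample(5:40, 1), len = 60, p = 0.3, gene = "gC")
    ref_b <- substr(reference_seq(panel), 22, 22)
    v <- variant_record(9022, ref_b, setdiff(c("A","C","G","T"), ref_b)[1], "gC")
    ci <- conservation_index(panel, v, g)
    col <- alignment_column(panel, 22)
    bases <- vapply(panel$seqs[panel$ids != "rCRS"],
                    function(s) substr(s, col + 1, col + 1), character(1))
    nongap <- bases[bases != "-"]
    expect_equal(ci, round(100 * sum(nongap == ref_b) / length(nongap), 2))
  }
})

test_that("scoring floors at neutral, ceils at definitely, and re-sums exactly", {
  rb <- default_rubric()
  none <- list(n_independent_reports = "unknown", heteroplasmy_observed = "unknown",
               segregates_with_phenotype = "unknown", biochemical_defect = "unknown",
               single_fibre_evidence = "unknown", cybrid_evidence = "unknown",
               conservation_index_pct = "unknown")
  expect_equal(score_pathogenicity(none, rb),
               list(total = 0, label = "neutral"))
  all_yes <- list(n_independent_reports = "4", heteroplasmy_observed = "yes",
                  segregates_with_phenotype = "yes", biochemical_defect = "yes",
                  single_fibre_evidence = "yes", cybrid_evidence = "yes",
                  conservation_index_pct = "95")
  top <- score_pathogenicity(all_yes, rb)
  expect_equal(top$total, sum(rb$weights))
  expect_identical(top$label, "definitely")

  # 200 random evidence vectors under random valid rubrics vs brute-force
  set.seed(47)
  tristates <- c("yes", "no", "unknown")
  for (rep in 1:200) {
    w <- round(runif(7, 0.5, 6), 1)
    names(w) <- c("n_independent_reports", "conservation",
                  "heteroplasmy_observed", "segregates_with_phenotype",
                  "biochemical_defect", "single_fibre_evidence",
                  "cybrid_evidence")
    cuts <- sort(sample(seq(1, sum(w), by = 0.5), 3))
    names(cuts) <- c("possibly", "probably", "definitely")
    rb2 <- rubric(w, conservation_threshold = runif(1, 50, 95),
                  cut_points = cuts)
    ev <- list(n_independent_reports = as.character(sample(0:5, 1)),
               heteroplasmy_observed = sample(tristates, 1),
               segregates_with_phenotype = sample(tristates, 1),
               biochemical_defect = sample(tristates, 1),
               single_fibre_evidence = sample(tristates, 1),
               cybrid_evidence = sample(tristates, 1),
               conservation_index_pct =
                 sample(c("unknown", as.character(sample(0:100, 1))), 1))
    got <- score_pathogenicity(ev, rb2)
    # independent re-summation
    expected <- 0
    if (as.numeric(ev$n_independent_reports) > 1)
      expected <- expected + w[["n_independent_reports"]]
    ci <- suppressWarnings(as.numeric(ev$conservation_index_pct))
    if (!is.na(ci) && ci >= rb2$conservation_threshold)
      expected <- expected + w[["conservation"]]
    for (f in names(w)[3:7]) if (ev[[f]] == "yes") expected <- expected + w[[f]]
    expect_equal(got$total, expected)
    expected_label <- if (expected >= cuts[3]) "definitely"
      else if (expected >= cuts[2]) "probably"
      else if (expected >= cuts[1]) "possibly" else "neutral"
    expect_identical(got$label, expected_label)
  }
})

test_that("adding a satisfied criterion never lowers the score or label rank", {
  set.seed(51)
  rank_of <- function(l) match(l, c("neutral", "possibly", "probably", "definitely"))
  flags <- c("heteroplasmy_observed", "segregates_with_phenotype",
             "biochemical_defect", "single_fibre_evidence", "cybrid_evidence")
  for (rep in 1:40) {
    w <- round(runif(7, 0.5, 6), 1)
    names(w) <- c("n_independent_reports", "conservation", flags)
    cuts <- sort(sample(seq(1, sum(w), by = 0.5), 3))
    names(cuts) <- c("possibly", "probably", "definitely")
    rb <- rubric(w, 75, cuts)
    ev <- list(n_independent_reports = as.character(sample(0:4, 1)),
               heteroplasmy_observed = sample(c("yes", "unknown"), 1),
               segregates_with_phenotype = sample(c("yes", "unknown"), 1),
               biochemical_defect = sample(c("yes", "unknown"), 1),
               single_fibre_evidence = sample(c("yes", "unknown"), 1),
               cybrid_evidence = sample(c("yes", "unknown"), 1),
               conservation_index_pct = "unknown")
    base <- score_pathogenicity(ev, rb)
    unmet <- flags[vapply(flags, function(f) ev[[f]] != "yes", logical(1))]
    if (length(unmet) == 0) next
    ev2 <- ev; ev2[[unmet[1]]] <- "yes"
    more <- score_pathogenicity(ev2, rb)
    expect_gte(more$total, base$total)
    expect_gte(rank_of(more$label), rank_of(base$label))
  }
})

test_that("cross-tabulation reproduces the published column totals and counts conserve", {
  counts <- predictor_rubric_counts()
  pairs <- expand_confusion_counts(counts)
  cm <- crosstabulate(pairs$classification, pairs$prediction)
  expect_equal(unname(cm$column_totals),
               c(100, 56, 2, 113)[match(colnames(cm$counts),
                                        c("neutral", "possibly", "probably",
                                          "definitely"))])
  expect_true(all(cm$counts[rownames(counts), colnames(counts)] == counts))
  expect_equal(sum(cm$counts), nrow(pairs))
  # empty input: all-zero matrix
  cm0 <- crosstabulate(character(0), character(0))
  expect_true(all(cm0$counts == 0))
  expect_error(crosstabulate("weird", "neutral"), "weird")
})

test_that("random label pairs cross-tabulate like brute-force counting", {
  set.seed(57)
  cls <- c("neutral", "possibly", "probably", "definitely")
  prd <- c("pathogenic", "probably", "possibly", "neutral", "no score")
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    a <- sample(cls, n, replace = TRUE)
    b <- sample(prd, n, replace = TRUE)
    cm <- crosstabulate(a, b)
    for (i in prd) for (j in cls)
      expect_equal(cm$counts[i, j], sum(a == j & b == i))
    # permutation invariance of the metrics
    perm <- sample(n)
    m1 <- suppressWarnings(concordance_metrics(cm))
    m2 <- suppressWarnings(concordance_metrics(crosstabulate(a[perm], b[perm])))
    expect_equal(m1$sensitivity_pct, m2$sensitivity_pct)
    expect_equal(m1$specificity_pct, m2$specificity_pct)
  }
})

test_that("concordance metrics match the published worked example", {
  cm <- crosstabulate(
    expand_confusion_counts(predictor_rubric_counts())$classification,
    expand_confusion_counts(predictor_rubric_counts())$prediction)
  m <- concordance_metrics(cm)
  expect_equal(round(m$sensitivity_pct), 29)
  expect_equal(m$sensitivity_pct, round(100 * 33 / 113, 1))
  expect_equal(m$specificity_pct, 71.0)
  # perfect agreement scores 100/100
  diag_pairs <- data.frame(
    classification = rep(c("definitely", "neutral"), each = 5),
    prediction = rep(c("pathogenic", "neutral"), each = 5))
  md <- concordance_metrics(crosstabulate(diag_pairs$classification,
                                          diag_pairs$prediction))
  expect_equal(md$sensitivity_pct, 100)
  expect_equal(md$specificity_pct, 100)
})
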