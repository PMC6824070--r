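# exhaustive 16-pair lookup written independently of classify_pair
PAIR_LOOKUP <- c(
  AA = "mismatch", AC = "mismatch", AG = "mismatch", AT = "watson-crick",
  CA = "mismatch", CC = "mismatch", CG = "watson-crick", CT = "mismatch",
  GA = "mismatch", GC = "watson-crick", GG = "mismatch", GT = "wobble",
  TA = "watson-crick", TC = "mismatch", TG = "wobble", TT = "mismatch")

test_that("pair classification matches the exhaustive lookup and is symmetric", {
  for (a in c("A", "C", "G", "T")) for (b in c("A", "C", "G", "T")) {
    expect_identical(as.character(classify_pair(a, b)),
                     unname(PAIR_LOOKUP[paste0(a, b)]))
    expect_identical(as.character(classify_pair(a, b)),
                     as.character(classify_pair(b, a)))
  }
  expect_identical(as.character(classify_pair("G", "T")), "wobble")
  expect_identical(as.character(classify_pair("G", "C")), "watson-crick")
  un <- classify_pair("N", "A")
  expect_identical(as.character(un), "unpaired")
  expect_true(attr(un, "indeterminate"))
})

test_that("cloverleaf templates are valid involutions at every tRNA length", {
  for (L in c(55, 59, 63, 68, 71, 76, 88, 100)) {
    st <- cloverleaf_template("g", L)
    expect_equal(st$n, L)
    paired <- which(!is.na(st$partner))
    expect_identical(st$partner[st$partner[paired]], paired)
    expect_false(any(st$partner[paired] == paired))
    # partners share a stem element; every stem has >= 3 pairs
    expect_identical(st$element[paired], st$element[st$partner[paired]])
    stems <- table(st$element[paired]) / 2
    expect_true(all(stems >= 3))
    expect_true(all(lengths(st$tertiary) %in% 2:3))
    # structure JSON round-trip
    path <- tempfile(fileext = ".json")
    write_structure_json(st, path)
    back <- read_structure_json(path)
    expect_identical(back$element, st$element)
    expect_identical(back$partner, st$partner)
    expect_equal(back$canonical, st$canonical)
  }
})

# build a small controlled scenario: one gene, a stem variant, several
# carrier species with/without partner compensation
compensation_scenario <- function(compensated, carriers_frac = 1,
                                  n = 10, seed = 1) {
  set.seed(seed)
  st <- cloverleaf_template("gS", 70)
  site <- which(st$element == "T-stem")[1]
  partner <- st$partner[site]
  ref <- strsplit(random_seq(70), "")[[1]]
  ref[site] <- "G"; ref[partner] <- "C"
  alt <- "A"
  g <- gene_model("gS", 5001, 5070, TRUE)
  species <- names(compensated)
  alns <- list(); calls <- list()
  for (sp in species) {
    k <- max(1, round(carriers_frac * n))
    rows <- lapply(seq_len(n), function(i) {
      r <- ref
      if (i <= k) {
        r[site] <- alt
        if (compensated[[sp]]) r[partner] <- complement_base(alt)
      }
      paste(r, collapse = "")
    })
    aln <- make_aln(c(rCRS = paste(ref, collapse = ""),
                      setNames(unlist(rows), sprintf("%s_%02d", sp, 1:n))),
                    species = sp, gene = "gS")
    alns[[sp]] <- aln
    calls[[sp]] <- call_variant(aln,
                                variant_record(5000 + site, "G", alt, "gS"), g)
  }
  list(structure = st, gene = g, alns = alns, calls = calls,
       site = site, partner = partner,
       variant = variant_record(5000 + site, "G", alt, "gS"))
}

test_that("partner compensation is classified All / Some / None", {
  for (pattern in list(c(a = TRUE, b = TRUE, c = TRUE),
                       c(a = TRUE, b = FALSE, c = TRUE),
                       c(a = FALSE, b = FALSE, c = FALSE))) {
    sc <- compensation_scenario(as.list(pattern), carriers_frac = 0.5, n = 12)
    pa <- assess_secondary(sc$variant, sc$gene, sc$structure, sc$alns,
                           unname(sc$calls))
    want <- if (all(pattern)) "All" else if (any(pattern)) "Some" else "None"
    expect_identical(pa$partner_changed, want)
    expect_identical(pa$rcrs_pair_class, "watson-crick")
    expect_identical(pa$element, "T-stem")
    if (any(pattern)) {
      # the description names the partner position in rCRS coordinates
      expect_match(pa$partner_change_description,
                   paste0("^", 5000 + sc$partner, "C>T$"))
      changed_species <- names(which(vapply(pa$detail, `[[`, logical(1),
                                            "changed")))
      expect_setequal(changed_species, names(pattern)[pattern])
    }
  }
})

test_that("loop variants get n/a partner fields and carrier sets are honoured", {
  set.seed(3)
  st <- cloverleaf_template("gL", 70)
  loop_site <- which(st$element == "T-loop")[2]
  ref <- strsplit(random_seq(70), "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), ref[loop_site])[1]
  rows <- lapply(1:8, function(i) {
    r <- ref; if (i <= 4) r[loop_site] <- alt; paste(r, collapse = "")
  })
  aln <- make_aln(c(rCRS = paste(ref, collapse = ""),
                    setNames(unlist(rows), sprintf("s%02d", 1:8))),
                  species = "spL", gene = "gL")
  g <- gene_model("gL", 6001, 6070, TRUE)
  v <- variant_record(6000 + loop_site, ref[loop_site], alt, "gL")
  cl <- call_variant(aln, v, g)
  pa <- assess_secondary(v, g, st, list(spL = aln), list(cl))
  expect_identical(pa$partner_changed, "n/a")
  expect_identical(pa$rcrs_pair_class, "unpaired")
  expect_true(pa$element == "T-loop")
  # empty carrier set is a hard error
  aln0 <- make_aln(c(rCRS = paste(ref, collapse = ""),
                     s1 = paste(ref, collapse = "")),
                   species = "spL", gene = "gL")
  cl0 <- call_variant(aln0, v, g)
  expect_error(assess_secondary(v, g, st, list(spL = aln0), list(cl0)),
               "no species")
})

test_that("tertiary assessments cover exactly the groups containing the site", {
  set.seed(8)
  st <- cloverleaf_template("gT", 72)
  g <- gene_model("gT", 7001, 7072, TRUE)
  ref <- strsplit(random_seq(72), "")[[1]]
  # membership oracle: for each local site, which groups contain its
  # canonical number or its partner's
  for (site in sample(seq_len(72), 25)) {
    alt <- setdiff(c("A", "C", "G", "T"), ref[site])[1]
    rows <- vapply(1:6, function(i) {
      r <- ref; r[site] <- alt; paste(r, collapse = "")
    }, character(1))
    aln <- make_aln(c(rCRS = paste(ref, collapse = ""),
                      setNames(rows, sprintf("s%d", 1:6))),
                    species = "spT", gene = "gT")
    v <- variant_record(7000 + site, ref[site], alt, "gT")
    cl <- call_variant(aln, v, g)
    ta <- assess_tertiary(v, g, st, list(spT = aln), list(cl))
    sites <- c(site, st$partner[site])
    sites <- sites[!is.na(sites)]
    expected_groups <- list()
    for (s in sites) {
      cn <- st$canonical[s]
      if (is.na(cn)) next
      for (grp in st$tertiary)
        if (cn %in% grp) expected_groups[[length(expected_groups) + 1]] <- grp
    }
    expect_length(ta, length(expected_groups))
    if (length(ta))
      expect_setequal(
        vapply(ta, function(a) paste(a$group, collapse = "-"), character(1)),
        vapply(expected_groups, paste, collapse = "-", character(1)))
    # no other site was touched, so changes must be none everywhere
    for (a in ta) if (length(a$other_local))
      expect_identical(a$other_site_changes, "none")
  }
})

test_that("planted tertiary changes are reported for exactly the planted species", {
  sim <- small_sim(seed = 61, p_tertiary_change = 1, p_partner_compensation = 0,
                   n_gap_columns = 0)
  genes <- human_gene_models(file.path(sim$dir, "gene_models.json"))
  structures <- lapply(names(genes), function(gn)
    read_structure_json(file.path(sim$dir, "structures", paste0(gn, ".json"))))
  names(structures) <- names(genes)
  checked <- 0L
  for (v in sim$truth$variants) {
    present <- names(Filter(function(ps) ps$status != "absent", v$per_species))
    if (length(present) == 0 || length(v$tertiary_changed_species) == 0) next
    g <- genes[[v$gene]]
    ref_strand <- if (g$molecule_sense_is_reference_strand)
      c(v$molecule_ref, v$molecule_alt)
    else complement_base(c(v$molecule_ref, v$molecule_alt))
    vr <- variant_record(v$rcrs_position, ref_strand[1], ref_strand[2], v$gene)
    alns <- setNames(lapply(present, function(sp) read_alignment(
      file.path(sim$dir, "alignments", paste0(sp, "__", v$gene, ".fasta")),
      "rCRS")), present)
    calls <- lapply(alns, function(a) call_variant(a, vr, g))
    ta <- assess_tertiary(vr, g, structures[[v$gene]], alns, unname(calls))
    if (length(ta) == 0) next
    # the generator changed a site of the first matching group in every
    # carrier species, so at least one emitted group must report changes
    agg <- vapply(ta, `[[`, character(1), "other_site_changes")
    expect_true(any(agg %in% c("all", "some")))
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})
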