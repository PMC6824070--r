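#' Simulation parameters for the synthetic dataset generator
#'
#' Defaults emulate the study conditions this pipeline was built for:
#' 33 species x 22 tRNA genes (726 alignments), 20-400 sequences per
#' species-gene alignment, realistic mt-tRNA gene lengths, planted
#' monomorphic/polymorphic variants with minor-allele counts spanning the
#' observed range, optional compensatory changes at pairing partners and
#' tertiary-interaction sites, co-segregating polymorphic columns that
#' define clades, and a small number of injected gap columns.
#'
#' @param n_species number of species (default 33)
#' @param n_genes number of genes (default 22)
#' @param sequences_per_species integer range (min, max) of rows per
#'   species-gene alignment (default c(20, 400))
#' @param gene_length integer range of gene lengths (default c(59, 75),
#'   within the 55-100 tRNA bound)
#' @param n_variants_per_gene planted variants per gene when
#'   `planted_variants = "auto"` (default 2)
#' @param planted_variants `"auto"`, or a list of plants: each
#'   `list(gene_id, local_index, alt, carriers = c(species = fraction))`
#'   with fraction in (0, 1]; fraction 1 plants a monomorphic variant,
#'   otherwise exactly `round(fraction * n)` carrier rows (at least 1,
#'   at most n-1) are assigned deterministically after a seeded shuffle
#' @param p_partner_compensation per carrier-species probability that the
#'   pairing partner of a stem variant is changed compensatorily in the
#'   carrier rows (default 0.5)
#' @param p_tertiary_change per carrier-species probability that another
#'   member of the variant's tertiary group is changed in carrier rows
#'   (default 0.3)
#' @param qc_noise list with per-alignment counts of injected extra rows:
#'   `n_remove_length` (internal insertions beyond tolerance),
#'   `n_trim_length` (pure terminal overhangs), `n_n_rich` (>= max_unknown
#'   N bases); default all 0
#' @param clade_spec list(n_columns, n_groups) of co-segregating
#'   polymorphic columns and row groups per gene (default 3 columns /
#'   5 groups, echoing the handful of clade-defining sites seen in real
#'   mt-tRNA alignments); requires
#'   `2^(n_columns-1) < n_groups <= 2^n_columns` so every clade column is
#'   polymorphic; set n_columns = 0 to disable
#' @param n_gap_columns deletion-style gap columns per alignment
#'   (default 1, never at planted or clade columns)
#' @param n_ref_gap_columns insertion columns where the reference row is
#'   gapped (default 1), exercising gap-adjusted coordinate mapping
#' @param seed integer master seed
#' @return list of class `simulation_params`
#' @export
simulation_params <- function(n_species = 33L, n_genes = 22L,
                              sequences_per_species = c(20L, 400L),
                              gene_length = c(59L, 75L),
                              n_variants_per_gene = 2L,
                              planted_variants = "auto",
                              p_partner_compensation = 0.5,
                              p_tertiary_change = 0.3,
                              qc_noise = list(n_remove_length = 0L,
                                              n_trim_length = 0L,
                                              n_n_rich = 0L),
                              clade_spec = list(n_columns = 3L, n_groups = 5L),
                              n_gap_columns = 1L,
                              n_ref_gap_columns = 1L,
                              seed = 1L) {
  stopifnot(n_species >= 1L, n_genes >= 1L,
            length(sequences_per_species) == 2L,
            sequences_per_species[1] >= 2L,
            gene_length[1] >= 55L, gene_length[2] <= 100L)
  nc <- clade_spec$n_columns; ng <- clade_spec$n_groups
  if (nc > 0L) {
    if (!(ng > 2^(nc - 1L) && ng <= 2^nc))
      stop("clade_spec requires 2^(n_columns-1) < n_groups <= 2^n_columns")
    if (nc + 2L * n_variants_per_gene + 6L > gene_length[1])
      stop("more clade/variant columns than the gene length can host")
  }
  structure(list(
    n_species = as.integer(n_species), n_genes = as.integer(n_genes),
    sequences_per_species = as.integer(sequences_per_species),
    gene_length = as.integer(gene_length),
    n_variants_per_gene = as.integer(n_variants_per_gene),
    planted_variants = planted_variants,
    p_partner_compensation = p_partner_compensation,
    p_tertiary_change = p_tertiary_change,
    qc_noise = qc_noise, clade_spec = clade_spec,
    n_gap_columns = as.integer(n_gap_columns),
    n_ref_gap_columns = as.integer(n_ref_gap_columns),
    seed = as.integer(seed)), class = "simulation_params")
}

# random molecule reference with Watson-Crick complementary stems
random_reference <- function(structure) {
  s <- sample(DNA_BASES, structure$n, replace = TRUE)
  paired <- which(!is.na(structure$partner))
  for (i in paired[paired < structure$partner[paired]])
    s[structure$partner[i]] <- complement_base(s[i])
  s
}

# a base different from `b`, deterministic rotation A->G->A, C->T->C
other_base <- function(b) chartr("AGCT", "GATC", b)

# sample() that never falls into the 1:n trap for length-1 inputs
safe_sample <- function(x, size = length(x), replace = FALSE) {
  if (length(x) == 1L) {
    if (replace) return(rep(x, size))
    stopifnot(size <= 1L)
    return(x[seq_len(size)])
  }
  sample(x, size, replace = replace)
}

#' Generate a truth-labelled synthetic dataset
#'
#' Emits a full input tree for the pipeline - aligned FASTA per
#' species-gene (with an embedded reference row `rCRS`), a structure JSON
#' per gene (schematic cloverleaf with stems >= 3 bp and the default
#' tertiary groups), a gene model JSON, a variant table with evidence
#' fields and external predictor labels, and a `truth.json` recording
#' every planted fact: per-variant per-species status and carrier
#' counts, compensated and tertiary-changed species sets, per-row QC
#' fate, and per-alignment clade assignments. Deterministic: the same
#' `params` (including seed) produce byte-identical trees. A validator
#' recounts planted variant statuses from the assembled alignments at
#' generation time and aborts on any inconsistency.
#'
#' @param params a [simulation_params()]
#' @param out_dir output directory (created; must not already contain a
#'   truth.json)
#' @return invisibly, the truth list (also written to
#'   `out_dir/truth.json`)
#' @export
simulate_dataset <- function(params, out_dir) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE)

  species <- sprintf("species%02d", seq_len(params$n_species))
  gene_ids <- sprintf("g%02d", seq_len(params$n_genes))

  # gene models on a synthetic circular coordinate system
  lens <- safe_sample(seq(params$gene_length[1], params$gene_length[2]),
                      params$n_genes, replace = TRUE)
  starts <- cumsum(c(100L, utils::head(lens, -1) + 50L))
  genes <- lapply(seq_along(gene_ids), function(i) {
    gene_model(gene_ids[i], starts[i], starts[i] + lens[i] - 1L,
               molecule_sense_is_reference_strand = (i %% 2L == 1L))
  })
  names(genes) <- gene_ids
  structures <- lapply(genes, function(g)
    cloverleaf_template(g$gene_id, gene_length(g)))
  refs <- lapply(structures, random_reference)

  # plant list
  plants <- params$planted_variants
  if (identical(plants, "auto"))
    plants <- auto_plants(genes, structures, refs, species,
                          params$n_variants_per_gene,
                          params$sequences_per_species)
  for (p in plants) {
    ref_b <- refs[[p$gene_id]][p$local_index]
    if (p$alt == ref_b)
      stop("planted alt equals the reference base at ", p$gene_id, ":",
           p$local_index)
  }

  # reserve per-gene special positions
  gene_plants <- split(plants, vapply(plants, `[[`, character(1), "gene_id"))
  special <- lapply(gene_ids, function(g) {
    pl <- gene_plants[[g]]
    sites <- integer(0)
    for (p in pl) {
      st <- structures[[g]]
      sites <- c(sites, p$local_index, st$partner[p$local_index],
                 tertiary_other_local(st, p$local_index))
    }
    sites[!is.na(sites)]
  })
  names(special) <- gene_ids

  clade_cols <- lapply(gene_ids, function(g) {
    nc <- params$clade_spec$n_columns
    if (nc == 0L) return(integer(0))
    free <- setdiff(seq_len(structures[[g]]$n), special[[g]])
    sort(safe_sample(free, nc))
  })
  names(clade_cols) <- gene_ids

  truth <- list(seed = params$seed, species = species,
                genes = lapply(genes, function(g) list(
                  gene_id = g$gene_id, start = g$rcrs_start, end = g$rcrs_end,
                  length = gene_length(g),
                  molecule_sense_is_reference_strand =
                    g$molecule_sense_is_reference_strand)),
                variants = list(), qc = list(), clades = list())

  # per-variant bookkeeping
  vtruth <- lapply(plants, function(p) list(
    gene = p$gene_id, local_index = p$local_index,
    rcrs_position = local_to_rcrs(p$local_index, genes[[p$gene_id]]),
    molecule_ref = refs[[p$gene_id]][p$local_index], molecule_alt = p$alt,
    per_species = list(), compensated_species = character(0),
    tertiary_changed_species = character(0)))

  for (sp in species) for (g in gene_ids) {
    n <- safe_sample(seq(params$sequences_per_species[1],
                         params$sequences_per_species[2]), 1L)
    st <- structures[[g]]
    L <- st$n
    ref_chars <- refs[[g]]
    mat <- matrix(rep(ref_chars, each = n), nrow = n, ncol = L)
    row_ids <- sprintf("%s_%s_%04d", sp, g, seq_len(n))
    rownames(mat) <- row_ids

    # clade groups: binary patterns over the clade columns
    cols <- clade_cols[[g]]
    if (length(cols)) {
      ng <- params$clade_spec$n_groups
      grp <- sample(rep_len(seq_len(ng), n))
      for (j in seq_along(cols)) {
        in_s <- ((grp - 1L) %/% 2L^(j - 1L)) %% 2L == 1L
        mat[in_s, cols[j]] <- other_base(ref_chars[cols[j]])
      }
    }

    # planted variants for this gene
    for (vi in seq_along(plants)) {
      p <- plants[[vi]]
      if (p$gene_id != g) next
      frac <- p$carriers[[sp]]
      if (is.null(frac) || is.na(frac)) {
        vtruth[[vi]]$per_species[[sp]] <-
          list(status = "absent", count_alt = 0L, n = n)
        next
      }
      k <- if (frac >= 1) n else max(1L, min(n - 1L, round(frac * n)))
      carriers <- sample(row_ids)[seq_len(k)]
      mat[carriers, p$local_index] <- p$alt
      status <- if (k == n) "monomorphic" else "polymorphic"
      vtruth[[vi]]$per_species[[sp]] <-
        list(status = status, count_alt = k, n = n,
             carrier_ids = as.list(carriers))

      partner <- st$partner[p$local_index]
      if (!is.na(partner) && stats::runif(1) < params$p_partner_compensation) {
        mat[carriers, partner] <- complement_base(p$alt)
        vtruth[[vi]]$compensated_species <-
          c(vtruth[[vi]]$compensated_species, sp)
      }
      tert <- tertiary_other_local(st, p$local_index)
      if (length(tert) && stats::runif(1) < params$p_tertiary_change) {
        mat[carriers, tert[1]] <- other_base(ref_chars[tert[1]])
        vtruth[[vi]]$tertiary_changed_species <-
          c(vtruth[[vi]]$tertiary_changed_species, sp)
      }
    }

    # deletion-style gap columns (never at special or clade columns)
    protected <- c(special[[g]], cols)
    free <- setdiff(seq_len(L), protected)
    gap_cols <- if (params$n_gap_columns > 0L)
      safe_sample(free, min(params$n_gap_columns, length(free))) else integer(0)
    for (j in gap_cols) {
      hit <- stats::runif(n) < 0.2
      mat[hit, j] <- "-"
    }

    # clade truth from the final planted matrix (min_minor = 1)
    truth$clades[[paste0(sp, "__", g)]] <-
      clade_truth_from_matrix(mat, cols, g, plants)

    # QC-noise rows are appended extras so planted counts survive QC
    qn <- params$qc_noise
    extras <- assemble_extras(qn, ref_chars, L, free)

    aln <- assemble_alignment(sp, g, mat, ref_chars, extras,
                              n_ref_gap = params$n_ref_gap_columns,
                              free_cols = free)
    write_alignment(aln, file.path(out_dir, "alignments",
                                   paste0(sp, "__", g, ".fasta")))
    truth$qc[[paste0(sp, "__", g)]] <- list(
      removed_length = as.list(extras$remove_ids),
      trimmed = as.list(extras$trim_ids),
      removed_n = as.list(extras$nrich_ids),
      n_planted = n)
  }

  truth$variants <- vtruth

  for (g in gene_ids)
    write_structure_json(structures[[g]],
                         file.path(out_dir, "structures", paste0(g, ".json")))
  jsonlite::write_json(
    lapply(genes, function(gm) list(
      gene_id = gm$gene_id, start = gm$rcrs_start, end = gm$rcrs_end,
      molecule_sense_is_reference_strand =
        gm$molecule_sense_is_reference_strand)),
    file.path(out_dir, "gene_models.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  vt <- variant_table_from_truth(vtruth, genes)
  utils::write.table(vt$variants, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vt$labels, file.path(out_dir, "predictor_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth$rubric_labels <- vt$rubric_labels

  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  validate_truth(out_dir, truth, genes)
  invisible(truth)
}

# first "other" local position of a tertiary group containing the site
# (or its partner) - the position the generator may change
tertiary_other_local <- function(st, local_index) {
  sites <- c(local_index, st$partner[local_index])
  sites <- sites[!is.na(sites)]
  for (site in sites) {
    canon <- st$canonical[site]
    if (is.na(canon)) next
    for (g in st$tertiary) {
      if (!canon %in% g) next
      others <- match(setdiff(g, canon), st$canonical)
      others <- others[!is.na(others)]
      if (length(others)) return(others[1])
    }
  }
  integer(0)
}

auto_plants <- function(genes, structures, refs, species, n_per_gene, seq_range) {
  plants <- list()
  for (g in names(genes)) {
    st <- structures[[g]]
    used <- integer(0)
    sites <- integer(0)
    while (length(sites) < n_per_gene) {
      cand <- setdiff(seq_len(st$n), used)
      if (length(cand) == 0L) stop("gene ", g, " too short for the plants")
      s <- safe_sample(cand, 1L)
      used <- c(used, s, st$partner[s], tertiary_other_local(st, s))
      used <- used[!is.na(used)]
      sites <- c(sites, s)
    }
    for (s in sites) {
      carriers <- list()
      for (sp in species) {
        u <- stats::runif(1)
        if (u < 0.4) next                       # absent
        else if (u < 0.7) carriers[[sp]] <- 1   # monomorphic
        else carriers[[sp]] <- stats::runif(1, 0.05, 0.95)
      }
      plants[[length(plants) + 1L]] <- list(
        gene_id = g, local_index = s,
        alt = other_base(refs[[g]][s]),
        carriers = carriers)
    }
  }
  plants
}

clade_truth_from_matrix <- function(mat, clade_cols, gene_id, plants) {
  # generator-side grouping over all polymorphic columns of the planted
  # matrix (gaps/N excluded from allele counts, as the pipeline defines)
  poly <- integer(0)
  for (j in seq_len(ncol(mat))) {
    tab <- table(factor(mat[, j], levels = DNA_BASES))
    tab <- tab[tab > 0L]
    if (length(tab) >= 2L) poly <- c(poly, j)
  }
  if (length(poly) == 0L)
    return(list(local_columns = list(), n_clades = 1L,
                assignment = setNames(as.list(rep("", nrow(mat))),
                                      rownames(mat))))
  sub <- mat[, poly, drop = FALSE]
  ok <- apply(sub, 1L, function(r) all(r %in% DNA_BASES))
  haps <- apply(sub, 1L, paste, collapse = "")
  haps[!ok] <- NA_character_
  list(local_columns = as.list(poly), n_clades = length(unique(haps[ok])),
       assignment = setNames(as.list(haps), rownames(mat)))
}

# build extra QC-noise rows (in molecule coordinates + overhang widths)
assemble_extras <- function(qn, ref_chars, L, free_cols) {
  mk <- function(n, prefix) if (n > 0L) sprintf("%s%02d", prefix, seq_len(n))
                            else character(0)
  remove_ids <- mk(qn$n_remove_length %||% 0L, "lenout")
  trim_ids <- mk(qn$n_trim_length %||% 0L, "overhang")
  nrich_ids <- mk(qn$n_n_rich %||% 0L, "nrich")
  nrich_rows <- lapply(nrich_ids, function(id) {
    chars <- ref_chars
    pos <- safe_sample(free_cols, min(6L, length(free_cols)))
    chars[pos] <- "N"
    chars
  })
  list(remove_ids = remove_ids, trim_ids = trim_ids, nrich_ids = nrich_ids,
       nrich_rows = nrich_rows, insert_width = 8L, overhang_width = 8L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble the final aligned strings: planted matrix + reference row +
# QC extras + reference-gap insertion columns + terminal overhang block
assemble_alignment <- function(sp, g, mat, ref_chars, extras, n_ref_gap,
                               free_cols) {
  n <- nrow(mat); L <- ncol(mat)
  ids <- c("rCRS", rownames(mat), extras$remove_ids, extras$trim_ids,
           extras$nrich_ids)
  total <- length(ids)
  base <- rbind(matrix(ref_chars, nrow = 1L), mat)
  for (id in extras$remove_ids) base <- rbind(base, ref_chars)
  for (id in extras$trim_ids) base <- rbind(base, ref_chars)
  for (row in extras$nrich_rows) base <- rbind(base, row)
  rownames(base) <- ids

  # column plan: optional leading overhang block, then locals 1..L with
  # insertion blocks spliced in after random interior positions
  blocks <- list()
  if (length(extras$trim_ids)) {
    w <- extras$overhang_width
    blk <- matrix("-", nrow = total, ncol = w, dimnames = list(ids, NULL))
    for (id in extras$trim_ids)
      blk[id, ] <- sample(DNA_BASES, w, replace = TRUE)
    blocks[[length(blocks) + 1L]] <- list(after = 0L, m = blk)
  }
  if (n_ref_gap > 0L) {
    for (k in seq_len(n_ref_gap)) {
      at <- sample(5L:(L - 5L), 1L)
      blk <- matrix("-", nrow = total, ncol = 1L, dimnames = list(ids, NULL))
      hit <- sample(rownames(mat), max(1L, round(0.3 * n)))
      # a single shared base so the inserted column is never polymorphic
      blk[hit, 1L] <- safe_sample(DNA_BASES, 1L)
      blocks[[length(blocks) + 1L]] <- list(after = at, m = blk)
    }
  }
  for (id in extras$remove_ids) {
    at <- sample(10L:(L - 10L), 1L)
    w <- extras$insert_width
    blk <- matrix("-", nrow = total, ncol = w, dimnames = list(ids, NULL))
    blk[id, ] <- sample(DNA_BASES, w, replace = TRUE)
    blocks[[length(blocks) + 1L]] <- list(after = at, m = blk)
  }

  pieces <- list()
  afters <- vapply(blocks, `[[`, integer(1), "after")
  for (b in blocks[afters == 0L]) pieces[[length(pieces) + 1L]] <- b$m
  for (j in seq_len(L)) {
    pieces[[length(pieces) + 1L]] <- base[, j, drop = FALSE]
    for (b in blocks[afters == j]) pieces[[length(pieces) + 1L]] <- b$m
  }
  full <- do.call(cbind, pieces)
  seqs <- do.call(paste0, lapply(seq_len(ncol(full)), function(j) full[, j]))
  species_alignment(sp, g, ids, seqs, "rCRS")
}

# evidence vectors engineered to hit each rubric label under the default
# rubric, plus a predictor label drawn from a fixed confusion structure
variant_table_from_truth <- function(vtruth, genes) {
  ev_for <- function(label) switch(label,
    neutral = list(n_independent_reports = "unknown",
                   heteroplasmy_observed = "unknown",
                   segregates_with_phenotype = "unknown",
                   biochemical_defect = "unknown",
                   single_fibre_evidence = "unknown",
                   cybrid_evidence = "unknown",
                   conservation_index_pct = "unknown"),
    possibly = list(n_independent_reports = "3",
                    heteroplasmy_observed = "yes",
                    segregates_with_phenotype = "yes",
                    biochemical_defect = "unknown",
                    single_fibre_evidence = "unknown",
                    cybrid_evidence = "unknown",
                    conservation_index_pct = "90"),
    probably = list(n_independent_reports = "3",
                    heteroplasmy_observed = "yes",
                    segregates_with_phenotype = "unknown",
                    biochemical_defect = "unknown",
                    single_fibre_evidence = "yes",
                    cybrid_evidence = "unknown",
                    conservation_index_pct = "90"),
    definitely = list(n_independent_reports = "3",
                      heteroplasmy_observed = "yes",
                      segregates_with_phenotype = "yes",
                      biochemical_defect = "yes",
                      single_fibre_evidence = "yes",
                      cybrid_evidence = "yes",
                      conservation_index_pct = "90"))
  pred_for <- function(label) {
    match_label <- c(neutral = "neutral", possibly = "possibly",
                     probably = "probably", definitely = "pathogenic")[[label]]
    if (stats::runif(1) < 0.6) match_label
    else sample(setdiff(PREDICTION_LABELS, match_label), 1L)
  }
  rows <- list(); labels <- character(0)
  for (v in vtruth) {
    g <- genes[[v$gene]]
    if (g$molecule_sense_is_reference_strand) {
      ref <- v$molecule_ref; alt <- v$molecule_alt
    } else {
      ref <- complement_base(v$molecule_ref)
      alt <- complement_base(v$molecule_alt)
    }
    label <- sample(CLASSIFICATION_LABELS, 1L)
    labels <- c(labels, label)
    ev <- ev_for(label)
    rows[[length(rows) + 1L]] <- c(
      list(position = v$rcrs_position, ref = ref, alt = alt, gene = v$gene,
           disease = paste0("synthetic-", label)),
      ev, list(predictor_label = pred_for(label)))
  }
  variants <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(variants = variants,
       labels = variants[, c("position", "ref", "alt", "gene",
                             "predictor_label")],
       rubric_labels = labels)
}

# recount planted variant statuses straight from the emitted FASTA files
# (one pass per alignment)
validate_truth <- function(out_dir, truth, genes) {
  by_gene <- split(seq_along(truth$variants),
                   vapply(truth$variants, `[[`, character(1), "gene"))
  for (sp in truth$species) for (g in names(by_gene)) {
    path <- file.path(out_dir, "alignments", paste0(sp, "__", g, ".fasta"))
    aln <- read_alignment(path, "rCRS")
    qc <- truth$qc[[paste0(sp, "__", g)]]
    noise <- unlist(c(qc$removed_length, qc$removed_n, qc$trimmed))
    keep <- !aln$ids %in% noise
    aln <- species_alignment(aln$species_id, aln$gene_id, aln$ids[keep],
                             aln$seqs[keep], "rCRS")
    rows <- nonref_seqs(aln)
    for (vi in by_gene[[g]]) {
      v <- truth$variants[[vi]]
      expect <- v$per_species[[sp]]
      if (is.null(expect)) next
      col <- alignment_column(aln, v$local_index)
      got <- sum(substr(rows, col + 1L, col + 1L) == v$molecule_alt)
      if (got != expect$count_alt)
        stop("truth validation failed for ", sp, "/", g, " variant ",
             vi, ": planted ", expect$count_alt, ", recounted ", got)
    }
  }
  invisible(TRUE)
}
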