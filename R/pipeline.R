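#' Pipeline configuration
#'
#' @param alignments_dir directory of `<species>__<gene>.fasta` files
#' @param variant_table path to the variant TSV
#' @param structures_dir directory of per-gene structure JSON files
#' @param gene_models path to the gene model JSON/YAML (default: the
#'   shipped human mt-tRNA set)
#' @param out_dir output directory for report tables
#' @param reference_row_id id of the human reference row in every
#'   alignment (default "rCRS")
#' @param length_tolerance,max_unknown,trim_policy QC thresholds, see
#'   [apply_qc()]
#' @param min_minor_allele minimum minor-allele count for a focal
#'   variant to receive clade analysis (default 5)
#' @param conservation_threshold rubric conservation threshold override
#'   (default: the rubric's own)
#' @param rubric a [rubric()] (default [default_rubric()])
#' @param seed integer seed recorded in the run log
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(alignments_dir, variant_table, structures_dir,
                            out_dir, gene_models = NULL,
                            reference_row_id = "rCRS",
                            length_tolerance = 5, max_unknown = 5,
                            trim_policy = "trim-ends",
                            min_minor_allele = 5L,
                            conservation_threshold = NULL,
                            rubric = default_rubric(), seed = 1L) {
  stopifnot(length_tolerance > 0, max_unknown > 0, min_minor_allele > 0)
  if (!is.null(conservation_threshold))
    rubric$conservation_threshold <- conservation_threshold
  structure(list(alignments_dir = alignments_dir,
                 variant_table = variant_table,
                 structures_dir = structures_dir,
                 gene_models = gene_models, out_dir = out_dir,
                 reference_row_id = reference_row_id,
                 length_tolerance = length_tolerance,
                 max_unknown = max_unknown, trim_policy = trim_policy,
                 min_minor_allele = as.integer(min_minor_allele),
                 rubric = rubric, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (paths section + thresholds section)
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- c(raw$paths, raw$thresholds)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

load_gene_models <- function(config) {
  if (is.null(config$gene_models)) human_gene_models()
  else human_gene_models(config$gene_models)
}

#' Run the full comparative analysis pipeline
#'
#' Executes the stages in dependency order: alignment QC, gap-aware
#' variant mapping and cross-species search, secondary/tertiary
#' compensation assessment, clade enumeration and haplotype networks for
#' focal variants whose minor allele reaches the `min_minor_allele`
#' threshold in a species, rubric scoring and predictor concordance.
#' Writes the report tables (QC counts, per-species calls, cross-species
#' summary, structural assessments, clade and network exports,
#' concordance matrix and metrics) plus a run log into `config$out_dir`.
#' Deterministic: re-running with identical inputs and config is
#' byte-identical.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with every stage's in-memory results
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  fasta <- sort(list.files(config$alignments_dir, pattern = "\\.fasta$",
                           full.names = TRUE))
  if (length(fasta) == 0L)
    stop("no alignment files (*.fasta) found in ", config$alignments_dir)
  genes <- load_gene_models(config)

  vt <- read_variant_table(config$variant_table)
  variants <- vt$records
  unknown_genes <- setdiff(unique(variants$gene), names(genes))
  if (length(unknown_genes))
    stop("variant table names gene(s) without a gene model: ",
         paste(unknown_genes, collapse = ", "))

  ## stage 1: QC
  qc_out <- lapply(fasta, function(f)
    apply_qc(read_alignment(f, config$reference_row_id),
             length_tolerance = config$length_tolerance,
             max_unknown = config$max_unknown,
             trim_policy = config$trim_policy))
  alignments <- lapply(qc_out, `[[`, "alignment")
  names(alignments) <- vapply(alignments, function(a)
    paste0(a$species_id, "__", a$gene_id), character(1))
  reports <- lapply(qc_out, `[[`, "report")
  qc_df <- qc_table(reports)

  ## stage 2: cross-species variant search
  by_gene <- split(seq_len(nrow(variants)), variants$gene)
  all_calls <- list(); summaries <- list()
  for (g in names(by_gene)) {
    alns <- alignments[vapply(alignments, function(a)
      a$gene_id == g, logical(1))]
    for (i in by_gene[[g]]) {
      v <- variant_from_row(variants[i, ])
      calls <- lapply(alns, function(a) call_variant(a, v, genes[[g]]))
      names(calls) <- vapply(alns, `[[`, character(1), "species_id")
      key <- sprintf("%s_%d%s>%s", g, v$rcrs_position, v$ref_allele,
                     v$alt_allele)
      all_calls[[key]] <- calls
      summaries[[key]] <- summarize_calls(unname(calls))
    }
  }
  calls_df <- do.call(rbind, lapply(all_calls, function(cs)
    calls_table(unname(cs))))
  rownames(calls_df) <- NULL
  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    v <- s$variant
    data.frame(gene = v$gene_id, position = v$rcrs_position,
               ref = v$ref_allele, alt = v$alt_allele,
               monomorphic_species = paste(s$monomorphic_species,
                                           collapse = ", "),
               polymorphic_species = paste(s$polymorphic_display,
                                           collapse = ", "),
               n_species_with_allele = s$n_species_with_allele,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL

  ## stage 3: structural assessment for variants present somewhere
  structures <- list()
  for (g in unique(variants$gene)) {
    sf <- file.path(config$structures_dir, paste0(g, ".json"))
    if (file.exists(sf)) structures[[g]] <- read_structure_json(sf)
  }
  sec_rows <- list(); tert_rows <- list()
  for (key in names(all_calls)) {
    calls <- Filter(function(cl) cl$status != "absent", all_calls[[key]])
    if (length(calls) == 0L) next
    v <- calls[[1]]$variant
    st <- structures[[v$gene_id]]
    if (is.null(st)) next
    alns <- setNames(
      lapply(names(calls), function(sp)
        alignments[[paste0(sp, "__", v$gene_id)]]),
      names(calls))
    pa <- assess_secondary(v, genes[[v$gene_id]], st, alns, unname(calls))
    sec_rows[[key]] <- data.frame(
      gene = v$gene_id, position = v$rcrs_position, ref = v$ref_allele,
      alt = v$alt_allele, element = pa$element,
      rcrs_pair_class = pa$rcrs_pair_class,
      mutant_pair_class = pa$mutant_pair_class,
      partner_changed = pa$partner_changed,
      partner_change = pa$partner_change_description,
      stringsAsFactors = FALSE)
    ta <- assess_tertiary(v, genes[[v$gene_id]], st, alns, unname(calls))
    for (a in ta)
      tert_rows[[length(tert_rows) + 1L]] <- data.frame(
        gene = v$gene_id, position = v$rcrs_position,
        focal_canonical = a$focal_canonical,
        group = paste(a$group, collapse = "-"),
        other_site_changes = a$other_site_changes,
        stringsAsFactors = FALSE)
  }
  secondary_df <- if (length(sec_rows)) do.call(rbind, sec_rows)
                  else data.frame()
  tertiary_df <- if (length(tert_rows)) do.call(rbind, tert_rows)
                 else data.frame()
  rownames(secondary_df) <- NULL

  ## stage 4: clades + networks for focal variants reaching the
  ## minor-allele threshold in >= 1 species
  clade_rows <- list(); networks <- list()
  for (key in names(all_calls)) {
    for (cl in all_calls[[key]]) {
      minor <- min(cl$count_alt, cl$n_nongap - cl$count_alt)
      eligible <- cl$status == "polymorphic" &&
        cl$count_alt >= config$min_minor_allele
      if (!eligible) next
      v <- cl$variant
      aln <- alignments[[paste0(cl$species_id, "__", v$gene_id)]]
      cols <- polymorphic_columns(aln, min_minor = 1L)
      mp <- to_molecule_position(v, genes[[v$gene_id]])
      focal_col <- alignment_column(aln, mp$local_index)
      if (!focal_col %in% cols) next
      cs <- enumerate_clades(aln, cols,
                             focal = list(column = focal_col,
                                          allele = mp$molecule_alt_base))
      net <- build_network(cs)
      nk <- paste0(key, "__", cl$species_id)
      networks[[nk]] <- net
      ct <- clade_table(cs)
      ct$position <- v$rcrs_position
      clade_rows[[nk]] <- ct
    }
  }
  clades_df <- if (length(clade_rows)) do.call(rbind, clade_rows)
               else data.frame()
  rownames(clades_df) <- NULL

  ## stage 5: scoring + concordance
  scores <- lapply(seq_len(nrow(variants)), function(i)
    score_pathogenicity(variants[i, ], config$rubric))
  scores_df <- data.frame(
    gene = variants$gene, position = as.integer(variants$position),
    ref = variants$ref, alt = variants$alt,
    total_points = vapply(scores, `[[`, numeric(1), "total"),
    classification = vapply(scores, `[[`, character(1), "label"),
    predictor_label = variants$predictor_label,
    stringsAsFactors = FALSE)
  cm <- crosstabulate(scores_df$classification, scores_df$predictor_label)
  metrics <- concordance_metrics(cm)
  cm_df <- as.data.frame.matrix(cm$counts)
  cm_df <- cbind(prediction = rownames(cm_df), cm_df)
  rownames(cm_df) <- NULL
  metrics_df <- data.frame(metric = c("sensitivity_pct", "specificity_pct"),
                           value = c(metrics$sensitivity_pct,
                                     metrics$specificity_pct))

  results <- list(qc = qc_df, calls = calls_df, summary = summary_df,
                  secondary = secondary_df, tertiary = tertiary_df,
                  clades = clades_df, scores = scores_df,
                  concordance_matrix = cm_df,
                  concordance_metrics = metrics_df)
  write_result_tables(results, config$out_dir)
  for (nk in sort(names(networks)))
    write_network(networks[[nk]],
                  file.path(config$out_dir, paste0("network_", nk, "_nodes.tsv")),
                  file.path(config$out_dir, paste0("network_", nk, "_edges.tsv")))

  log_lines <- c(
    paste0("mttrnacomp ", as.character(utils::packageVersion("mttrnacomp"))),
    paste0("seed: ", config$seed),
    paste0("alignments: ", length(fasta)),
    paste0("variants parsed: ", nrow(variants), " rejected: ", vt$n_rejected),
    paste0("thresholds: length_tolerance=", config$length_tolerance,
           " max_unknown=", config$max_unknown,
           " trim_policy=", config$trim_policy,
           " min_minor_allele=", config$min_minor_allele,
           " conservation_threshold=", config$rubric$conservation_threshold),
    paste0("qc removed: ", sum(qc_df$n_removed_length + qc_df$n_removed_n),
           " trimmed: ", sum(qc_df$n_trimmed)),
    paste0("calls: ", nrow(calls_df)),
    paste0("clade analyses: ", length(networks)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(c(results, list(networks = networks,
                            variant_calls = all_calls,
                            summaries = summaries,
                            n_alignments = length(fasta))))
}
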