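CLASSIFICATION_LABELS <- c("neutral", "possibly", "probably", "definitely")
PREDICTION_LABELS <- c("pathogenic", "probably", "possibly", "neutral", "no score")

#' Panel conservation index at a variant site
#'
#' Percentage of non-reference panel rows whose base at the variant's
#' mapped column equals the rCRS base, among rows with a non-gap base
#' there. Reported to 2 decimals (e.g. 44 of 45 matching rows gives
#' 97.78).
#'
#' @param panel a [species_alignment()] of reference sequences including
#'   the rCRS row
#' @param variant a [variant_record()]
#' @param gene the matching [gene_model()]
#' @return percentage in [0, 100], rounded to 2 decimals; `NA` with a
#'   warning when every panel row is gapped at the site
#' @export
conservation_index <- function(panel, variant, gene) {
  mp <- to_molecule_position(variant, gene)
  col <- alignment_column(panel, mp$local_index)
  bases <- substr(nonref_seqs(panel), col + 1L, col + 1L)
  nongap <- bases[bases != "-"]
  if (length(nongap) == 0L) {
    warning("conservation index undefined: all panel rows gapped at site")
    return(NA_real_)
  }
  round(100 * sum(nongap == mp$molecule_ref_base) / length(nongap), 2)
}

#' Default Yarham-style scoring rubric
#'
#' Point weights per evidence criterion, the conservation threshold, and
#' the cut-points mapping total points to the four-way classification.
#' The weighting favours functional studies (single fibre and cybrid
#' evidence). All values are configuration: pass a modified list, or a
#' YAML file via [read_rubric()].
#'
#' @return list of class `scoring_rubric` with `weights` (named numeric),
#'   `conservation_threshold` (percentage), and `cut_points` (named
#'   numeric, strictly increasing lower bounds for possibly / probably /
#'   definitely)
#' @export
default_rubric <- function() {
  rubric(
    weights = c(n_independent_reports = 2, conservation = 2,
                heteroplasmy_observed = 2, segregates_with_phenotype = 2,
                biochemical_defect = 2, single_fibre_evidence = 5,
                cybrid_evidence = 5),
    conservation_threshold = 75,
    cut_points = c(possibly = 7, probably = 11, definitely = 13))
}

#' Construct a scoring rubric
#'
#' @param weights named numeric vector of per-criterion points (names as
#'   in [default_rubric()])
#' @param conservation_threshold conservation index (%) at or above which
#'   the conservation criterion is awarded
#' @param cut_points strictly increasing named numeric vector of lower
#'   bounds for the labels possibly, probably, definitely; totals below
#'   the first bound classify as neutral
#' @return object of class `scoring_rubric`
#' @export
rubric <- function(weights, conservation_threshold, cut_points) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(weights >= 0), is.numeric(cut_points),
            identical(names(cut_points), c("possibly", "probably", "definitely")))
  if (any(diff(cut_points) <= 0)) stop("cut-points must be strictly increasing")
  structure(list(weights = weights,
                 conservation_threshold = conservation_threshold,
                 cut_points = cut_points),
            class = "scoring_rubric")
}

#' Read a rubric from a YAML config
#'
#' @param path YAML file with keys `weights`, `conservation_threshold`,
#'   `cut_points`
#' @return a [rubric()]
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  rubric(unlist(raw$weights), raw$conservation_threshold,
         unlist(raw$cut_points)[c("possibly", "probably", "definitely")])
}

#' Score a variant's evidence under a rubric
#'
#' Sums the weights of satisfied criteria: a tristate criterion is
#' awarded only when "yes" (an "unknown" awards 0); the report criterion
#' when `n_independent_reports > 1`; the conservation criterion when the
#' conservation index is known and at or above the rubric threshold. The
#' label follows from the cut-points. Deterministic; all-unknown evidence
#' scores the minimum and classifies as neutral.
#'
#' @param evidence named list or one-row data.frame with the fields
#'   `n_independent_reports`, `heteroplasmy_observed`,
#'   `segregates_with_phenotype`, `biochemical_defect`,
#'   `single_fibre_evidence`, `cybrid_evidence` (tristate
#'   "yes"/"no"/"unknown") and `conservation_index_pct` (number or
#'   "unknown")
#' @param rubric a [rubric()] (default [default_rubric()])
#' @return list with `total` (points) and `label` (one of neutral,
#'   possibly, probably, definitely)
#' @export
score_pathogenicity <- function(evidence, rubric = default_rubric()) {
  w <- rubric$weights
  tri <- function(x) !is.null(x) && !is.na(x) && tolower(as.character(x)) == "yes"
  reports <- suppressWarnings(as.numeric(evidence$n_independent_reports))
  total <- 0
  if (!is.na(reports) && reports > 1) total <- total + w[["n_independent_reports"]]
  ci <- suppressWarnings(as.numeric(evidence$conservation_index_pct))
  if (!is.na(ci) && ci >= rubric$conservation_threshold)
    total <- total + w[["conservation"]]
  for (f in c("heteroplasmy_observed", "segregates_with_phenotype",
              "biochemical_defect", "single_fibre_evidence", "cybrid_evidence"))
    if (tri(evidence[[f]])) total <- total + w[[f]]
  cp <- rubric$cut_points
  label <- if (total >= cp[["definitely"]]) "definitely"
           else if (total >= cp[["probably"]]) "probably"
           else if (total >= cp[["possibly"]]) "possibly"
           else "neutral"
  list(total = total, label = label)
}

#' Cross-tabulate rubric classifications against predictor labels
#'
#' Builds the 5x4 confusion matrix of an external predictor's label
#' (pathogenic / probably / possibly / neutral / no score) against the
#' rubric classification (definitely / probably / possibly / neutral;
#' "pathogenic" is accepted as a synonym for "definitely"). "No score"
#' predictions count in the column totals but never as agreement.
#'
#' @param classification character vector of rubric labels
#' @param prediction character vector of predictor labels, same length
#' @return object of class `confusion_matrix`: integer matrix (rows =
#'   predictions, cols = classifications) plus column totals
#' @export
crosstabulate <- function(classification, prediction) {
  stopifnot(length(classification) == length(prediction))
  classification <- tolower(classification)
  classification[classification == "pathogenic"] <- "definitely"
  prediction <- tolower(prediction)
  bad <- setdiff(unique(classification), CLASSIFICATION_LABELS)
  if (length(bad)) stop("unknown classification label(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(prediction), PREDICTION_LABELS)
  if (length(bad)) stop("unknown prediction label(s): ",
                        paste(bad, collapse = ", "))
  m <- table(factor(prediction, levels = PREDICTION_LABELS),
             factor(classification, levels = CLASSIFICATION_LABELS))
  m <- matrix(as.integer(m), nrow = length(PREDICTION_LABELS),
              dimnames = list(prediction = PREDICTION_LABELS,
                              classification = CLASSIFICATION_LABELS))
  structure(list(counts = m, column_totals = colSums(m)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat("column totals:", paste(x$column_totals, collapse = " "), "\n")
  invisible(x)
}

#' Sensitivity and specificity of the predictor against the rubric
#'
#' Operational definitions with the rubric labels as truth:
#' sensitivity = 100 x (predicted pathogenic among rubric-definite) /
#' (all rubric-definite); specificity = 100 x (predicted neutral among
#' rubric-neutral) / (all rubric-neutral). "No score" predictions remain
#' in the denominators. Both reported to 1 decimal; a zero denominator
#' yields `NA` with a warning.
#'
#' @param matrix a [crosstabulate()] result
#' @return list with `sensitivity_pct`, `specificity_pct`, and
#'   `agreement` (per-cell fraction table)
#' @export
concordance_metrics <- function(matrix) {
  m <- matrix$counts
  tot <- matrix$column_totals
  sens <- if (tot[["definitely"]] > 0)
    round(100 * m["pathogenic", "definitely"] / tot[["definitely"]], 1)
  else { warning("no rubric-definite variants; sensitivity undefined"); NA_real_ }
  spec <- if (tot[["neutral"]] > 0)
    round(100 * m["neutral", "neutral"] / tot[["neutral"]], 1)
  else { warning("no rubric-neutral variants; specificity undefined"); NA_real_ }
  agree <- sweep(m, 2L, pmax(tot, 1L), "/")
  list(sensitivity_pct = sens, specificity_pct = spec, agreement = agree)
}

#' Expand a confusion-count matrix into label pairs
#'
#' Convenience inverse of [crosstabulate()] for published count tables:
#' given a matrix of counts (rows = predictor labels, columns = rubric
#' classifications), reconstructs the individual
#' (classification, prediction) pairs.
#'
#' @param counts integer matrix with rownames in the prediction
#'   vocabulary and colnames in the classification vocabulary
#' @return data.frame with columns `classification` and `prediction`
#' @export
expand_confusion_counts <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    data.frame(
      classification = rep(colnames(counts)[idx[k, 2]], counts[idx[k, 1], idx[k, 2]]),
      prediction = rep(rownames(counts)[idx[k, 1]], counts[idx[k, 1], idx[k, 2]]),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
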