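STEM_ELEMENTS <- c("acceptor-stem", "D-stem", "AC-stem", "T-stem")

#' Default tertiary interaction groups
#'
#' The nine long-range contacts (canonical tRNA numbering) used to fold
#' the cloverleaf into its L-shape. Six are attested directly in the
#' compensatory-change notation this pipeline reproduces (9-23, 10-25-45,
#' 13-22-46, 19-56, 26-44, 54-58); the remaining three follow the
#' canonical tRNA contact set. Override per analysis via the structure
#' JSON.
#'
#' @return list of nine integer vectors of canonical positions
#' @export
default_tertiary_groups <- function() {
  list(c(8L, 14L), c(9L, 23L), c(10L, 25L, 45L), c(13L, 22L, 46L),
       c(15L, 48L), c(18L, 55L), c(19L, 56L), c(26L, 44L), c(54L, 58L))
}

#' Construct a tRNA cloverleaf structure annotation
#'
#' @param gene_id gene label
#' @param element character vector, one element label per molecule
#'   position, from {acceptor-stem, D-stem, D-loop, AC-stem, AC-loop,
#'   variable-region, T-stem, T-loop, D-AC-joint, discriminator}
#' @param canonical numeric vector of standard tRNA position numbers
#'   (NA where no canonical number applies)
#' @param partner integer vector of pairing partners (local indices,
#'   NA for unpaired positions); must be an involution without fixed
#'   points, with both partners in the same stem element
#' @param tertiary list of canonical-position sets (2 or 3 members each)
#' @return object of class `trna_structure`
#' @export
trna_structure <- function(gene_id, element, canonical, partner,
                           tertiary = default_tertiary_groups()) {
  n <- length(element)
  stopifnot(length(canonical) == n, length(partner) == n)
  valid <- c(STEM_ELEMENTS, "D-loop", "AC-loop", "T-loop",
             "variable-region", "D-AC-joint", "discriminator")
  if (!all(element %in% valid))
    stop("unknown element label(s): ",
         paste(setdiff(element, valid), collapse = ", "))
  partner <- as.integer(partner)
  paired <- which(!is.na(partner))
  if (any(partner[paired] == paired))
    stop("partner map has fixed points")
  if (!all(partner[partner[paired]] == paired))
    stop("partner map is not an involution")
  if (!all(element[paired] == element[partner[paired]]) ||
      !all(element[paired] %in% STEM_ELEMENTS))
    stop("partners must lie in the same stem element")
  sizes <- lengths(tertiary)
  if (length(tertiary) && !all(sizes %in% c(2L, 3L)))
    stop("tertiary groups must have 2 or 3 members")
  structure(list(gene_id = as.character(gene_id), n = n,
                 element = element, canonical = as.numeric(canonical),
                 partner = partner,
                 tertiary = lapply(tertiary, as.numeric)),
            class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat(sprintf("<trna_structure> %s: %d nt, %d pairs, %d tertiary groups\n",
              x$gene_id, x$n, sum(!is.na(x$partner)) / 2L, length(x$tertiary)))
  invisible(x)
}

#' Build a schematic cloverleaf template for a gene length
#'
#' Lays out a standard cloverleaf (acceptor stem 7 bp, D-stem 4 bp with
#' 8-nt loop, anticodon stem 5 bp with 7-nt loop, variable region, T-stem
#' 5 bp with 7-nt loop, discriminator base) over `length` positions,
#' shrinking the variable region first and then loops and stems (never
#' below 3 bp) for short genes, and growing the variable region for long
#' ones. Canonical numbers follow the standard 1-76 scheme; stems keep
#' their outermost canonical pairs when shrunk. These templates are
#' schematic, generated by this function - not curated experimental
#' structures - and serve as the default annotation for both the shipped
#' human gene set and synthetic genes.
#'
#' @param gene_id gene label
#' @param length molecule length in nt (55-100)
#' @param tertiary tertiary groups (canonical positions)
#' @return a [trna_structure()]
#' @export
cloverleaf_template <- function(gene_id, length,
                                tertiary = default_tertiary_groups()) {
  length <- as.integer(length)
  if (length < 55L || length > 100L)
    stop("template length must be in 55..100")
  # part sizes: names and default/min values; stems counted per side
  sz <- c(acc = 7L, d = 4L, dloop = 8L, ac = 5L, acloop = 7L,
          var = 1L, t = 5L, tloop = 7L)
  total <- function(s) 2L * (s["acc"] + s["d"] + s["ac"] + s["t"]) +
    s["dloop"] + s["acloop"] + s["tloop"] + s["var"] + 3L + 1L  # joints 8,9,26 + disc
  delta <- length - as.integer(total(sz))
  if (delta > 0L) sz["var"] <- sz["var"] + delta
  else if (delta < 0L) {
    # shrink order keeps tertiary-contact positions as long as possible
    plan <- list(c("dloop", 6L), c("tloop", 5L), c("d", 3L),
                 c("t", 3L), c("ac", 3L), c("acc", 5L),
                 c("dloop", 4L), c("tloop", 4L))
    need <- -delta
    for (p in plan) {
      if (need == 0L) break
      part <- p[1]; floor_v <- as.integer(p[2])
      per_unit <- if (part %in% c("acc", "d", "ac", "t")) 2L else 1L
      avail <- (sz[part] - floor_v) * per_unit
      take <- min(avail, need)
      take <- (take %/% per_unit) * per_unit
      sz[part] <- sz[part] - take %/% per_unit
      need <- need - take
    }
    if (need > 0L) stop("cannot lay out a cloverleaf of length ", length)
    sz["var"] <- sz["var"] + 0L
    # absorb odd remainders into the variable region
    rem <- length - as.integer(total(sz))
    if (rem < 0L) stop("cannot lay out a cloverleaf of length ", length)
    sz["var"] <- sz["var"] + rem
  }
  stopifnot(total(sz) == length)

  element <- character(length); canonical <- rep(NA_real_, length)
  partner <- rep(NA_integer_, length)
  i <- 0L
  put <- function(k, elem, canon) {
    idx <- i + seq_len(k)
    element[idx] <<- elem
    canonical[idx] <<- canon
    i <<- i + k
    idx
  }
  acc5 <- put(sz["acc"], "acceptor-stem", seq_len(sz["acc"]))
  put(2L, "D-AC-joint", c(8, 9))
  d5 <- put(sz["d"], "D-stem", 10 + seq_len(sz["d"]) - 1)
  put(sz["dloop"], "D-loop", 14 + seq_len(sz["dloop"]) - 1)
  d3 <- put(sz["d"], "D-stem", 26 - sz["d"] + seq_len(sz["d"]))
  put(1L, "D-AC-joint", 26)
  ac5 <- put(sz["ac"], "AC-stem", 27 + seq_len(sz["ac"]) - 1)
  put(sz["acloop"], "AC-loop", 32 + seq_len(sz["acloop"]) - 1)
  ac3 <- put(sz["ac"], "AC-stem", 44 - sz["ac"] + seq_len(sz["ac"]))
  v <- sz["var"]
  put(v, "variable-region",
      c(44 + seq_len(min(v, 5L)) - 1, rep(NA_real_, max(0L, v - 5L))))
  t5 <- put(sz["t"], "T-stem", 49 + seq_len(sz["t"]) - 1)
  put(sz["tloop"], "T-loop", 54 + seq_len(sz["tloop"]) - 1)
  t3 <- put(sz["t"], "T-stem", 66 - sz["t"] + seq_len(sz["t"]))
  acc3 <- put(sz["acc"], "acceptor-stem", 73 - sz["acc"] + seq_len(sz["acc"]))
  put(1L, "discriminator", 73)

  pair_up <- function(a, b) {
    partner[a] <<- rev(b); partner[b] <<- rev(a)
  }
  pair_up(acc5, acc3); pair_up(d5, d3); pair_up(ac5, ac3); pair_up(t5, t3)

  # drop tertiary groups whose canonical positions are absent at this length
  tert <- Filter(function(g) sum(g %in% canonical) >= 2L, tertiary)
  trna_structure(gene_id, element, canonical, partner, tert)
}

#' Classify a base pairing
#'
#' A:T/T:A/G:C/C:G are Watson-Crick; G:T/T:G are wobble; any other
#' A/C/G/T combination is a mismatch; an N or gap on either side yields
#' "unpaired" with attribute `indeterminate = TRUE`. Symmetric in its
#' arguments. Molecule-sense bases (U as T).
#'
#' @param base_a,base_b single characters
#' @return one of "watson-crick", "wobble", "mismatch", "unpaired"
#' @export
classify_pair <- function(base_a, base_b) {
  a <- toupper(chartr("U", "T", base_a)); b <- toupper(chartr("U", "T", base_b))
  if (!(a %in% DNA_BASES) || !(b %in% DNA_BASES)) {
    out <- "unpaired"
    attr(out, "indeterminate") <- TRUE
    return(out)
  }
  key <- paste0(a, b)
  if (key %in% c("AT", "TA", "GC", "CG")) "watson-crick"
  else if (key %in% c("GT", "TG")) "wobble"
  else "mismatch"
}

# molecule-sense reference sequence (degapped reference row)
molecule_reference <- function(alignment) {
  gsub("-", "", reference_seq(alignment), fixed = TRUE)
}

# per-species change assessment at a set of molecule-local sites:
# a species counts as changed if any assessed row carries a non-gap,
# non-N base differing from the reference base at any of the sites.
# Assessed rows are the variant carriers for polymorphic species and all
# non-reference rows for monomorphic species.
species_site_changes <- function(sites, alignments, calls) {
  res <- lapply(calls, function(cl) {
    aln <- alignments[[cl$species_id]]
    if (is.null(aln)) stop("no alignment supplied for species ", cl$species_id)
    rows <- nonref_seqs(aln)
    if (cl$status == "polymorphic") rows <- rows[names(rows) %in% cl$carrier_ids]
    ref_mol <- molecule_reference(aln)
    per_site <- lapply(sites, function(li) {
      col <- alignment_column(aln, li)
      ref_base <- substr(ref_mol, li, li)
      bases <- substr(rows, col + 1L, col + 1L)
      dev <- bases %in% DNA_BASES & bases != ref_base
      list(local_index = li, ref_base = ref_base,
           n_assessed = length(bases), n_changed = sum(dev),
           deviant_bases = bases[dev])
    })
    changed <- any(vapply(per_site, function(s) s$n_changed > 0L, logical(1)))
    list(species_id = cl$species_id, status = cl$status,
         changed = changed, per_site = per_site)
  })
  names(res) <- vapply(calls, `[[`, character(1), "species_id")
  res
}

# All/Some/None trichotomy over a nonempty species change list
change_trichotomy <- function(detail) {
  changed <- vapply(detail, `[[`, logical(1), "changed")
  if (all(changed)) "All" else if (any(changed)) "Some" else "None"
}

#' Assess Watson-Crick maintenance at a variant's pairing partner
#'
#' For a stem-site variant, classifies the reference pairing (rCRS base
#' against its partner), the mutant pairing (the human alternate allele
#' against the rCRS partner base), and whether the partner base has
#' changed in the species carrying the variant: `All` if every carrier
#' species deviates from the rCRS partner base, `Some` for a proper
#' subset, `None` if none does. Deviations are assessed within the
#' variant-carrying sequences for polymorphic species and within all
#' sequences for monomorphic species. Loop/joint/discriminator sites get
#' `n/a` partner fields.
#'
#' @param variant a [variant_record()]
#' @param gene the matching [gene_model()]
#' @param structure the gene's [trna_structure()]
#' @param alignments named list of QC'd alignments (by species) for the
#'   species where the variant is present
#' @param calls list of `species_variant_call` with status monomorphic or
#'   polymorphic (nonempty)
#' @return object of class `pairing_assessment`
#' @export
assess_secondary <- function(variant, gene, structure, alignments, calls) {
  calls <- Filter(function(cl) cl$status != "absent", calls)
  if (length(calls) == 0L)
    stop("assessment undefined: no species carries the variant")
  mp <- to_molecule_position(variant, gene)
  li <- mp$local_index
  if (li > structure$n) stop("variant local index beyond structure length")
  elem <- structure$element[li]
  p <- structure$partner[li]

  if (is.na(p)) {
    return(structure(
      list(variant = variant, element = elem, local_index = li,
           partner_local_index = NA_integer_,
           rcrs_pair_class = "unpaired", mutant_pair_class = "unpaired",
           partner_changed = "n/a", partner_change_description = "",
           detail = NULL),
      class = "pairing_assessment"))
  }

  ref_mol <- molecule_reference(alignments[[1]])
  ref_at_site <- substr(ref_mol, li, li)
  ref_at_partner <- substr(ref_mol, p, p)
  if (ref_at_site != mp$molecule_ref_base)
    warning("reference row base ", ref_at_site, " at molecule position ",
            li, " differs from catalogued reference allele ",
            mp$molecule_ref_base)

  detail <- species_site_changes(p, alignments, calls)
  trich <- change_trichotomy(detail)

  # modal partner change, described in reference-strand orientation
  dev <- unlist(lapply(detail, function(d) d$per_site[[1]]$deviant_bases))
  descr <- ""
  if (length(dev)) {
    modal <- names(sort(table(dev), decreasing = TRUE))[1]
    rcrs_pos <- local_to_rcrs(p, gene)
    strand <- function(b) if (gene$molecule_sense_is_reference_strand) b
                          else complement_base(b)
    descr <- sprintf("%d%s>%s", rcrs_pos, strand(ref_at_partner), strand(modal))
  }

  structure(
    list(variant = variant, element = elem, local_index = li,
         partner_local_index = p,
         rcrs_pair_class = as.character(classify_pair(ref_at_site, ref_at_partner)),
         mutant_pair_class = as.character(classify_pair(mp$molecule_alt_base, ref_at_partner)),
         partner_changed = trich, partner_change_description = descr,
         detail = detail),
    class = "pairing_assessment")
}

#' @export
print.pairing_assessment <- function(x, ...) {
  v <- x$variant
  cat(sprintf("<pairing> m.%d%s>%s in %s (%s): %s -> %s; partner changed: %s %s\n",
              v$rcrs_position, v$ref_allele, v$alt_allele, v$gene_id,
              x$element, x$rcrs_pair_class, x$mutant_pair_class,
              x$partner_changed, x$partner_change_description))
  invisible(x)
}

#' Assess tertiary-interaction sites around a variant
#'
#' Emits one assessment per tertiary group containing the variant site
#' or (if the site is paired) its partner: the remaining positions of the
#' group present in this gene are checked for deviation from the rCRS
#' base, carrier-restricted exactly as in [assess_secondary()], and
#' summarised as all/some/none across species. A site belonging to no
#' group yields an empty list.
#'
#' @inheritParams assess_secondary
#' @return list of `tertiary_assessment` objects (possibly empty)
#' @export
assess_tertiary <- function(variant, gene, structure, alignments, calls) {
  calls <- Filter(function(cl) cl$status != "absent", calls)
  if (length(calls) == 0L)
    stop("assessment undefined: no species carries the variant")
  mp <- to_molecule_position(variant, gene)
  focal <- mp$local_index
  partner <- structure$partner[focal]
  sites <- c(focal, if (!is.na(partner)) partner)

  out <- list()
  for (site in sites) {
    canon <- structure$canonical[site]
    if (is.na(canon)) next
    for (g in structure$tertiary) {
      if (!canon %in% g) next
      others_canon <- setdiff(g, canon)
      others_local <- match(others_canon, structure$canonical)
      others_local <- others_local[!is.na(others_local)]
      if (length(others_local) == 0L) {
        changes <- "none"; detail <- NULL
      } else {
        detail <- species_site_changes(others_local, alignments, calls)
        changes <- tolower(change_trichotomy(detail))
      }
      out[[length(out) + 1L]] <- structure(
        list(variant = variant, focal_site = site, focal_canonical = canon,
             group = g, other_canonical = others_canon,
             other_local = others_local,
             other_site_changes = changes, detail = detail),
        class = "tertiary_assessment")
    }
  }
  out
}

#' @export
print.tertiary_assessment <- function(x, ...) {
  cat(sprintf("<tertiary> canonical %s in group {%s}: other sites changed in %s species\n",
              format(x$focal_canonical),
              paste(x$group, collapse = ","), x$other_site_changes))
  invisible(x)
}

#' Write a structure annotation as JSON
#'
#' Schema: `{gene_id, elements: [{local_index, element, canonical}],
#' pairs: [[i,j], ...], tertiary: [[canonical, ...], ...]}`.
#'
#' @param structure a [trna_structure()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure_json <- function(structure, path) {
  elements <- lapply(seq_len(structure$n), function(i) {
    list(local_index = i, element = structure$element[i],
         canonical = if (is.na(structure$canonical[i])) NULL
                     else structure$canonical[i])
  })
  paired <- which(!is.na(structure$partner))
  pairs <- lapply(paired[paired < structure$partner[paired]],
                  function(i) c(i, structure$partner[i]))
  jsonlite::write_json(
    list(gene_id = structure$gene_id, elements = elements,
         pairs = pairs, tertiary = structure$tertiary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a structure annotation from JSON
#'
#' @param path path to a structure JSON written by [write_structure_json()]
#' @return a [trna_structure()]
#' @export
read_structure_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- length(raw$elements)
  element <- character(n); canonical <- rep(NA_real_, n)
  for (e in raw$elements) {
    i <- e$local_index
    element[i] <- e$element
    if (length(e$canonical) == 1L) canonical[i] <- as.numeric(e$canonical)
  }
  partner <- rep(NA_integer_, n)
  for (p in raw$pairs) {
    partner[p[[1]]] <- p[[2]]; partner[p[[2]]] <- p[[1]]
  }
  tertiary <- lapply(raw$tertiary, function(g) as.numeric(unlist(g)))
  trna_structure(raw$gene_id, element, canonical, partner, tertiary)
}
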