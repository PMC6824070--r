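---
title: "Methods: cross-species analysis of pathogenic mt-tRNA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species analysis of pathogenic mt-tRNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mttrnacomp)
```

## The question and the approach

Human mitochondrial tRNA (mt-tRNA) point mutations cause disease, yet
several of them occur as ordinary population variants in non-human
species that show no disease. If a sheep or a boar carries, at the
homologous site, the very allele that causes myopathy or MERRF in
humans, the surrounding sequence context of that species becomes
informative: compensatory changes at the pairing partner, at tertiary
contact sites, or elsewhere in the molecule may be masking the
pathogenic effect. `mttrnacomp` implements that comparative analysis as
a reproducible pipeline over per-species multiple sequence alignments
that embed a human rCRS-derived reference row.

The stages, in dependency order:

1. **Alignment QC** (`apply_qc`): remove rows whose ungapped length
   deviates from the reference by more than a tolerance, and rows with
   too many unknown bases.
2. **Coordinate mapping** (`to_molecule_position`,
   `alignment_column`): rCRS position to molecule-local index (strand
   aware), then to an alignment column, skipping gaps in the reference
   row.
3. **Cross-species search** (`call_variant`, `summarize_calls`):
   classify each catalogued substitution per species as absent,
   monomorphic (carried by every non-gap sequence) or polymorphic
   (carried by some but not all).
4. **Structure assessment** (`classify_pair`, `assess_secondary`,
   `assess_tertiary`): is Watson-Crick pairing maintained by a change at
   the partner base, and do sites of the nine long-range tertiary
   contacts change alongside?
5. **Clades and networks** (`polymorphic_columns`, `enumerate_clades`,
   `build_network`): group sequences by their haplotype over the gene's
   polymorphic sites and connect the haplotypes in a minimum-spanning
   network.
6. **Scoring and concordance** (`score_pathogenicity`, `crosstabulate`,
   `concordance_metrics`): a configurable Yarham-style evidence rubric,
   compared against an external predictor's labels.

## Conventions that everything else depends on

**Molecule orientation.** Alignments are stored and processed in the
5'→3' orientation of the tRNA molecule. Eight human mt-tRNA genes (Gln,
Ala, Asn, Cys, Tyr, Ser1, Glu, Pro) are encoded opposite to the rCRS
reference strand; for those, `to_molecule_position` reverses the
coordinate (`rcrs_end - pos + 1`) and complements both alleles, so that
e.g. m.5650G>A in mt-tRNA-Ala is handled as the C>U change it is in the
molecule. This is the only convention under which a single gap-aware
column lookup serves all genes uniformly. The internal alphabet uses T,
never U.

**Indexing.** rCRS positions are 1-based (matching variant catalogues);
alignment columns are 0-based. Molecule-local indices are 1-based along
the ungapped reference row.

**Denominators.** A gap at the queried column removes that sequence
from the monomorphic/polymorphic denominator (`n_nongap`); a third
allele or an N counts as "other" and never contributes to the queried
substitution's carrier count. Treating deletions as carriers would
conflate variant types, and the sources of such catalogues track
specific substitutions.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `length_tolerance` | 5 nt | remove rows whose ungapped length differs from the reference by **more than** this |
| `max_unknown` | 5 | remove rows with **at least** this many N |
| `trim_policy` | `"trim-ends"` | rescue rows whose excess is pure terminal overhang |
| `min_minor_allele` | 5 | minor-allele count a focal variant needs in a species before clade analysis |
| conservation threshold | 75 % | panel conservation at or above which the rubric's conservation criterion is awarded |
| rubric weights | 2/2/2/2/2/5/5 | reports, conservation, heteroplasmy, segregation, biochemistry, single-fibre, cybrid |
| rubric cut-points | 7 / 11 / 13 | lower bounds for possibly / probably / definitely |

The length and N thresholds are deliberately asymmetric in strictness
(`> 5` versus `>= 5`): both match the conventions of the QC protocols
this pipeline automates. The original protocols resolved length
outliers by manual inspection; that cannot be encoded, so the automated
rule is: trim when the entire excess lies outside the reference's first
and last non-gap columns (a sequencing overhang), otherwise remove. N
counts are taken on the retained, possibly trimmed sequence, mirroring
what a curator would keep.

The rubric's exact weights and cut-points are configuration, not claims:
published evidence-scoring schemes of this family weight functional
studies (single-fibre, cybrid) most heavily and classify on a four-way
scale, and the defaults reproduce that shape. Any analysis that depends
on the absolute points should ship its own `rubric()` or YAML config.

## Structure annotations are data

Cloverleaf element labels, pairing partners, canonical numbering and
tertiary groups enter as a per-gene JSON annotation; no folding
algorithm runs anywhere. `cloverleaf_template()` generates schematic
annotations: standard layout (acceptor 7 bp, D-arm 4 bp/8 nt, anticodon
5 bp/7 nt, T-arm 5 bp/7 nt, discriminator), canonical 1-76 numbering,
stems shrunk to no fewer than 3 bp for short genes, variable region
absorbing the slack. These are schematic templates, not curated
experimental structures - adequate for exercising the assessment logic
and for synthetic data, and replaceable by curated annotations through
the same JSON interface for real analyses.

The nine default tertiary groups (canonical numbering) are {8,14},
{9,23}, {10,25,45}, {13,22,46}, {15,48}, {18,55}, {19,56}, {26,44},
{54,58} - the standard long-range contact set that folds the cloverleaf
into its L-shape; all nine are overridable per gene in the JSON.

"Changed" at a partner or tertiary site means any non-gap, non-N
deviation from the reference base, assessed within the variant-carrying
sequences for polymorphic species and within all sequences for
monomorphic species. Carrier-restricted assessment is the only
well-defined choice for polymorphic species: the question is what
context accompanies the variant, and non-carrier rows carry no variant
to accompany. The All/Some/None trichotomy is then taken across
species.

## Clades and the network stand-in

A clade is a set of sequences sharing an identical base string over the
gene's polymorphic columns (minor-allele count >= 1 by default; gaps and
N are not alleles). Rows with a gap or N at any clade-defining column
cannot be assigned a fully observed haplotype; they are set aside and
reported rather than silently dropped. Clades sort by descending
frequency, ties broken lexicographically, so output order is
deterministic.

Median-joining network software commonly used for this analysis is
proprietary; the package builds a **minimum-spanning network** instead:
Kruskal's MST under Hamming distance with lexicographic tie-breaking,
plus every non-tree edge whose distance equals the maximum edge weight
on the tree path between its endpoints (equivalently: all edges that
belong to some MST). That retains the tie structure a median-joining
display would show, is fully deterministic, and the node/edge tables are
exported as TSV for external tools. Median vectors (inferred unsampled
haplotypes) are deliberately out of scope.

## The conservation index

`conservation_index` is the percentage of non-reference panel rows
whose base at the mapped column equals the rCRS base, among rows with a
non-gap base there, reported to 2 decimals. The same formula applies to
any panel: a nine-genome reference panel gives the coarse-grained index
used during rubric scoring, and nothing in the implementation assumes a
panel size.

## The synthetic data generator

`simulate_dataset()` exists so that every stage is testable without
downloads, with exact truth labels. Its defaults are the study-like
conditions: 33 species x 22 genes (726 alignments), 20-400 sequences
per alignment, gene lengths 59-75 nt, two planted variants per gene,
partner compensation probability 0.5 and tertiary-change probability
0.3 per carrier species, three co-segregating clade columns splitting
rows into five groups, at most two gap columns per alignment (one
deletion-style, one insertion column gapping the reference row), and no
QC noise unless requested.

Design choices that make truth exact rather than stochastic:

- **Carrier sets are deterministic**: exactly `round(fraction * n)`
  rows after a seeded shuffle (all rows at fraction 1), so a planted
  "9 of 94" is exactly 9 of 94.
- **QC noise rows are appended extras**, never mutations of planted
  rows, so planted carrier counts survive QC untouched.
- **Clade columns co-segregate** in binary block patterns, with the
  constraint `2^(n_columns-1) < n_groups <= 2^n_columns` so every clade
  column is genuinely polymorphic.
- **Reference-gap insertion columns carry one shared base**, so they
  never register as polymorphic columns.
- **Planted sites are protected**: no gap column ever lands on a
  variant site, its partner, a tertiary site or a clade column.
- A validator re-reads the emitted FASTA at generation time and
  recounts every planted carrier; generation aborts on any mismatch.

What the generator does **not** emulate: phylogenetically realistic
substitution processes (no evolutionary model), alignment errors,
heteroplasmy within individuals, indel variants, or base-quality
artefacts. Passing tests therefore demonstrate pipeline correctness -
exact bookkeeping, coordinate arithmetic, classification logic - not
robustness to real-data pathologies such as misalignment.

## Numerical and degenerate-input choices

- Filter order in QC cannot change the outcome (both criteria are
  row-local); the implementation applies length first, then N, and a
  property test asserts order invariance.
- An alignment reduced to its reference row by QC is a warning, not an
  error; downstream calls on it return `absent` with `n_nongap = 0` and
  a warning.
- `classify_pair` returns `unpaired` with an `indeterminate` flag when
  either side is N or gap.
- Zero denominators in concordance metrics yield `NA` with a warning
  rather than an error, so partial tables still report the defined
  metric.
- All result tables are written with fixed column order, deterministic
  row sort (gene, position, species) and '.' decimals; re-running a
  stage on identical input is byte-identical.

## Problem sizes in the shipped checks

The test suite and the acceptance script size their simulations to run
comfortably on a single core: the 726-alignment generation uses 20-40
sequences per alignment; planted-status recovery checks 500
variant-species pairs (10 species x 5 genes x 10 variants); the
exhaustive spanning-tree oracle runs on complete graphs of up to 8
haplotypes; coordinate-mapping equivalence samples 1,000 random gap
patterns. These sizes are the package's choices for its own continuous
verification; all of them scale up through the same parameters.

## Known limitations

- The shipped per-gene structure templates are schematic; conclusions
  about a specific real gene's pairing geometry require curated
  annotations supplied through the structure JSON.
- The rubric is structurally faithful but its default points are
  configuration; absolute scores should not be compared across
  differently configured runs.
- The minimum-spanning network is a reproducible stand-in, not a
  median-joining network; it never infers unsampled haplotypes.
- Species-row insertions relative to the reference are not assigned
  rCRS coordinates; the pipeline reports the aligned column only.
- Heteroplasmy and indels are out of scope throughout.
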