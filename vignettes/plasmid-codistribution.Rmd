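---
title: "Methods: annotating and quantifying ARG–HRG co-distribution on plasmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and quantifying ARG–HRG co-distribution on plasmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidcodist)
```

## Scope and model

The package quantifies how tightly antibiotic resistance genes (ARGs) and
mercury-related genes (HRGs: the *mer* operon genes plus the *hgcAB*
methylation pair) co-occur on plasmid genomes. Its unit of analysis is the
annotated plasmid: an ordered list of protein-coding genes with 1-based
inclusive coordinates, a replicon length and topology, and host metadata.
All downstream statistics are functions of (a) which genes are HRGs or
ARGs and (b) either the *gene order* (cluster detection) or the *base-pair
geometry* (distance statistics) of those genes.

Annotation is similarity-search based: the package consumes tabular
protein-hit tables (the standard 12-column BLASTP/DIAMOND format, plus
query/subject lengths) rather than running an aligner itself. That keeps
the statistical pipeline deterministic and testable; any aligner producing
the tabular format can feed it.

## Annotation rules and their parameters

* **Stringent acceptance** (mer genes and ARGs): e-value ≤ 1e-5, identity
  ≥ 80 %, coverage ≥ 90 %. All three bounds are inclusive, exactly as
  printed thresholds are conventionally read. These are the standard
  resistome-annotation cutoffs; they are exposed through
  `filter_criteria()` for sensitivity analysis.
* **Coverage definition.** Tabular hit formats do not carry a coverage
  column, and "coverage" is ambiguous between query- and subject-side. The
  package uses alignment length over *query* length (the plasmid protein),
  capped at 100 % — the common resistome convention, which prevents short
  reference fragments from inflating calls. Subject-side coverage is
  available via `coverage_of(side = "subject")`.
* **Best hit per gene.** Each gene receives at most one assignment per
  category (a gene may be both an HRG and an ARG — the categories are
  independent). Ties on bit score break by smaller e-value, larger
  identity, then lexicographic subject id, so annotation is deterministic.
* **hgcAB path.** Plasmid *hgcA*/*hgcB* homologs are too divergent for the
  identity/coverage bounds, so they travel a lenient path (e-value only),
  compensated by two structural screens: *hgcA* must contain the cap-helix
  motif `G[IV]NVWC[ASG][ASG]GK` (18 admissible variants, tested by
  exhaustive enumeration), and *hgcB* survives only with a retained *hgcA*
  at most 2 genes away. The "near" bound reuses the cluster gap constant;
  it is configurable (`max_sep_genes`). A candidate *hgcA* without a
  supplied protein sequence is discarded rather than passed unchecked.
* **ARG class harmonization.** Secondary catalogues are aligned to the
  primary catalogue's class vocabulary in two passes — exact ARG-name
  match, then propagation of any class renaming established by the first
  pass — with a stringent similarity search as the final fallback and
  `"unmatched"` as the residual class. If one raw class name was renamed
  to several different primary classes in pass one, propagation uses the
  most frequent target (ties lexicographic); the inputs seen in practice
  do not exercise this corner, but the rule must be total and
  deterministic. The procedure is idempotent, which is property-tested.

## Cluster detection and naming

An HRG cluster is at least two HRGs adjacent in gene order or separated by
at most `gap_max = 2` other genes. The rule is purely rank-based — it
counts genes, not base pairs — because the definition of "separated by two
other genes" is an ordinal statement. Clusters are maximal runs under that
relation, trimmed so both ends are HRGs; singleton HRGs are not clusters.

The canonical type string lists, in reading order, HRG gene names with one
`X` per intervening gene. Reading order follows the strand majority of the
cluster's HRGs: plus-strand clusters read in rank order, minus-strand
clusters reversed (so operons read promoter-first, the order operon names
are conventionally written in). A strand tie is resolved to the
lexicographically smaller orientation — an arbitrary but deterministic
choice; the partition itself is invariant under reversing a whole plasmid,
which is property-tested. Incidences are counted per occurrence, not per
plasmid: a plasmid carrying two identical clusters contributes two.

## Distance statistics

* **Physical genetic distance** is the number of base pairs strictly
  between two gene extents; overlapping or abutting genes are at distance
  0. This makes "ARG adjacent to HRG" read as ~0 bp, the natural notion of
  co-localization. Midpoint conventions would add half the gene lengths to
  every distance and blur the adjacent case.
* **Topology.** Distances are linear by default. A circular-aware mode
  (minimum of the direct gap and the gap around the origin) exists and is
  tested, but is off by default: annotation pipelines typically emit
  linearized coordinates and there is no evidence the dataset-scale
  statistics used circular arithmetic. The choice only matters for gene
  pairs flanking the origin.
* **A-H-incidence_ave.** For thresholds 0, 200, …, 100 000 bp (501 grid
  points, endpoints inclusive), the curve value is the number of ARGs
  whose minimum distance to any HRG on their plasmid is ≤ the threshold,
  summed over plasmids and divided by the number of contributing plasmids.
  Only plasmids with both categories contribute; each ARG counts at most
  once per threshold (the statistic counts ARGs, not ARG–HRG pairs). The
  curve is non-decreasing by construction.
* **A-H-distance_min.** Per plasmid: the minimum pairwise distance, also
  broken down per ARG class. The HRG de-redundancy step (each HRG class
  represented once) is implemented as a per-ARG-class instance selection,
  which provably cannot change a minimum; it is property-tested against
  the plain pair minimum. The naive global variant — keeping one HRG
  instance per class for the whole plasmid — *can* distort per-class
  minima when an HRG class recurs in two clusters, which is why the
  selection is scoped per ARG class.
* **Nearest-class preference.** Each dual-bearing plasmid votes for the
  ARG class achieving its plasmid minimum after removing excluded classes
  (default: multidrug, whose efflux systems are so widespread they would
  swamp the tally). Distance ties between classes go to the
  lexicographically smallest name and are reported via `message()`; the
  tally records how many plasmids contributed.

## Group comparisons

Host-source categories (human, animal, wastewater and sludge,
miscellaneous sources, NA) are assigned by the first matching keyword rule
in a shipped, editable YAML file; rule order is the precedence order.
Nonempty metadata matching nothing falls back to miscellaneous; plasmids
with no metadata are NA and are excluded from grouped statistics, never
silently defaulted. Pathogenicity is a static species → label snapshot
(the live pathogen registries are not desk-reproducible).

The Kruskal–Wallis H (tie-corrected, chi-square p on k−1 df), the Wilcoxon
rank-sum test (normal approximation with tie and continuity correction)
and the Spearman coefficient (midranks, t-approximation p) are implemented
directly and validated in the test suite against the corresponding `stats`
reference implementations to 1e-9 on random data — a deliberate dual
route, so the package's reported statistics are both self-contained and
independently checked. Degenerate inputs are handled explicitly: identical
values give H = 0, p = 1; constant input leaves Spearman undefined and
flagged rather than fabricated. Pairwise rank-sum tests run only after the
Kruskal–Wallis gate (p < 0.05, configurable). Significance bands follow
the four-star figure convention (0.05/0.01/0.001/0.0001).

Percentages in all report tables are rounded half-up to two decimals, the
convention used in published count tables; `round()`'s banker's rounding
would differ on exact halves.

## What the generator emulates — and what it does not

`simulate_dataset()` produces gene tables, hit tables and metadata with a
ground-truth manifest. Its defaults are the study conditions the package
is meant to operate under:

* plasmid lengths log-uniform on 5–1100 kb (the observed range of
  HRG-bearing plasmids);
* cluster types drawn from the published-style incidence spectrum (the 24
  most common types with their relative frequencies); 0–2 clusters per
  plasmid plus occasional singleton HRGs, giving up to ~24 HRGs per
  plasmid;
* ARGs planted at a point-mass 500 bp from the nearest cluster edge (at
  most two per cluster — one per side — so every planted distance is
  exact); class frequencies follow the observed class distribution, with
  a multidrug mass to exercise the exclusion rule;
* host-source mix proportional to the observed cohort (≈52 % human, 14 %
  animal, 8 % wastewater and sludge, 9 % miscellaneous, 16 % NA);
* a size–HRG Spearman association with target ρ = 0.30, planted by
  rank-coupling lengths to per-plasmid HRG counts; the mixing weight is
  calibrated by bisection on the drawn sample so the realized coefficient
  matches the target despite the heavy ties in HRG counts;
* hit noise: a fraction of filler genes receive decoy hits, each violating
  exactly one stringent criterion (identity 70–79.9, coverage 50–89.9, or
  e-value > 1e-5, cycled deterministically), so every filter predicate is
  exercised; all true hits pass all criteria.

Planted clusters are separated by more than `gap_max` filler genes, so
detection is unambiguous and recovery can be asserted exactly. A
cluster-free plasmid never carries both standalone ARGs and a singleton
HRG, so every dual-bearing plasmid owes its distances to planted offsets.

The generator deliberately does **not** emulate: nucleotide sequence
content (hits are synthesized, not aligned), mobile-element context
(transposons, integrons), gene-content correlations beyond the planted
size–HRG association, plasmid copy number, or taxonomic structure beyond a
small genus pool. Passing recovery tests therefore demonstrates the
correctness of the statistical machinery under known truth — not that any
particular biological dataset satisfies the generator's assumptions.
Dataset-scale observational quantities (medians of minimum distances,
group-difference p-values on real cohorts) depend on the real data and are
not asserted anywhere in the package.

## Numerical and engineering choices

* Coordinates are 1-based inclusive throughout (GenBank convention); one
  convention end to end avoids off-by-one drift. Compound GenBank
  locations (`join`, `complement(join(...))`) collapse to their min–max
  extent with strand from the complement flag — only gene order and extent
  matter downstream.
* Gene ranks are 0-based, sorted by start with end/id tie-breaks, so rank
  arithmetic is deterministic even for pathological coordinate ties.
* The GenBank reader is a purpose-built flat-file parser covering LOCUS
  topology/length, source qualifiers and CDS features (it is validated
  against an independent parser on the shipped fixture); records with
  irreparably inverted coordinates are skipped with a warning rather than
  aborting a batch.
* All randomness flows through a single integer seed; the generator is
  byte-deterministic given its configuration.
* Problem sizes used by the shipped tests and the acceptance script: 500
  random instances of ≤ 20 genes for the brute-force oracle comparisons,
  100 random datasets for the statistical-test oracles, and a
  1000-plasmid simulation for end-to-end parameter recovery.

## Known limitations

* Annotation quality is bounded by the hit tables and catalogues supplied;
  the package adds no remote lookups and never invents metadata.
* The hgcB pairing rule uses gene-rank distance, not base pairs; a
  rank-adjacent but physically distant pair (huge intervening gene) would
  still pass.
* Class harmonization trusts exact name equality; orthographic variants of
  the same ARG name ("TEM-1" vs "TEM1") fall through to the similarity
  fallback.
* The host-source keyword rules are intentionally simple substring
  matches; ambiguous metadata ("human wastewater") resolves by category
  precedence, which is the documented, editable behavior.
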