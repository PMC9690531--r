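# plasmidcodist

Plasmid resistome annotation and mercury–antibiotic resistance gene
co-distribution analysis.

## The problem

Mercury pollution exerts a selective pressure that can co-select for
antibiotic resistance: on plasmids, mercury-related genes (HRGs — the *mer*
detoxification operon genes *merA/B/C/D/E/F/G/P/R/T* and the *hgcAB*
methylation pair) are frequently linked physically to antibiotic resistance
genes (ARGs), so a single selective agent can drive the spread of both.
Quantifying that linkage across thousands of plasmid genomes requires a
reproducible pipeline: annotate both gene categories from similarity-search
hits under explicit thresholds, characterize the architecture of *mer* gene
clusters, and measure how tightly ARGs and HRGs co-occur in physical
genomic distance.

This package implements that pipeline for microbial genomics researchers
studying co-selection on mobile genetic elements. It covers:

* **Input handling** — GenBank flat files or plain gene tables, plus
  tabular (BLAST/DIAMOND-style, 12- or 14-column) protein hit tables and
  SARG-shaped reference catalogues (`FASTA` + `class__name` list file).
* **Annotation** — stringent hit filtering (e-value ≤ 1e-5, identity ≥ 80 %,
  coverage ≥ 90 %, all inclusive; coverage = alignment length / query
  length, capped at 100 %), best-hit-per-gene selection, the lenient
  *hgcAB* path with the HgcA cap-helix motif screen
  `G(I/V)NVWC(A/S/G)(A/S/G)GK` and the *hgcB*-near-*hgcA* pairing rule, and
  two-step ARG class-name harmonization across catalogues with a
  similarity-search fallback.
* **Cluster typing** — an HRG cluster is ≥ 2 HRGs adjacent in gene order or
  separated by ≤ 2 other genes; each cluster gets a canonical hyphen-joined
  type string (gene names, `X` per intervening gene, minus-strand operons
  read promoter-first), tallied into an incidence spectrum.
* **Co-distribution statistics** — for plasmids carrying both categories:
  the *A-H-incidence_ave* curve (average number of ARGs within *d* bp of an
  HRG, *d* = 0…100 kb in 200 bp steps), the per-plasmid *A-H-distance_min*
  (minimum ARG–HRG distance, also per ARG class), and the nearest-ARG-class
  preference tally (multidrug excluded by default). Distance is the number
  of bp strictly between gene extents; overlap counts as 0.
* **Cohort comparisons** — host-source classification (human / animal /
  wastewater and sludge / miscellaneous sources / NA) from editable YAML
  keyword rules, pathogenicity lookup from a static species map,
  Kruskal–Wallis and Wilcoxon rank-sum tests (tie-corrected, validated
  against the stats reference implementations), Spearman correlation, and
  Table-style report generators.
* **Synthetic data** — a seeded generator that plants cluster types, ARG
  offsets, host-source mixes and a size–HRG association, emitting a
  ground-truth manifest so every pipeline stage is testable end to end
  without any external download.

## Worked example

The packaged three-plasmid toy dataset has hand-checkable properties:

```r
library(plasmidcodist)
tw <- toy_worked_example()

ct <- cluster_table(tw$records, tw$assignments)
ct
#>   plasmid_id start_rank end_rank n_hrg span_bp                     type_string
#> 1         pA          0        6     6    7600 merR-merT-merP-X-merA-merD-merE
#> 2         pB          0        2     3    3200                  merA-merD-merE
```

Plasmid `pA` carries the canonical seven-token operon (one non-HRG gene
inside, hence the `X`); `pB` carries `merA-merD-merE` laid on the minus
strand — the type string reads promoter-first regardless. `pC`'s lone
*merA* is not a cluster, so 9 of the 10 HRGs are clustered:

```r
clustered_fraction(tw$records, tw$assignments)
#> [1] 90

r <- ah_distance_min(tw$records[["pA"]], tw$assignments)
r$per_arg_class_min
#>  sulfonamide tetracycline
#>          500         5000
r$plasmid_min
#> [1] 500
```

On `pA` the sulfonamide ARG sits 500 bp from the nearest HRG and the
tetracycline ARG 5000 bp away, so the plasmid minimum is 500 bp and `pA`'s
nearest ARG class is sulfonamide. Across the three plasmids:

```r
nearest_class_preference(tw$records, tw$assignments)
#>        arg_class plasmid_count percent
#> 1 aminoglycoside             1   33.33
#> 2    beta-lactam             1   33.33
#> 3    sulfonamide             1   33.33

ah_incidence_curve(tw$records, tw$assignments)
#> <incidence_curve> 'all': 501 thresholds, 3 plasmids, value(max) = 1.333
```

The full pipeline runs the same way on real inputs: `parse_genbank()` or
`read_gene_table()` for the plasmids, `read_hit_table()` for the similarity
hits, `read_sarg_catalogue()` / `bacmet_keyword_catalogue()` for the
references, then `annotate_dataset()` feeding `cluster_table()`,
`min_distance_table()`, `ah_incidence_curve()`, `group_curves()` and the
report functions (`taxonomic_summary()`, `headline_ratios()`).

## Package layout

* `R/plasmid_io.R` — GenBank/tabular readers, data model, writers
* `R/annotation.R` — hit filtering, motif/pairing rules, catalogues, class
  harmonization, dataset annotation
* `R/cluster_typing.R` — cluster detection, canonical naming, spectra
* `R/codistribution.R` — distances, incidence curves, minima, preference
* `R/cohort_summary.R` — host-source/pathogenicity classification, rank
  tests, report tables
* `R/synthetic_data.R` — seeded generator, fixtures, worked example
* `vignettes/plasmid-codistribution.Rmd` — methods and design notes
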