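Package: plasmidcodist
Title: Plasmid Resistome Annotation and Mercury-Antibiotic Resistance Gene
    Co-Distribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates mercury-related genes (mer operon and hgcAB) and
    antibiotic resistance genes on plasmid genomes from protein
    similarity-search hit tables, detects mer gene clusters and their
    canonical architecture types, and quantifies the physical co-distribution
    of antibiotic and mercury resistance genes with incidence-by-distance
    curves, per-plasmid minimum-distance statistics and nearest-class
    preference tallies. Includes host-source and pathogenicity group
    comparisons (Kruskal-Wallis, Wilcoxon rank-sum, Spearman) and a
    synthetic-plasmid generator with a planted ground-truth manifest for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
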