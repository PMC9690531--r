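test_that("coverage is alignment length over query length, capped at 100", {
  expect_equal(coverage_of(mk_hit(aln_len = 90, qlen = 100)), 90)
  expect_equal(coverage_of(mk_hit(aln_len = 100, qlen = 100)), 100)
  expect_equal(coverage_of(mk_hit(aln_len = 120, qlen = 100)), 100)
  expect_equal(coverage_of(mk_hit(aln_len = 90, qlen = 100, slen = 200),
                           side = "subject"), 45)
  set.seed(1)
  h <- random_hits(200)
  expect_equal(coverage_of(h), pmin(100, 100 * h$aln_len / h$qlen))
})

test_that("filter thresholds are inclusive and lenient mode drops only on e-value", {
  boundary <- mk_hit(identity = 80.0, aln_len = 90, qlen = 100,
                     evalue = 1e-5)
  expect_equal(nrow(filter_hits(boundary)), 1L)
  expect_equal(nrow(filter_hits(mk_hit(identity = 79.9, aln_len = 95,
                                       qlen = 100, evalue = 1e-10))), 0L)
  expect_equal(nrow(filter_hits(mk_hit(identity = 90, aln_len = 89,
                                       qlen = 100, evalue = 1e-10))), 0L)
  expect_equal(nrow(filter_hits(mk_hit(identity = 90, aln_len = 95,
                                       qlen = 100, evalue = 1.1e-5))), 0L)
  lenient <- filter_criteria("lenient")
  expect_equal(nrow(filter_hits(mk_hit(identity = 20, aln_len = 10,
                                       qlen = 100, evalue = 1e-6),
                                lenient)), 1L)
  expect_equal(nrow(filter_hits(mk_hit(evalue = 1e-4), lenient)), 0L)
})

test_that("filtering equals a brute-force re-scan and is monotone", {
  set.seed(7)
  for (rep_i in 1:5) {
    h <- random_hits(1000)
    crit <- filter_criteria("stringent")
    kept <- filter_hits(h, crit)
    manual <- h[h$evalue <= 1e-5 & h$identity_pct >= 80 &
                  pmin(100, 100 * h$aln_len / h$qlen) >= 90, ]
    expect_equal(kept, manual)
    # relaxing any threshold never shrinks the kept set
    relaxed <- filter_hits(h, filter_criteria("stringent",
                                              min_identity_pct = 60))
    expect_true(all(rownames(kept) %in% rownames(relaxed)))
    # stringent is a subset of lenient at equal e-value bound
    len_kept <- filter_hits(h, filter_criteria("lenient"))
    expect_true(all(rownames(kept) %in% rownames(len_kept)))
  }
})

test_that("best hit maximizes bitscore with the documented tie order", {
  h <- rbind(mk_hit(subject_id = "a", bitscore = 150),
             mk_hit(subject_id = "b", bitscore = 200))
  expect_equal(best_hit_per_gene(h)$subject_id, "b")
  # brute-force comparison on random tied/untied sets
  set.seed(11)
  for (rep_i in 1:50) {
    h <- random_hits(sample(2:30, 1), queries = paste0("g", 1:3))
    h$bitscore <- sample(c(100, 200, 300), nrow(h), replace = TRUE)
    h$evalue <- sample(c(1e-10, 1e-20), nrow(h), replace = TRUE)
    got <- best_hit_per_gene(h)
    for (q in unique(h$query_id)) {
      sub <- h[h$query_id == q, ]
      sub <- sub[order(-sub$bitscore, sub$evalue, -sub$identity_pct,
                       sub$subject_id), ]
      expect_equal(got[got$query_id == q, , drop = FALSE][1, ],
                   sub[1, ], ignore_attr = TRUE)
    }
  }
})

test_that("hgcA motif matches exactly the 18-variant degenerate alphabet", {
  expect_true(hgca_motif_present("MKTGINVWCAAGKLL"))
  expect_false(hgca_motif_present("MKTGLNVWCAAGKLL"))
  variants <- expand.grid(p2 = c("I", "V"), p7 = c("A", "S", "G"),
                          p8 = c("A", "S", "G"), stringsAsFactors = FALSE)
  expect_equal(nrow(variants), 18L)
  set.seed(3)
  flank <- function() paste(sample(LETTERS[1:20], 8, replace = TRUE),
                            collapse = "")
  for (i in seq_len(nrow(variants))) {
    core <- paste0("G", variants$p2[i], "NVWC", variants$p7[i],
                   variants$p8[i], "GK")
    expect_true(hgca_motif_present(paste0(flank(), core, flank())))
    # spoil one constrained position per variant
    spoiled <- core
    substr(spoiled, 2, 2) <- "W"
    expect_false(hgca_motif_present(paste0("MMM", spoiled, "MMM")))
  }
})

test_that("hgcB candidates survive only near a retained hgcA", {
  toks <- c("o", "o", "o", "o", "o", "hgcA", "hgcB", "o", "o", "o", "hgcB")
  p <- mk_plasmid(toks)
  cand <- data.frame(gene_id = p$genes$gene_id[c(6, 7, 11)],
                     gene_name = c("hgcA", "hgcB", "hgcB"),
                     stringsAsFactors = FALSE)
  kept <- validate_hgcab(cand, p, max_sep_genes = 2L)
  expect_equal(kept$gene_id, p$genes$gene_id[c(6, 7)])
  # lone hgcB with no hgcA on the plasmid is always discarded
  lone <- cand[cand$gene_name == "hgcB", ]
  expect_equal(nrow(validate_hgcab(lone, p, 2L)), 0L)
  # hgcB at rank 10 with nearest hgcA at rank 3 exceeds the bound
  p2 <- mk_plasmid(rep("o", 12))
  cand2 <- data.frame(gene_id = p2$genes$gene_id[c(4, 11)],
                      gene_name = c("hgcA", "hgcB"),
                      stringsAsFactors = FALSE)
  expect_equal(validate_hgcab(cand2, p2, 2L)$gene_name, "hgcA")
})

test_that("ARG class harmonization applies name-match then class-propagation", {
  primary <- data.frame(class_name = c("beta-lactam", "sulfonamide"),
                        arg_name = c("TEM-1", "sul1"),
                        ids = c("P1", "P2"), stringsAsFactors = FALSE)
  other <- data.frame(class_name = c("beta_lactamase", "beta_lactamase",
                                     "weird_class"),
                      arg_name = c("TEM-1", "NEW-99", "orphan"),
                      ids = c("C1", "C2", "C3"), stringsAsFactors = FALSE)
  m <- harmonize_arg_classes(primary, list(card = other))
  expect_equal(m$class_name_harmonized[m$arg_name == "TEM-1"], "beta-lactam")
  expect_equal(m$rule_applied[m$arg_name == "TEM-1"], "name-match")
  expect_equal(m$class_name_harmonized[m$arg_name == "NEW-99"], "beta-lactam")
  expect_equal(m$rule_applied[m$arg_name == "NEW-99"], "class-propagation")
  expect_equal(m$rule_applied[m$arg_name == "orphan"], "similarity-fallback")
  # ambiguity: one ARG name under two primary classes is an error
  bad_primary <- rbind(primary, data.frame(class_name = "quinolone",
                                           arg_name = "TEM-1", ids = "P3"))
  expect_error(harmonize_arg_classes(bad_primary, list(card = other)),
               "multiple primary classes")
})

test_that("harmonization is idempotent on its own output", {
  primary <- data.frame(class_name = c("beta-lactam", "sulfonamide"),
                        arg_name = c("TEM-1", "sul1"), ids = c("P1", "P2"),
                        stringsAsFactors = FALSE)
  other <- data.frame(class_name = c("beta_lactamase", "beta_lactamase",
                                     "sulphonamides"),
                      arg_name = c("TEM-1", "NEW-99", "sul1"),
                      ids = c("C1", "C2", "C3"), stringsAsFactors = FALSE)
  m1 <- harmonize_arg_classes(primary, list(db = other))
  other2 <- data.frame(class_name = m1$class_name_harmonized,
                       arg_name = m1$arg_name, ids = other$ids,
                       stringsAsFactors = FALSE)
  m2 <- harmonize_arg_classes(primary, list(db = other2))
  expect_equal(m2$class_name_harmonized, m1$class_name_harmonized)
})

test_that("similarity fallback assigns the best surviving hit's class", {
  cat_ <- reference_catalogue(data.frame(
    subject_id = c("S1", "S2"), gene_name = c("sul1", "tetA"),
    class_label = c("sulfonamide", "tetracycline"),
    stringsAsFactors = FALSE))
  hits <- rbind(mk_hit("argA", "S1", identity = 95, aln_len = 95),
                mk_hit("argB", "S2", identity = 60, aln_len = 95))
  out <- fallback_class_assignment(c("argA", "argB", "argC"), cat_, hits)
  expect_equal(out$class_name_harmonized,
               c("sulfonamide", "unmatched", "unmatched"))
  expect_equal(out$rule_applied,
               c("similarity-fallback", "unmatched", "unmatched"))
  # random fixture equals brute-force filter + argmax oracle
  set.seed(5)
  h <- random_hits(200, queries = paste0("arg", 1:20))
  h$subject_id <- sample(c("S1", "S2"), 200, replace = TRUE)
  out <- fallback_class_assignment(paste0("arg", 1:20), cat_, h)
  keep <- h[h$evalue <= 1e-5 & h$identity_pct >= 80 &
              pmin(100, 100 * h$aln_len / h$qlen) >= 90, ]
  for (q in out$arg_name) {
    sub <- keep[keep$query_id == q, ]
    expected <- if (!nrow(sub)) "unmatched" else {
      sub <- sub[order(-sub$bitscore, sub$evalue, -sub$identity_pct,
                       sub$subject_id), ]
      c(S1 = "sulfonamide", S2 = "tetracycline")[[sub$subject_id[1]]]
    }
    expect_equal(out$class_name_harmonized[out$arg_name == q], expected)
  }
})

test_that("catalogue readers parse the SARG-like shape", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">S1 dihydropteroate synthase", "MKT",
               ">S2 tet efflux", "MAA", ">S3 tet efflux variant", "MCC"), fa)
  lf <- tempfile(fileext = ".txt")
  writeLines(c("sulfonamide__sul1\tS1", "tetracycline__tetA\tS2,S3"), lf)
  cat_ <- read_sarg_catalogue(fa, lf, source_db = "sarg")
  expect_equal(nrow(cat_), 3L)
  expect_equal(cat_$class_label, c("sulfonamide", "tetracycline",
                                   "tetracycline"))
  expect_equal(cat_$gene_name[2:3], c("tetA", "tetA"))
  # class and name split on the FIRST double underscore
  lf2 <- tempfile(); writeLines("beta_lactam__TEM_1\tS1", lf2)
  rows <- parse_arg_list(lf2)
  expect_equal(rows$class_name, "beta_lactam")
  expect_equal(rows$arg_name, "TEM_1")
  expect_error(read_sarg_catalogue(fa, {
    lf3 <- tempfile(); writeLines("x__y\tMISSING", lf3); lf3
  }), "absent from FASTA")
})

test_that("BacMet keyword extraction selects mercury rows only", {
  mf <- tempfile(fileext = ".tsv")
  writeLines(c("BacMet_ID\tGene_name\tCompound",
               "BAC1\tmerA\tMercury (Hg)",
               "BAC2\tarsB\tArsenic (As)",
               "BAC3\tmerT\tmercury"), mf)
  cat_ <- bacmet_keyword_catalogue(mf)
  expect_equal(cat_$subject_id, c("BAC1", "BAC3"))
  expect_equal(cat_$gene_name, c("merA", "merT"))
})

test_that("hit table reader accepts 14 columns or 12 + lengths sidecar", {
  tf <- tempfile()
  write.table(mk_hit("g1", "s1")[, 1:12], tf, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_hit_table(tf), "lengths TSV is required")
  lenf <- tempfile()
  writeLines(c("seq_id\tlength", "g1\t100", "s1\t100"), lenf)
  h <- read_hit_table(tf, lenf)
  expect_equal(h$qlen, 100L)
  tf2 <- tempfile()
  write.table(mk_hit("g1", "s1"), tf2, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_equal(read_hit_table(tf2)$slen, 100L)
})

test_that("annotate_dataset assigns categories independently and validates ids", {
  p <- mk_plasmid(c("merA", "o"))
  recs <- plasmid_set(list(p))
  hrg_cat <- example_hrg_catalogue()
  arg_cat <- example_arg_catalogue()
  merA_id <- hrg_cat$subject_id[hrg_cat$gene_name == "merA"]
  sul1_id <- arg_cat$subject_id[arg_cat$gene_name == "sul1"]
  g1 <- p$genes$gene_id[1]
  hrg_hits <- mk_hit(g1, merA_id, identity = 95, aln_len = 99, qlen = 100)
  arg_hits <- mk_hit(g1, sul1_id, identity = 92, aln_len = 99, qlen = 100)
  asn <- annotate_dataset(recs, hrg_hits, arg_hits, hrg_cat, arg_cat)
  expect_equal(nrow(asn), 2L)
  expect_setequal(asn$category, c("HRG", "ARG"))
  expect_equal(asn$gene_name[asn$category == "HRG"], "merA")
  expect_equal(asn$class_label[asn$category == "ARG"], "sulfonamide")
  expect_error(
    annotate_dataset(recs, mk_hit("ghost", merA_id), NULL, hrg_cat),
    "unknown gene id.*ghost")
})

test_that("hgcA requires the motif and hgcB requires a nearby valid hgcA", {
  hrg_cat <- example_hrg_catalogue()
  idA <- hrg_cat$subject_id[hrg_cat$gene_name == "hgcA"]
  idB <- hrg_cat$subject_id[hrg_cat$gene_name == "hgcB"]
  p <- mk_plasmid(c("hgcA", "hgcB", "o", "o", "o", "o", "hgcB"))
  recs <- plasmid_set(list(p))
  ids <- p$genes$gene_id
  hits <- rbind(mk_hit(ids[1], idA, identity = 40, aln_len = 50),
                mk_hit(ids[2], idB, identity = 45, aln_len = 50),
                mk_hit(ids[7], idB, identity = 45, aln_len = 50))
  seqs <- c("MGGINVWCAAGKPP")
  names(seqs) <- ids[1]
  asn <- annotate_dataset(recs, hits, NULL, hrg_cat,
                          protein_seqs = seqs)
  # hgcA with motif kept; adjacent hgcB kept; distant hgcB dropped
  expect_equal(asn$gene_name, c("hgcA", "hgcB"))
  expect_equal(asn$gene_id, ids[1:2])
  # without the motif, hgcA falls and takes every hgcB with it
  seqs_bad <- c("MGGLNVWCAAGKPP"); names(seqs_bad) <- ids[1]
  asn2 <- annotate_dataset(recs, hits, NULL, hrg_cat,
                           protein_seqs = seqs_bad)
  expect_equal(nrow(asn2), 0L)
  # missing protein sequence is treated as motif-absent
  asn3 <- annotate_dataset(recs, hits, NULL, hrg_cat)
  expect_equal(nrow(asn3), 0L)
})
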