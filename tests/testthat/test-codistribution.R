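test_that("feature distance is the strict between-gap, circular-aware on demand", {
  p <- plasmid_record("p", data.frame(
    gene_id = c("h", "a"), start = c(1001L, 2501L), end = c(2000L, 3000L),
    strand = 1L, product = ""), length_bp = 10000L)
  g <- p$genes
  expect_equal(feature_distance(g[1, ], g[2, ], p), 500L)
  expect_equal(feature_distance(g[2, ], g[1, ], p), 500L)
  # overlap and abutment give 0
  ov <- data.frame(start = 1500L, end = 2500L)
  expect_equal(feature_distance(g[1, ], ov, p), 0L)
  ab <- data.frame(start = 2001L, end = 2500L)
  expect_equal(feature_distance(g[1, ], ab, p), 0L)
  # circular wrap: features flanking the origin touch across it
  pc <- plasmid_record("pc", data.frame(
    gene_id = c("x", "y"), start = c(1L, 9901L), end = c(100L, 10000L),
    strand = 1L, product = ""), length_bp = 10000L, topology = "circular")
  gc_ <- pc$genes
  expect_equal(feature_distance(gc_[1, ], gc_[2, ], pc,
                                circular_aware = TRUE), 0L)
  expect_equal(feature_distance(gc_[1, ], gc_[2, ], pc,
                                circular_aware = FALSE), 9800L)
  # wrap distance counts the bp strictly between, around the origin
  pc2 <- plasmid_record("pc2", data.frame(
    gene_id = c("x", "y"), start = c(1L, 9801L), end = c(100L, 9900L),
    strand = 1L, product = ""), length_bp = 10000L, topology = "circular")
  g2 <- pc2$genes
  expect_equal(feature_distance(g2[1, ], g2[2, ], pc2,
                                circular_aware = TRUE), 100L)
})

test_that("incidence curve matches the worked two-plasmid example", {
  # plasmid q1: one ARG at 500 bp; q2: ARGs at 300 bp and 10000 bp
  p1 <- mk_plasmid(c("merA", "ARG:sulfonamide"), pid = "q1", gap_bp = 500L)
  g2 <- data.frame(
    gene_id = paste0("q2_g", 1:3),
    start = c(101L, 1101L + 300L, 1101L + 10000L),
    end = c(1100L, 1101L + 300L + 999L, 1101L + 10000L + 999L),
    strand = 1L,
    product = c("merA", "tetA", "sul2"), stringsAsFactors = FALSE)
  # fix exact gaps: ARG1 starts end1+301 -> 300; ARG2 end1+10001 -> 10000
  g2$start <- c(101L, 1100L + 301L, 1100L + 10001L)
  g2$end <- g2$start + c(999L, 999L, 999L)
  p2 <- plasmid_record("q2", g2, length_bp = 200000L)
  recs <- plasmid_set(list(p1, p2))
  asn <- rbind(mk_assignments(p1, c("merA", "ARG:sulfonamide")),
               data.frame(plasmid_id = "q2", gene_id = "q2_g1",
                          category = "HRG", gene_name = "merA",
                          class_label = "merA", stringsAsFactors = FALSE),
               data.frame(plasmid_id = "q2",
                          gene_id = c("q2_g2", "q2_g3"), category = "ARG",
                          gene_name = c("tetA", "sul2"),
                          class_label = c("tetracycline", "sulfonamide"),
                          stringsAsFactors = FALSE))
  cur <- ah_incidence_curve(recs, asn)
  expect_equal(nrow(cur), 501L)
  expect_equal(attr(cur, "n_plasmids"), 2L)
  expect_equal(cur$value[cur$threshold_bp == 600], 1.0)
  expect_equal(cur$value[cur$threshold_bp == 10000], 1.5)
  expect_equal(cur$value[cur$threshold_bp == 0], 0)
  # non-decreasing, bounded by the mean ARG count per contributing plasmid
  expect_true(all(diff(cur$value) >= 0))
  expect_lte(cur$value[501], 3 / 2)
})

test_that("plasmids beyond the grid give an identically zero curve", {
  p <- mk_plasmid(c("merA", "ARG:sulfonamide"), gap_bp = 150000L)
  asn <- mk_assignments(p, c("merA", "ARG:sulfonamide"))
  cur <- ah_incidence_curve(plasmid_set(list(p)), asn)
  expect_true(all(cur$value == 0))
  expect_error(ah_incidence_curve(plasmid_set(list(mk_plasmid("o"))),
                                  mk_assignments(p, "merA")),
               "no plasmid carries both")
})

test_that("per-class minima match hand computation and brute force", {
  toks <- c("ARG:tetracycline", "o", "merA", "ARG:sulfonamide")
  p <- mk_plasmid(toks, gap_bp = 1000L)
  asn <- mk_assignments(p, toks)
  r <- ah_distance_min(p, asn)
  # gene span 1000, gap 1000: tet..merA has one gene between -> 3000 bp
  expect_equal(unname(r$per_arg_class_min["tetracycline"]), 3000)
  expect_equal(unname(r$per_arg_class_min["sulfonamide"]), 1000)
  expect_equal(r$plasmid_min, 1000)
  # overlapping ARG/HRG gives zero
  p0 <- plasmid_record("z", data.frame(
    gene_id = c("h", "a"), start = c(100L, 500L), end = c(1000L, 1400L),
    strand = 1L, product = ""))
  asn0 <- rbind(
    data.frame(plasmid_id = "z", gene_id = "h", category = "HRG",
               gene_name = "merA", class_label = "merA"),
    data.frame(plasmid_id = "z", gene_id = "a", category = "ARG",
               gene_name = "sul1", class_label = "sulfonamide"))
  expect_equal(ah_distance_min(p0, asn0)$plasmid_min, 0)
  expect_error(ah_distance_min(mk_plasmid("o"), asn0), "lacks an HRG")
})

test_that("co-distribution statistics equal brute-force enumeration", {
  set.seed(55)
  n_ok <- 0L
  for (rep_i in 1:500) {
    p <- random_token_plasmid(sprintf("b%03d", rep_i))
    toks <- p$genes$product
    asn <- mk_assignments(p, toks)
    if (is.null(asn) || length(unique(asn$category)) < 2L) next
    n_ok <- n_ok + 1L
    recs <- plasmid_set(list(p))
    arg_ids <- asn$gene_id[asn$category == "ARG"]
    hrg_ids <- asn$gene_id[asn$category == "HRG"]
    mins <- brute_arg_minima(p, arg_ids, hrg_ids)
    # distance minima: per ARG class and per plasmid
    r <- ah_distance_min(p, asn)
    cls <- asn$class_label[asn$category == "ARG"]
    for (cl in unique(cls)) {
      expect_equal(unname(r$per_arg_class_min[cl]),
                   min(mins[cls == cl]))
    }
    expect_equal(r$plasmid_min, min(mins))
    # incidence curve on a coarse grid
    thr <- seq(0L, 20000L, by = 4000L)
    cur <- ah_incidence_curve(recs, asn, step_bp = 4000L, max_bp = 20000L)
    expect_equal(cur$value, brute_curve(recs, asn, thr)$value)
  }
  expect_gte(n_ok, 200L)
})

test_that("removing a non-minimizing ARG never changes the plasmid minimum", {
  set.seed(77)
  for (rep_i in 1:50) {
    p <- random_token_plasmid(sprintf("m%03d", rep_i))
    asn <- mk_assignments(p, p$genes$product)
    if (is.null(asn) || length(unique(asn$category)) < 2L) next
    r <- ah_distance_min(p, asn)
    arg_rows <- which(asn$category == "ARG")
    if (length(arg_rows) < 2L) next
    mins <- brute_arg_minima(p, asn$gene_id[arg_rows],
                             asn$gene_id[asn$category == "HRG"])
    drop_idx <- arg_rows[which.max(mins)]
    if (sum(mins == min(mins)) == length(mins)) next
    r2 <- ah_distance_min(p, asn[-drop_idx, ])
    expect_equal(r2$plasmid_min, r$plasmid_min)
  }
})

test_that("nearest-class preference excludes multidrug and breaks ties low", {
  toks <- c("ARG:multidrug", "merA", "o", "ARG:sulfonamide")
  p <- mk_plasmid(toks, gap_bp = 200L)
  asn <- mk_assignments(p, toks)
  pref <- nearest_class_preference(plasmid_set(list(p)), asn)
  # multidrug is adjacent but excluded; sulfonamide wins
  expect_equal(pref$arg_class, "sulfonamide")
  expect_equal(pref$plasmid_count, 1L)
  expect_equal(pref$percent, 100)
  # a plasmid with only excluded classes is skipped with a message
  toks2 <- c("merA", "ARG:multidrug")
  p2 <- mk_plasmid(toks2, pid = "p2")
  expect_message(
    pref2 <- nearest_class_preference(plasmid_set(list(p2)),
                                      mk_assignments(p2, toks2)),
    "only excluded")
  expect_equal(nrow(pref2), 0L)
  # tie at equal distance goes to the lexicographically smaller class
  toks3 <- c("ARG:tetracycline", "merA", "ARG:aminoglycoside")
  p3 <- mk_plasmid(toks3, pid = "p3")
  expect_message(
    pref3 <- nearest_class_preference(plasmid_set(list(p3)),
                                      mk_assignments(p3, toks3)),
    "tie")
  expect_equal(pref3$arg_class, "aminoglycoside")
})

test_that("grouped curves split by label and reduce to the pooled curve", {
  p1 <- mk_plasmid(c("merA", "ARG:sulfonamide"), pid = "h1", gap_bp = 400L)
  p2 <- mk_plasmid(c("merA", "ARG:sulfonamide"), pid = "h2", gap_bp = 400L)
  p3 <- mk_plasmid(c("merA", "ARG:sulfonamide"), pid = "w1", gap_bp = 9000L)
  recs <- plasmid_set(list(p1, p2, p3))
  asn <- rbind(mk_assignments(p1, c("merA", "ARG:sulfonamide")),
               mk_assignments(p2, c("merA", "ARG:sulfonamide")),
               mk_assignments(p3, c("merA", "ARG:sulfonamide")))
  labels <- c(h1 = "human", h2 = "human", w1 = "wastewater and sludge")
  cur <- group_curves(recs, asn, labels)
  expect_named(cur, c("human", "wastewater and sludge"))
  # identical plasmids give identical curves
  single <- group_curves(recs, asn, c(h1 = "human", h2 = "human"))
  expect_equal(single$human$value,
               ah_incidence_curve(recs[c("h1", "h2")],
                                  asn[asn$plasmid_id != "w1", ])$value)
  # planted nearer ARGs dominate at every threshold
  expect_true(all(cur$human$value >= cur$`wastewater and sludge`$value))
  # NA labels are excluded; empty groups warn
  expect_warning(group_curves(recs, asn[asn$plasmid_id == "h1", ],
                              c(h1 = "human", w1 = "wastewater and sludge")),
                 "omitted")
})
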