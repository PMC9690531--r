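# shared builders and brute-force oracles

# plasmid from a token vector: HRG names become HRG genes, "X"/"o" fillers,
# "ARG:<class>" plants an ARG gene; gene length 1000 bp, gap 100 bp
mk_plasmid <- function(tokens, pid = "p1", strands = NULL, gap_bp = 100L,
                       len_bp = 1000L, topology = "linear") {
  n <- length(tokens)
  if (is.null(strands)) strands <- rep(1L, n)
  start <- 101L + (seq_len(n) - 1L) * (len_bp + gap_bp)
  genes <- data.frame(gene_id = sprintf("%s_g%02d", pid, seq_len(n)),
                      start = start, end = start + len_bp - 1L,
                      strand = strands, product = tokens,
                      stringsAsFactors = FALSE)
  plasmid_record(pid, genes, length_bp = max(genes$end) + 500L,
                 topology = topology)
}

# assignments for a token plasmid
mk_assignments <- function(plasmid, tokens) {
  g <- plasmid$genes
  rows <- list()
  hrg <- grepl("^mer|^hgc", tokens)
  if (any(hrg)) {
    rows$h <- data.frame(plasmid_id = plasmid$plasmid_id,
                         gene_id = g$gene_id[hrg], category = "HRG",
                         gene_name = tokens[hrg], class_label = tokens[hrg],
                         stringsAsFactors = FALSE)
  }
  arg <- grepl("^ARG:", tokens)
  if (any(arg)) {
    cls <- sub("^ARG:", "", tokens[arg])
    rows$a <- data.frame(plasmid_id = plasmid$plasmid_id,
                         gene_id = g$gene_id[arg], category = "ARG",
                         gene_name = cls, class_label = cls,
                         stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

mk_hit <- function(query_id = "g1", subject_id = "s1", identity = 95,
                   aln_len = 100L, evalue = 1e-20, bitscore = 200,
                   qlen = 100L, slen = 100L) {
  data.frame(query_id = query_id, subject_id = subject_id,
             identity_pct = identity, aln_len = as.integer(aln_len),
             mismatches = 0L, gap_opens = 0L, qstart = 1L,
             qend = as.integer(aln_len), sstart = 1L,
             send = as.integer(aln_len), evalue = evalue,
             bitscore = bitscore, qlen = as.integer(qlen),
             slen = as.integer(slen), stringsAsFactors = FALSE)
}

random_hits <- function(n, queries = paste0("g", 1:5)) {
  data.frame(query_id = sample(queries, n, replace = TRUE),
             subject_id = paste0("s", sample(1:8, n, replace = TRUE)),
             identity_pct = round(runif(n, 60, 100), 1),
             aln_len = sample(30:120, n, replace = TRUE),
             mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 1L,
             sstart = 1L, send = 1L,
             evalue = 10^runif(n, -40, -2),
             bitscore = round(runif(n, 50, 500), 1),
             qlen = sample(80:120, n, replace = TRUE),
             slen = sample(80:120, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- brute-force oracles ----------------------------------------------------

# cluster partition by scanning every consecutive HRG pair
brute_clusters <- function(hrg_ranks, gap_max) {
  hrg_ranks <- sort(hrg_ranks)
  if (length(hrg_ranks) < 2L) return(list())
  groups <- list(); cur <- hrg_ranks[1]
  for (r in hrg_ranks[-1]) {
    if (r - cur[length(cur)] - 1L <= gap_max) {
      cur <- c(cur, r)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- r
    }
  }
  groups[[length(groups) + 1L]] <- cur
  Filter(function(g) length(g) >= 2L, groups)
}

brute_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) max(0L, s2 - e1 - 1L)
  else if (e2 < s1) max(0L, s1 - e2 - 1L)
  else 0L
}

# per-ARG minimum distance to any HRG, exhaustive pair enumeration
brute_arg_minima <- function(plasmid, arg_ids, hrg_ids) {
  g <- plasmid$genes
  vapply(arg_ids, function(a) {
    ai <- match(a, g$gene_id)
    min(vapply(hrg_ids, function(h) {
      hi <- match(h, g$gene_id)
      brute_gap(g$start[ai], g$end[ai], g$start[hi], g$end[hi])
    }, numeric(1)))
  }, numeric(1))
}

# incidence curve by quadruple loop over (plasmid, ARG, HRG, threshold)
brute_curve <- function(records, assignments, thresholds) {
  pids <- Reduce(intersect, list(
    unique(assignments$plasmid_id[assignments$category == "ARG"]),
    unique(assignments$plasmid_id[assignments$category == "HRG"])))
  vals <- vapply(thresholds, function(d) {
    total <- 0L
    for (pid in pids) {
      sub <- assignments[assignments$plasmid_id == pid, ]
      mins <- brute_arg_minima(records[[pid]],
                               sub$gene_id[sub$category == "ARG"],
                               sub$gene_id[sub$category == "HRG"])
      total <- total + sum(mins <= d)
    }
    total / length(pids)
  }, numeric(1))
  data.frame(threshold_bp = thresholds, value = vals)
}

# random token plasmid with planted HRGs/ARGs at random positions
random_token_plasmid <- function(pid, max_genes = 20L) {
  n <- sample(2:max_genes, 1L)
  pool <- c("merA", "merR", "merD", "merT", "o",
            "ARG:sulfonamide", "ARG:tetracycline")
  tokens <- sample(pool, n, replace = TRUE)
  mk_plasmid(tokens, pid = pid, gap_bp = sample(c(50L, 500L, 3000L), 1L))
}
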