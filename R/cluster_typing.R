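# ---- HRG cluster detection --------------------------------------------------

#' Detect maximal HRG clusters on a plasmid
#'
#' An HRG cluster is at least two mercury-related genes that are adjacent in
#' gene order or separated by no more than `gap_max` other genes. Two
#' consecutive HRGs (by rank) belong to the same cluster iff the number of
#' non-HRG genes strictly between them is `<= gap_max`; clusters are maximal
#' runs under that relation, trimmed so both ends are HRGs. Singleton HRGs
#' are not clusters. The rule is purely rank-based: it counts genes, not
#' base pairs.
#'
#' @param plasmid A [plasmid_record()].
#' @param hrg_gene_ids Character vector of gene ids annotated as HRGs.
#' @param gap_max Maximum number of intervening non-HRG genes (default 2).
#' @return List of `hrg_cluster` objects with fields `plasmid_id`,
#'   `member_ranks` (HRG and intervening genes), `hrg_ranks`, `span_bp`,
#'   `strand_majority` (+1, -1 or 0 for a tie).
#' @export
detect_clusters <- function(plasmid, hrg_gene_ids, gap_max = 2L) {
  g <- plasmid$genes
  hrg_rank <- sort(g$rank[g$gene_id %in% hrg_gene_ids])
  if (length(hrg_rank) < 2L) return(list())
  new_run <- c(TRUE, diff(hrg_rank) - 1L > gap_max)
  run_id <- cumsum(new_run)
  runs <- split(hrg_rank, run_id)
  runs <- runs[lengths(runs) >= 2L]
  lapply(unname(runs), function(rr) {
    members <- seq.int(min(rr), max(rr))
    sel <- g$rank %in% members
    strands <- g$strand[g$rank %in% rr]
    s <- sum(strands)
    structure(list(plasmid_id = plasmid$plasmid_id,
                   member_ranks = members,
                   hrg_ranks = rr,
                   span_bp = max(g$end[sel]) - min(g$start[sel]) + 1L,
                   strand_majority = as.integer(sign(s))),
              class = "hrg_cluster")
  })
}

#' @export
print.hrg_cluster <- function(x, ...) {
  cat(sprintf("<hrg_cluster> %s ranks %d..%d (%d HRGs, %d bp, strand %s)\n",
              x$plasmid_id, min(x$member_ranks), max(x$member_ranks),
              length(x$hrg_ranks), x$span_bp,
              c("-", "tie", "+")[x$strand_majority + 2L]))
  invisible(x)
}

#' Canonical cluster-type string
#'
#' Tokens are, in reading order, the HRG gene names with one `"X"` per
#' intervening non-HRG gene, joined by hyphens. Reading order is plasmid
#' rank order when the strand majority of the cluster's HRGs is `+1` and
#' reversed when `-1`, so minus-strand operons read promoter-first; on a
#' strand tie the lexicographically smaller of the two orientations is used.
#'
#' @param cluster An `hrg_cluster` from [detect_clusters()].
#' @param plasmid The corresponding [plasmid_record()].
#' @param hrg_names Named character vector mapping HRG gene ids to catalogue
#'   gene names (e.g. `merA`).
#' @return The token string, e.g. `"merR-merT-merP-X-merA-merD-merE"`.
#' @export
name_cluster_type <- function(cluster, plasmid, hrg_names) {
  g <- plasmid$genes
  idx <- match(cluster$member_ranks, g$rank)
  ids <- g$gene_id[idx]
  tokens <- ifelse(g$rank[idx] %in% cluster$hrg_ranks,
                   unname(hrg_names[ids]), "X")
  if (anyNA(tokens)) {
    stop("cluster member without an HRG name: ",
         paste(ids[is.na(tokens)], collapse = ", "))
  }
  fwd <- paste(tokens, collapse = "-")
  rev_ <- paste(rev(tokens), collapse = "-")
  if (cluster$strand_majority > 0L) fwd
  else if (cluster$strand_majority < 0L) rev_
  else min(fwd, rev_)
}

#' Detect and name HRG clusters across a dataset
#'
#' Convenience wrapper: runs [detect_clusters()] and [name_cluster_type()]
#' on every plasmid with HRG assignments.
#'
#' @param records A [plasmid_set()].
#' @param assignments Assignment table from [annotate_dataset()] (HRG rows
#'   are used).
#' @param gap_max See [detect_clusters()].
#' @return Data frame: `plasmid_id`, `start_rank`, `end_rank`, `n_hrg`,
#'   `span_bp`, `type_string`.
#' @export
cluster_table <- function(records, assignments, gap_max = 2L) {
  hrg <- assignments[assignments$category == "HRG", , drop = FALSE]
  rows <- lapply(names(records), function(pid) {
    sub <- hrg[hrg$plasmid_id == pid, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    nm <- stats::setNames(sub$gene_name, sub$gene_id)
    cl <- detect_clusters(records[[pid]], sub$gene_id, gap_max)
    if (!length(cl)) return(NULL)
    do.call(rbind, lapply(cl, function(x) data.frame(
      plasmid_id = pid, start_rank = min(x$member_ranks),
      end_rank = max(x$member_ranks), n_hrg = length(x$hrg_ranks),
      span_bp = x$span_bp,
      type_string = name_cluster_type(x, records[[pid]], nm),
      stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    plasmid_id = character(), start_rank = integer(), end_rank = integer(),
    n_hrg = integer(), span_bp = integer(), type_string = character(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

# round half away from zero, the tables' formatting convention
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tally cluster types into an incidence spectrum
#'
#' Counts incidences per distinct type string (per occurrence, so a plasmid
#' carrying two identical clusters contributes twice), computes the percent
#' of incidences to two decimals (half-up), and sorts by incidence
#' descending then type string ascending.
#'
#' @param type_strings Character vector of cluster type strings.
#' @return Data frame of class `cluster_spectrum`: `type_string`,
#'   `incidence`, `percent`, with attributes `n_types` and `n_incidences`.
#' @export
tally_cluster_types <- function(type_strings) {
  if (!length(type_strings)) {
    out <- data.frame(type_string = character(), incidence = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
  } else {
    tt <- table(type_strings)
    out <- data.frame(type_string = names(tt),
                      incidence = as.integer(tt),
                      stringsAsFactors = FALSE)
    out$percent <- round_half_up(100 * out$incidence / sum(out$incidence))
    out <- out[order(-out$incidence, out$type_string), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_types") <- nrow(out)
  attr(out, "n_incidences") <- sum(out$incidence)
  class(out) <- c("cluster_spectrum", "data.frame")
  out
}

#' Number of cluster types rarer than a threshold
#'
#' @param spectrum A `cluster_spectrum` from [tally_cluster_types()].
#' @param k Incidence threshold (strictly below).
#' @return List with `n_rare`, `n_types`, `percent` of types with
#'   incidence `< k`.
#' @export
rare_type_fraction <- function(spectrum, k = 5L) {
  n_rare <- sum(spectrum$incidence < k)
  list(n_rare = n_rare, n_types = nrow(spectrum),
       percent = if (nrow(spectrum)) {
         round_half_up(100 * n_rare / nrow(spectrum))
       } else NA_real_)
}

#' Fraction of HRGs lying inside clusters
#'
#' @param records A [plasmid_set()].
#' @param assignments Assignment table (HRG rows are used).
#' @param gap_max See [detect_clusters()].
#' @return Percentage of HRGs grouped into clusters, two decimals; `NA` when
#'   there are no HRGs.
#' @export
clustered_fraction <- function(records, assignments, gap_max = 2L) {
  hrg <- assignments[assignments$category == "HRG", , drop = FALSE]
  total <- nrow(hrg)
  if (!total) return(NA_real_)
  inside <- 0L
  for (pid in unique(hrg$plasmid_id)) {
    ids <- hrg$gene_id[hrg$plasmid_id == pid]
    cl <- detect_clusters(records[[pid]], ids, gap_max)
    inside <- inside + sum(lengths(lapply(cl, `[[`, "hrg_ranks")))
  }
  round_half_up(100 * inside / total)
}
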