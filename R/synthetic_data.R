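# ---- example catalogues -----------------------------------------------------

#' Synthetic mercury-gene reference catalogue
#'
#' One entry per mer-operon gene name plus the hgcA/hgcB methylation pair;
#' the class label of a mercury-related gene is its gene name. Synthetic
#' stand-in for a keyword-extracted metal-resistance catalogue.
#'
#' @return A [reference_catalogue()].
#' @export
example_hrg_catalogue <- function() {
  genes <- c("merA", "merB", "merB1", "merC", "merD", "merE", "merF",
             "merG", "merP", "merR", "merT", "hgcA", "hgcB")
  reference_catalogue(data.frame(
    subject_id = sprintf("HRG%04d", seq_along(genes)),
    gene_name = genes, class_label = genes, source_db = "synthetic",
    stringsAsFactors = FALSE))
}

ARG_CLASS_GENES <- list(
  aminoglycoside = c("aadA1", "aph3-Ia", "aac6-Ib"),
  sulfonamide = c("sul1", "sul2"),
  tetracycline = c("tetA", "tetM"),
  `macrolide-lincosamide-streptogramin` = c("ermB", "mphA"),
  `beta-lactam` = c("blaTEM-1", "blaCTX-M-15"),
  chloramphenicol = c("catA1", "floR"),
  trimethoprim = "dfrA1",
  quinolone = "qnrS1",
  polymyxin = "mcr-1",
  vancomycin = "vanA",
  fosfomycin = "fosA3",
  rifamycin = "arr-2",
  kasugamycin = "ksgA",
  multidrug = c("acrB", "oqxA"))

#' Synthetic ARG reference catalogue
#'
#' A small catalogue spanning the antibiotic-resistance classes used in the
#' preference analysis (plus multidrug), with a handful of representative
#' gene names per class.
#'
#' @return A [reference_catalogue()].
#' @export
example_arg_catalogue <- function() {
  rows <- do.call(rbind, lapply(names(ARG_CLASS_GENES), function(cl) {
    data.frame(gene_name = ARG_CLASS_GENES[[cl]], class_label = cl,
               stringsAsFactors = FALSE)
  }))
  rows$subject_id <- sprintf("ARG%04d", seq_len(nrow(rows)))
  rows$source_db <- "synthetic"
  reference_catalogue(rows[, c("subject_id", "gene_name", "class_label",
                               "source_db")])
}

#' Synthetic pathogenicity map
#'
#' @return Named character vector species -> `pathogen`/`non-pathogen`.
#' @export
example_pathogenicity_map <- function() {
  c("Klebsiella pneumoniae" = "pathogen",
    "Escherichia coli" = "pathogen",
    "Salmonella enterica" = "pathogen",
    "Enterobacter cloacae" = "pathogen",
    "Citrobacter freundii" = "pathogen",
    "Shewanella baltica" = "non-pathogen",
    "Halomonas elongata" = "non-pathogen",
    "Marinobacter adhaerens" = "non-pathogen")
}

# Table-2-like default cluster-type spectrum (visible rows, normalized)
DEFAULT_CLUSTER_SPECTRUM <- c(
  "merR-merT-merP-X-merA-merD-merE" = 543,
  "merR-merT-merP-merC-merA-merD-merE" = 457,
  "merA-merD-merE" = 96,
  "merR-merT-merP-merA-merB-merD-merE" = 77,
  "merR-merT-merP-X-merA" = 76,
  "merR-merT-merP-merF-merA-merD-merE" = 62,
  "merD-merE" = 48,
  "merR-merT-merP-merA-merD-merE" = 39,
  "merR-merT-merP" = 31,
  "merR-X-merB-merD-merE" = 27,
  "merR-merT-merP-X-merA-merD" = 16,
  "merR-X-X-merC-merA-merD" = 16,
  "merR-merT-merP-merC-merA-merD" = 14,
  "merR-merT" = 11,
  "merR-merT-merP-merC-merA" = 10,
  "merR-merT-merP-merA-merG-merB1" = 9,
  "merR-merT-merP-merA-merB-X-X-merE" = 8,
  "merT-merP-X-merA-merD-merE" = 7,
  "merP-X-merA" = 6,
  "merR-X-X-merC-X-X-merD" = 6,
  "merT-merP-merC-merA-merD-merE" = 5,
  "merP-X-merA-merD-merE" = 5,
  "merB-merD-merE" = 5,
  "merR-X-merC-merA" = 5)

DEFAULT_ARG_CLASS_FREQ <- c(
  aminoglycoside = 0.23, sulfonamide = 0.13, tetracycline = 0.13,
  `macrolide-lincosamide-streptogramin` = 0.12, `beta-lactam` = 0.10,
  multidrug = 0.10, chloramphenicol = 0.05, trimethoprim = 0.04,
  quinolone = 0.04, polymyxin = 0.03, vancomycin = 0.02,
  fosfomycin = 0.005, rifamycin = 0.005)

# host-source mix mirroring the HRG-bearing cohort proportions
DEFAULT_HOST_MIX <- c(human = 901, animal = 242,
                      `wastewater and sludge` = 144,
                      `miscellaneous sources` = 159, `NA` = 277) / 1723

HOST_METADATA <- list(
  human = list(host_species = "Homo sapiens", isolation_source = "clinical"),
  animal = list(host_species = "Sus scrofa", isolation_source = "pig farm"),
  `wastewater and sludge` = list(host_species = "",
                                 isolation_source = "activated sludge"),
  `miscellaneous sources` = list(host_species = "",
                                 isolation_source = "agricultural soil"),
  `NA` = list(host_species = "", isolation_source = ""))

GENUS_POOL <- c(Klebsiella = 0.36, Escherichia = 0.16, Salmonella = 0.14,
                Enterobacter = 0.10, Citrobacter = 0.08, Shewanella = 0.06,
                Halomonas = 0.05, Marinobacter = 0.05)
GENUS_SPECIES <- c(Klebsiella = "pneumoniae", Escherichia = "coli",
                   Salmonella = "enterica", Enterobacter = "cloacae",
                   Citrobacter = "freundii", Shewanella = "baltica",
                   Halomonas = "elongata", Marinobacter = "adhaerens")

#' Simulation configuration
#'
#' Defaults emulate the observed study conditions: plasmid lengths
#' log-uniform on 5-1100 kb, cluster types drawn from the published-style
#' incidence spectrum, ARGs planted at a point-mass 500 bp from the nearest
#' HRG, the host-source mix of the HRG-bearing cohort, and a planted
#' monotone size-HRG association with Spearman rho 0.30.
#'
#' @param n_plasmids Number of plasmids.
#' @param length_range_kb Log-uniform plasmid length range, kb.
#' @param cluster_spectrum Named probability vector over cluster type
#'   strings (normalized internally).
#' @param n_cluster_probs Probabilities of 0, 1, 2, ... planted clusters
#'   per plasmid.
#' @param p_singleton_hrg Probability of one additional isolated HRG.
#' @param p_minus_cluster Probability a planted cluster sits on the minus
#'   strand (laid in reversed order so its canonical type is unchanged).
#' @param p_arg_per_plasmid Mean planted ARG count (Poisson; capped at two
#'   per cluster so planted distances stay exact).
#' @param arg_class_frequencies Named probability vector over ARG classes.
#' @param distance_model Planted ARG offset from the nearest HRG:
#'   `list(kind = "point", bp = 500)` or
#'   `list(kind = "uniform", min_bp =, max_bp =)`.
#' @param host_source_mix Probabilities over the four host-source
#'   categories plus `"NA"`.
#' @param size_hrg_rho Target Spearman correlation between plasmid length
#'   and HRG count (planted by rank coupling).
#' @param hit_noise Fraction of filler genes receiving a decoy hit that
#'   violates exactly one stringent criterion.
#' @param gap_max Cluster gap constant used to space planted structures.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_plasmids = 100L,
                       length_range_kb = c(5, 1100),
                       cluster_spectrum = DEFAULT_CLUSTER_SPECTRUM,
                       n_cluster_probs = c(`0` = 0.3, `1` = 0.5, `2` = 0.2),
                       p_singleton_hrg = 0.10,
                       p_minus_cluster = 0.25,
                       p_arg_per_plasmid = 2,
                       arg_class_frequencies = DEFAULT_ARG_CLASS_FREQ,
                       distance_model = list(kind = "point", bp = 500),
                       host_source_mix = DEFAULT_HOST_MIX,
                       size_hrg_rho = 0.30,
                       hit_noise = 0.2,
                       gap_max = 2L,
                       seed = 20221118L) {
  cluster_spectrum <- cluster_spectrum / sum(cluster_spectrum)
  arg_class_frequencies <- arg_class_frequencies / sum(arg_class_frequencies)
  host_source_mix <- host_source_mix / sum(host_source_mix)
  n_cluster_probs <- n_cluster_probs / sum(n_cluster_probs)
  cfg <- list(n_plasmids = as.integer(n_plasmids),
              length_range_kb = length_range_kb,
              cluster_spectrum = cluster_spectrum,
              n_cluster_probs = n_cluster_probs,
              p_singleton_hrg = p_singleton_hrg,
              p_minus_cluster = p_minus_cluster,
              p_arg_per_plasmid = p_arg_per_plasmid,
              arg_class_frequencies = arg_class_frequencies,
              distance_model = distance_model,
              host_source_mix = host_source_mix,
              size_hrg_rho = size_hrg_rho,
              hit_noise = hit_noise,
              gap_max = as.integer(gap_max),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_plasmids >= 1L,
            length(cfg$length_range_kb) == 2L,
            cfg$length_range_kb[1] > 0,
            cfg$length_range_kb[2] >= cfg$length_range_kb[1],
            abs(sum(cfg$cluster_spectrum) - 1) < 1e-9,
            abs(sum(cfg$arg_class_frequencies) - 1) < 1e-9,
            abs(sum(cfg$host_source_mix) - 1) < 1e-9)
  known <- unlist(lapply(example_hrg_catalogue()$gene_name, identity))
  toks <- unique(unlist(strsplit(names(cfg$cluster_spectrum), "-",
                                 fixed = TRUE)))
  bad <- setdiff(toks, c(known, "X"))
  if (length(bad)) stop("cluster spectrum uses unknown gene token(s): ",
                        paste(bad, collapse = ", "))
  unknown_cls <- setdiff(names(cfg$arg_class_frequencies),
                         names(ARG_CLASS_GENES))
  if (length(unknown_cls)) stop("unknown ARG class(es): ",
                                paste(unknown_cls, collapse = ", "))
  # an average planted cluster must fit the smallest plasmid
  max_tokens <- max(lengths(strsplit(names(cfg$cluster_spectrum), "-")))
  if (max_tokens * 5000 > cfg$length_range_kb[2] * 1000) {
    stop("infeasible config: largest cluster cannot fit any plasmid")
  }
  invisible(cfg)
}

# ---- layout of one plasmid --------------------------------------------------

# Draws the content bundle of one plasmid (clusters, args, singleton) and
# lays genes out from coordinate ~1; returns genes, local truth tables.
layout_plasmid <- function(cfg, pid) {
  env <- new.env()
  env$rows <- list()
  env$pos <- sample(100:400, 1L)
  env$k <- 0L
  gene <- function(len, strand, product, is_hrg_name = NA_character_,
                   is_arg_class = NA_character_, arg_gene = NA_character_) {
    env$k <- env$k + 1L
    gid <- sprintf("%s_g%03d", pid, env$k)
    start <- env$pos
    end <- start + len - 1L
    env$pos <- end + 1L
    env$rows[[env$k]] <- data.frame(
      gene_id = gid, start = start, end = end, strand = strand,
      product = product, hrg_name = is_hrg_name, arg_class = is_arg_class,
      arg_gene = arg_gene, stringsAsFactors = FALSE)
    gid
  }
  gap <- function(n) env$pos <- env$pos + n
  filler <- function() {
    gene(sample(600:4500, 1L), sample(c(1L, -1L), 1L),
         "hypothetical protein")
    gap(sample(20:200, 1L))
  }
  draw_offset <- function() {
    dm <- cfg$distance_model
    if (dm$kind == "point") as.integer(dm$bp)
    else sample(dm$min_bp:dm$max_bp, 1L)
  }
  arg_gene_row <- function() {
    cls <- sample(names(cfg$arg_class_frequencies), 1L,
                  prob = cfg$arg_class_frequencies)
    nm <- ARG_CLASS_GENES[[cls]][sample.int(length(ARG_CLASS_GENES[[cls]]), 1L)]
    gene(sample(800:1200, 1L), sample(c(1L, -1L), 1L),
         paste(cls, "resistance protein"), is_arg_class = cls, arg_gene = nm)
  }

  n_cl <- sample(seq_along(cfg$n_cluster_probs) - 1L, 1L,
                 prob = cfg$n_cluster_probs)
  types <- if (n_cl > 0L) {
    sample(names(cfg$cluster_spectrum), n_cl, replace = TRUE,
           prob = cfg$cluster_spectrum)
  } else character()
  n_args <- stats::rpois(1L, cfg$p_arg_per_plasmid)
  if (n_cl > 0L) n_args <- min(n_args, 2L * n_cl)
  # slots: (cluster i, right), then (cluster i, left)
  slots <- c(paste0("R", seq_len(n_cl)), paste0("L", seq_len(n_cl)))
  arg_slots <- if (n_cl > 0L) slots[seq_len(n_args)] else character()

  clusters <- list()
  for (i in seq_len(max(n_cl, 1L))) {
    if (i == 1L) for (j in seq_len(sample(2:3, 1L))) filler()
    if (n_cl == 0L) break
    minus <- stats::runif(1) < cfg$p_minus_cluster
    toks <- strsplit(types[i], "-", fixed = TRUE)[[1]]
    laid <- if (minus) rev(toks) else toks
    # left ARG, at the planted offset before the cluster's first HRG
    if (paste0("L", i) %in% arg_slots) {
      d <- draw_offset()
      arg_gene_row()
      gap(d)
    }
    first_k <- env$k + 1L
    for (t in seq_along(laid)) {
      if (laid[t] == "X") {
        gene(sample(600:2000, 1L), if (minus) -1L else 1L,
             "hypothetical protein")
      } else {
        gene(sample(600:1700, 1L), if (minus) -1L else 1L,
             paste(laid[t], "mercury resistance protein"),
             is_hrg_name = laid[t])
      }
      if (t < length(laid)) gap(sample(10:60, 1L))
    }
    clusters[[i]] <- list(type = types[i], first_k = first_k,
                          last_k = env$k, minus = minus)
    # right ARG
    if (paste0("R", i) %in% arg_slots) {
      d <- draw_offset()
      gap(d)
      arg_gene_row()
    }
    for (j in seq_len(sample((cfg$gap_max + 2L):(cfg$gap_max + 5L), 1L))) {
      filler()
    }
  }
  if (n_cl == 0L && n_args > 0L) {
    for (a in seq_len(n_args)) {
      arg_gene_row()
      for (j in seq_len(sample(1:3, 1L))) filler()
    }
  }
  # a singleton HRG never joins standalone ARGs on a cluster-free plasmid:
  # dual-bearing plasmids must owe their distances to planted offsets only
  if (stats::runif(1) < cfg$p_singleton_hrg && !(n_cl == 0L && n_args > 0L)) {
    nm <- sample(c("merA", "merR", "merD"), 1L)
    gene(sample(600:1700, 1L), sample(c(1L, -1L), 1L),
         paste(nm, "mercury resistance protein"), is_hrg_name = nm)
    for (j in seq_len(cfg$gap_max + 2L)) filler()
  }
  filler()
  genes <- do.call(rbind, env$rows)
  list(genes = genes, clusters = clusters, span = max(genes$end),
       n_hrg = sum(!is.na(genes$hrg_name)))
}

# ---- main generator ---------------------------------------------------------

#' Simulate a plasmid dataset with planted ground truth
#'
#' Generates plasmid gene tables, similarity-search hit tables and host
#' metadata whose downstream annotation, cluster typing and co-distribution
#' statistics are known by construction, together with a ground-truth
#' manifest for parameter-recovery tests. Planted clusters are separated by
#' more than `gap_max` filler genes so detection is unambiguous; every true
#' assignment's hit passes the stringent criteria, and decoy hits violate
#' exactly one criterion each (identity in 70-79.9, coverage in 50-89.9, or
#' e-value above 1e-5, cycled deterministically) so each filter predicate is
#' exercised. The size-HRG association is planted by rank-coupling the
#' plasmid lengths to the per-plasmid HRG counts with an internally
#' calibrated mixing weight, so the realized Spearman coefficient matches
#' the configured target.
#'
#' @param config A [sim_config()].
#' @return List with `records` ([plasmid_set()]), `hrg_hits`, `arg_hits`
#'   (hit data frames), `hrg_catalogue`, `arg_catalogue`, and `manifest`
#'   (see Details). The manifest carries `assignments` (the true assignment
#'   table), `clusters` (plasmid, type string), `arg_placements` (plasmid,
#'   gene, class, true minimum distance to an HRG in bp), `host_sources`,
#'   `pathogenicity`, `n_hrg`, `length_bp` and `spearman` (target and
#'   realized).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_plasmids
  pids <- sprintf("p%04d", seq_len(n))

  layouts <- lapply(pids, function(pid) layout_plasmid(config, pid))
  n_hrg <- vapply(layouts, `[[`, integer(1), "n_hrg")
  spans <- vapply(layouts, `[[`, numeric(1), "span")

  # plasmid lengths, log-uniform; couple to HRG counts at the target rho
  lr <- log(config$length_range_kb * 1000)
  len_draw <- exp(stats::runif(n, lr[1], lr[2]))
  assign_idx <- couple_ranks(len_draw, n_hrg, spans, config$size_hrg_rho)
  # assign_idx[i] = index of the layout given to plasmid i
  length_bp <- pmax(round(len_draw), spans[assign_idx] + 200)

  hosts <- sample(names(config$host_source_mix), n, replace = TRUE,
                  prob = config$host_source_mix)
  genus <- sample(names(GENUS_POOL), n, replace = TRUE, prob = GENUS_POOL)

  hrg_cat <- example_hrg_catalogue()
  arg_cat <- example_arg_catalogue()
  hrg_sub <- stats::setNames(hrg_cat$subject_id, hrg_cat$gene_name)
  arg_sub_by_name <- stats::setNames(arg_cat$subject_id, arg_cat$gene_name)

  records <- vector("list", n)
  truth_asn <- list(); truth_cl <- list(); truth_arg <- list()
  hrg_hits <- list(); arg_hits <- list()
  decoy_phase <- 0L

  for (i in seq_len(n)) {
    lay <- layouts[[assign_idx[i]]]
    g <- lay$genes
    # layouts are reused under a new plasmid id: re-key gene ids
    g$gene_id <- sprintf("%s_g%03d", pids[i], seq_len(nrow(g)))
    meta <- HOST_METADATA[[hosts[i]]]
    records[[i]] <- plasmid_record(
      pids[i], g[, c("gene_id", "start", "end", "strand", "product")],
      length_bp = length_bp[i], topology = "linear",
      host_species = meta$host_species,
      isolation_source = meta$isolation_source,
      host_genus = genus[i],
      organism = paste(genus[i], GENUS_SPECIES[[genus[i]]]))

    hrg_rows <- which(!is.na(g$hrg_name))
    arg_rows <- which(!is.na(g$arg_class))
    qlen <- pmax(50L, as.integer((g$end - g$start + 1L) %/% 3L))

    mk_hit <- function(r, subj, slen) {
      q <- qlen[r]
      aln <- q - sample(0:max(0L, floor(0.08 * q)), 1L)
      data.frame(query_id = g$gene_id[r], subject_id = subj,
                 identity_pct = round(stats::runif(1, 85, 99.9), 1),
                 aln_len = aln, mismatches = sample(0:10, 1L),
                 gap_opens = sample(0:2, 1L), qstart = 1L, qend = aln,
                 sstart = 1L, send = aln,
                 evalue = 10^stats::runif(1, -80, -20),
                 bitscore = round(1.9 * aln + stats::runif(1, 0, 20), 1),
                 qlen = q, slen = slen, stringsAsFactors = FALSE)
    }
    for (r in hrg_rows) {
      hrg_hits[[length(hrg_hits) + 1L]] <-
        mk_hit(r, unname(hrg_sub[g$hrg_name[r]]), qlen[r])
    }
    for (r in arg_rows) {
      arg_hits[[length(arg_hits) + 1L]] <-
        mk_hit(r, unname(arg_sub_by_name[g$arg_gene[r]]), qlen[r])
    }
    # decoy hits on filler genes, each violating exactly one criterion
    filler_rows <- which(is.na(g$hrg_name) & is.na(g$arg_class))
    n_decoy <- floor(config$hit_noise * length(filler_rows))
    if (n_decoy > 0L) {
      for (r in utils::head(filler_rows, n_decoy)) {
        q <- qlen[r]
        viol <- decoy_phase %% 3L; decoy_phase <- decoy_phase + 1L
        idy <- if (viol == 0L) stats::runif(1, 70, 79.9) else stats::runif(1, 85, 99)
        aln <- if (viol == 1L) max(1L, floor(stats::runif(1, 0.5, 0.899) * q)) else q
        ev <- if (viol == 2L) 10^stats::runif(1, -4.9, -2) else 10^stats::runif(1, -40, -20)
        to_hrg <- stats::runif(1) < 0.5
        subj <- if (to_hrg) {
          mer_only <- hrg_cat$subject_id[!hrg_cat$gene_name %in% c("hgcA", "hgcB")]
          mer_only[sample.int(length(mer_only), 1L)]
        } else {
          arg_cat$subject_id[sample.int(nrow(arg_cat), 1L)]
        }
        row <- data.frame(query_id = g$gene_id[r], subject_id = subj,
                          identity_pct = round(idy, 1), aln_len = aln,
                          mismatches = sample(0:30, 1L),
                          gap_opens = sample(0:3, 1L), qstart = 1L,
                          qend = aln, sstart = 1L, send = aln, evalue = ev,
                          bitscore = round(1.2 * aln, 1), qlen = q,
                          slen = q, stringsAsFactors = FALSE)
        if (to_hrg) hrg_hits[[length(hrg_hits) + 1L]] <- row
        else arg_hits[[length(arg_hits) + 1L]] <- row
      }
    }
    # ground truth
    if (length(hrg_rows)) {
      truth_asn[[length(truth_asn) + 1L]] <- data.frame(
        plasmid_id = pids[i], gene_id = g$gene_id[hrg_rows],
        category = "HRG", gene_name = g$hrg_name[hrg_rows],
        class_label = g$hrg_name[hrg_rows], stringsAsFactors = FALSE)
    }
    if (length(arg_rows)) {
      truth_asn[[length(truth_asn) + 1L]] <- data.frame(
        plasmid_id = pids[i], gene_id = g$gene_id[arg_rows],
        category = "ARG", gene_name = g$arg_gene[arg_rows],
        class_label = g$arg_class[arg_rows], stringsAsFactors = FALSE)
      if (length(hrg_rows)) {
        true_min <- vapply(arg_rows, function(r) {
          min(linear_gap(g$start[r], g$end[r], g$start[hrg_rows],
                         g$end[hrg_rows]))
        }, numeric(1))
        truth_arg[[length(truth_arg) + 1L]] <- data.frame(
          plasmid_id = pids[i], gene_id = g$gene_id[arg_rows],
          arg_class = g$arg_class[arg_rows], true_min_bp = true_min,
          stringsAsFactors = FALSE)
      }
    }
    for (cl in lay$clusters) {
      truth_cl[[length(truth_cl) + 1L]] <- data.frame(
        plasmid_id = pids[i], type_string = cl$type,
        minus_strand = cl$minus, stringsAsFactors = FALSE)
    }
  }

  records <- plasmid_set(records, provenance = "simulate_dataset")
  manifest <- list(
    config = config,
    assignments = rbind_or_empty(truth_asn, c("plasmid_id", "gene_id",
                                              "category", "gene_name",
                                              "class_label")),
    clusters = rbind_or_empty(truth_cl, c("plasmid_id", "type_string",
                                          "minus_strand")),
    arg_placements = rbind_or_empty(truth_arg, c("plasmid_id", "gene_id",
                                                 "arg_class", "true_min_bp")),
    host_sources = stats::setNames(replace(hosts, hosts == "NA",
                                           NA_character_), pids),
    pathogenicity = stats::setNames(
      unname(ifelse(genus %in% c("Shewanella", "Halomonas", "Marinobacter"),
                    "non-pathogen", "pathogen")), pids),
    n_hrg = stats::setNames(n_hrg[assign_idx], pids),
    length_bp = stats::setNames(length_bp, pids),
    spearman = list(target = config$size_hrg_rho,
                    realized = stats::cor(length_bp, n_hrg[assign_idx],
                                          method = "spearman")))
  list(records = records,
       hrg_hits = rbind_or_empty(hrg_hits, names(empty_hits())),
       arg_hits = rbind_or_empty(arg_hits, names(empty_hits())),
       hrg_catalogue = hrg_cat, arg_catalogue = arg_cat,
       manifest = manifest)
}

rbind_or_empty <- function(rows, cols) {
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                  stringsAsFactors = FALSE)
  }
}

# Assign content layouts to plasmid lengths so that the realized Spearman
# correlation between final length and HRG count matches the target.
# Mixing weight w is calibrated by bisection on this sample.
couple_ranks <- function(len_draw, n_hrg, spans, rho_target) {
  n <- length(len_draw)
  noise <- stats::rnorm(n)
  r_len <- scale(rank(len_draw, ties.method = "first"))[, 1]
  ord_hrg <- order(n_hrg)  # layouts sorted by HRG count
  realized <- function(w) {
    score <- w * r_len + (1 - w) * noise
    idx <- integer(n)
    idx[order(score)] <- ord_hrg
    len_final <- pmax(round(len_draw), spans[idx] + 200)
    stats::cor(len_final, n_hrg[idx], method = "spearman")
  }
  assign_for <- function(w) {
    score <- w * r_len + (1 - w) * noise
    idx <- integer(n)
    idx[order(score)] <- ord_hrg
    idx
  }
  if (length(unique(n_hrg)) < 2L) return(assign_for(0))
  lo <- 0; hi <- 1
  if (realized(1) <= rho_target) return(assign_for(1))
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (realized(mid) < rho_target) lo <- mid else hi <- mid
  }
  assign_for((lo + hi) / 2)
}

# ---- fixtures ---------------------------------------------------------------

#' Cluster-spectrum fixture with exact planted incidences
#'
#' Builds a minimal dataset (one single-cluster plasmid per incidence) whose
#' detected cluster-type spectrum is exactly the requested (type, incidence)
#' table. By default the 24 most common published-style types are planted;
#' `include_rare = TRUE` additionally plants 64 rare types (each with
#' incidence below 5, totalling 101 incidences), giving a spectrum with 88
#' types and 1680 incidences.
#'
#' @param incidences Named integer vector: type string -> incidence count.
#' @param include_rare Add the 64-type rare tail.
#' @return List with `records` (a [plasmid_set()]) and `assignments` (an
#'   HRG assignment table).
#' @export
table2_fixture <- function(incidences = DEFAULT_CLUSTER_SPECTRUM,
                           include_rare = FALSE) {
  incidences <- round(incidences)
  if (include_rare) {
    rare <- rare_type_strings(64L)
    rare_inc <- stats::setNames(c(rep(2L, 37L), rep(1L, 27L)), rare)
    clash <- intersect(names(rare_inc), names(incidences))
    if (length(clash)) stop("rare types clash with requested types")
    incidences <- c(incidences, rare_inc)
  }
  records <- list(); asn <- list(); k <- 0L
  for (ty in names(incidences)) {
    toks <- strsplit(ty, "-", fixed = TRUE)[[1]]
    for (rep_i in seq_len(incidences[[ty]])) {
      k <- k + 1L
      pid <- sprintf("t2_%04d", k)
      pos <- 100L
      rows <- lapply(seq_along(toks), function(t) {
        start <- pos + (t - 1L) * 1100L
        data.frame(gene_id = sprintf("%s_g%02d", pid, t), start = start,
                   end = start + 999L, strand = 1L,
                   product = if (toks[t] == "X") "hypothetical protein"
                             else toks[t],
                   stringsAsFactors = FALSE)
      })
      g <- do.call(rbind, rows)
      records[[k]] <- plasmid_record(pid, g, length_bp = max(g$end) + 100L)
      is_hrg <- toks != "X"
      asn[[k]] <- data.frame(plasmid_id = pid, gene_id = g$gene_id[is_hrg],
                             category = "HRG", gene_name = toks[is_hrg],
                             class_label = toks[is_hrg],
                             stringsAsFactors = FALSE)
    }
  }
  list(records = plasmid_set(records, provenance = "table2_fixture"),
       assignments = do.call(rbind, asn))
}

# 64 distinct 4-token rare types absent from the default spectrum
rare_type_strings <- function(n) {
  mer <- c("merA", "merB", "merB1", "merC", "merD", "merE", "merF",
           "merG", "merP", "merR", "merT")
  combos <- expand.grid(a = mer, b = mer, stringsAsFactors = FALSE)
  cand <- paste0(combos$a, "-X-X-", combos$b)
  # canonical form under a strand tie is the lexicographically smaller
  # orientation; keep only candidates already canonical and not in use
  canon <- vapply(cand, function(s) {
    toks <- strsplit(s, "-", fixed = TRUE)[[1]]
    min(s, paste(rev(toks), collapse = "-"))
  }, character(1))
  cand <- unique(canon[canon == cand])
  cand <- setdiff(cand, names(DEFAULT_CLUSTER_SPECTRUM))
  if (length(cand) < n) stop("not enough rare type candidates")
  sort(cand)[seq_len(n)]
}

#' Three-plasmid worked example
#'
#' A hand-checkable dataset used throughout the documentation: plasmid pA
#' carries the seven-gene cluster merR-merT-merP-X-merA-merD-merE with a
#' sulfonamide ARG 500 bp downstream and a tetracycline ARG 5000 bp
#' downstream (plasmid minimum 500 bp, nearest class sulfonamide); pB
#' carries merA-merD-merE on the minus strand with an aminoglycoside ARG
#' 2000 bp away; pC carries a lone merA (no cluster) and a beta-lactam ARG
#' 1200 bp away.
#'
#' @return List with `records` and `assignments`.
#' @export
toy_worked_example <- function() {
  # pA: cluster + sul1 at 500 bp + tetA at 5000 bp from cluster end
  a_tok <- c("merR", "merT", "merP", "X", "merA", "merD", "merE")
  a_start <- 101L + (seq_along(a_tok) - 1L) * 1100L   # 1000 bp genes, 100 gaps
  a_genes <- data.frame(
    gene_id = sprintf("pA_g%02d", 1:9),
    start = c(a_start, max(a_start) + 999L + 501L,
              max(a_start) + 999L + 5001L),
    end = c(a_start + 999L, max(a_start) + 999L + 501L + 899L,
            max(a_start) + 999L + 5001L + 899L),
    strand = c(rep(1L, 7L), 1L, -1L),
    product = c(a_tok, "sul1", "tetA"), stringsAsFactors = FALSE)
  pA <- plasmid_record("pA", a_genes, length_bp = 60000L,
                       topology = "linear", host_species = "Homo sapiens",
                       isolation_source = "clinical",
                       host_genus = "Klebsiella",
                       organism = "Klebsiella pneumoniae")
  # pB: merE, merD, merA laid forward, all minus strand -> canonical
  # reading order reverses to merA-merD-merE; aadA1 2000 bp downstream
  b_tok <- c("merE", "merD", "merA")
  b_start <- 201L + (seq_along(b_tok) - 1L) * 1100L
  b_genes <- data.frame(
    gene_id = sprintf("pB_g%02d", 1:4),
    start = c(b_start, max(b_start) + 999L + 2001L),
    end = c(b_start + 999L, max(b_start) + 999L + 2001L + 799L),
    strand = c(rep(-1L, 3L), 1L),
    product = c(b_tok, "aadA1"), stringsAsFactors = FALSE)
  pB <- plasmid_record("pB", b_genes, length_bp = 30000L,
                       topology = "linear", host_species = "Sus scrofa",
                       isolation_source = "pig farm",
                       host_genus = "Escherichia",
                       organism = "Escherichia coli")
  # pC: lone merA and a beta-lactam ARG 1200 bp away
  c_genes <- data.frame(
    gene_id = c("pC_g01", "pC_g02"),
    start = c(501L, 501L + 999L + 1201L),
    end = c(1500L, 501L + 999L + 1201L + 860L),
    strand = c(1L, 1L),
    product = c("merA", "blaTEM-1"), stringsAsFactors = FALSE)
  pC <- plasmid_record("pC", c_genes, length_bp = 20000L,
                       topology = "linear", host_species = "",
                       isolation_source = "activated sludge",
                       host_genus = "Shewanella",
                       organism = "Shewanella baltica")
  asn <- rbind(
    data.frame(plasmid_id = "pA",
               gene_id = sprintf("pA_g%02d", c(1:3, 5:7)),
               category = "HRG",
               gene_name = c("merR", "merT", "merP", "merA", "merD", "merE"),
               class_label = c("merR", "merT", "merP", "merA", "merD", "merE"),
               stringsAsFactors = FALSE),
    data.frame(plasmid_id = "pA", gene_id = c("pA_g08", "pA_g09"),
               category = "ARG", gene_name = c("sul1", "tetA"),
               class_label = c("sulfonamide", "tetracycline"),
               stringsAsFactors = FALSE),
    data.frame(plasmid_id = "pB", gene_id = sprintf("pB_g%02d", 1:3),
               category = "HRG", gene_name = c("merE", "merD", "merA"),
               class_label = c("merE", "merD", "merA"),
               stringsAsFactors = FALSE),
    data.frame(plasmid_id = "pB", gene_id = "pB_g04", category = "ARG",
               gene_name = "aadA1", class_label = "aminoglycoside",
               stringsAsFactors = FALSE),
    data.frame(plasmid_id = "pC", gene_id = "pC_g01", category = "HRG",
               gene_name = "merA", class_label = "merA",
               stringsAsFactors = FALSE),
    data.frame(plasmid_id = "pC", gene_id = "pC_g02", category = "ARG",
               gene_name = "blaTEM-1", class_label = "beta-lactam",
               stringsAsFactors = FALSE))
  list(records = plasmid_set(list(pA, pB, pC),
                             provenance = "toy_worked_example"),
       assignments = asn)
}
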