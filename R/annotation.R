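# ---- hit tables -------------------------------------------------------------

HIT_COLS <- c("query_id", "subject_id", "identity_pct", "aln_len",
              "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Read a tabular protein similarity-search hit table
#'
#' Accepts the standard 12-column tabular output of BLASTP-like searches
#' (query, subject, \%identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score), optionally extended with
#' two extra columns `qlen` and `slen`. When the 12-column form is given,
#' query/subject lengths must be supplied through `lengths_path`, a TSV with
#' columns `seq_id`, `length`.
#'
#' @param path Hit table path (no header).
#' @param lengths_path Optional TSV mapping sequence ids to amino-acid
#'   lengths, applied to both queries and subjects.
#' @return Data frame of hits with columns `r toString(HIT_COLS)` plus
#'   `qlen`, `slen`.
#' @export
read_hit_table <- function(path, lengths_path = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "")
  if (!ncol(tab) %in% c(12L, 14L)) {
    stop("hit table ", path, ": expected 12 or 14 columns, found ", ncol(tab))
  }
  names(tab)[1:12] <- HIT_COLS
  if (ncol(tab) == 14L) {
    names(tab)[13:14] <- c("qlen", "slen")
  } else {
    if (is.null(lengths_path)) {
      stop("hit table ", path, " has 12 columns; a lengths TSV is required")
    }
    len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
    lv <- stats::setNames(as.integer(len$length), len$seq_id)
    tab$qlen <- unname(lv[tab$query_id])
    tab$slen <- unname(lv[tab$subject_id])
    if (anyNA(tab$qlen) || anyNA(tab$slen)) {
      miss <- unique(c(tab$query_id[is.na(tab$qlen)],
                       tab$subject_id[is.na(tab$slen)]))
      stop("lengths TSV missing id(s): ", paste(utils::head(miss, 5),
                                                collapse = ", "))
    }
  }
  validate_hits(tab)
}

validate_hits <- function(hits) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  need <- c("query_id", "subject_id", "identity_pct", "aln_len", "evalue",
            "bitscore", "qlen", "slen")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("identity_pct", "evalue", "bitscore")) {
    hits[[col]] <- as.numeric(hits[[col]])
  }
  for (col in c("aln_len", "qlen", "slen")) hits[[col]] <- as.integer(hits[[col]])
  stopifnot(all(hits$identity_pct >= 0 & hits$identity_pct <= 100),
            all(hits$aln_len >= 1), all(hits$evalue >= 0),
            all(hits$qlen >= 1), all(hits$slen >= 1))
  hits
}

# empty hit frame with the right shape
empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             qlen = integer(), slen = integer(), stringsAsFactors = FALSE)
}

# ---- filtering --------------------------------------------------------------

#' Hit-acceptance criteria
#'
#' The stringent profile (e-value <= 1e-5, identity >= 80\%, coverage >=
#' 90\%) is used for all mer-operon genes and for ARGs; the lenient profile
#' applies only the e-value bound and is reserved for the hgcA/hgcB search,
#' whose plasmid homologs are too divergent for the identity/coverage bounds.
#' All thresholds are inclusive.
#'
#' @param mode `"stringent"` or `"lenient"`.
#' @param max_evalue,min_identity_pct,min_coverage_pct Override individual
#'   thresholds; `min_*` of `-Inf` disables a bound.
#' @return List of class `filter_criteria`.
#' @export
filter_criteria <- function(mode = c("stringent", "lenient"),
                            max_evalue = NULL, min_identity_pct = NULL,
                            min_coverage_pct = NULL) {
  mode <- match.arg(mode)
  def <- if (mode == "stringent") {
    list(max_evalue = 1e-5, min_identity_pct = 80, min_coverage_pct = 90)
  } else {
    list(max_evalue = 1e-5, min_identity_pct = -Inf, min_coverage_pct = -Inf)
  }
  if (!is.null(max_evalue)) def$max_evalue <- max_evalue
  if (!is.null(min_identity_pct)) def$min_identity_pct <- min_identity_pct
  if (!is.null(min_coverage_pct)) def$min_coverage_pct <- min_coverage_pct
  structure(c(def, list(mode = mode)), class = "filter_criteria")
}

#' Alignment coverage of a hit
#'
#' Coverage is alignment length over query length (the plasmid protein),
#' expressed as a percentage and capped at 100; gapped alignments can exceed
#' the query length, and a capped ratio keeps the threshold semantics of
#' "at least 90\% of the protein aligned". Subject-side coverage is
#' available for sensitivity analysis.
#'
#' @param hits Hit data frame (see [read_hit_table()]).
#' @param side `"query"` (default) or `"subject"`.
#' @return Numeric vector of coverages in \[0, 100\].
#' @export
coverage_of <- function(hits, side = c("query", "subject")) {
  side <- match.arg(side)
  len <- if (side == "query") hits$qlen else hits$slen
  if (any(len == 0L)) stop("zero sequence length in coverage computation")
  pmin(100, 100 * hits$aln_len / len)
}

#' Filter hits against acceptance criteria
#'
#' Keeps exactly the hits with `evalue <= max_evalue`, `identity_pct >=
#' min_identity_pct` and coverage `>= min_coverage_pct` (all inclusive);
#' the lenient profile bounds only the e-value.
#'
#' @param hits Hit data frame.
#' @param criteria A [filter_criteria()] object.
#' @param coverage_side Passed to [coverage_of()].
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, criteria = filter_criteria("stringent"),
                        coverage_side = "query") {
  if (!nrow(hits)) return(hits)
  keep <- hits$evalue <= criteria$max_evalue &
    hits$identity_pct >= criteria$min_identity_pct &
    coverage_of(hits, coverage_side) >= criteria$min_coverage_pct
  hits[keep, , drop = FALSE]
}

#' Best hit per query gene
#'
#' Selects, per query, the hit maximizing bit score; ties are broken by
#' minimum e-value, then maximum identity, then lexicographically smallest
#' subject id, so the choice is deterministic.
#'
#' @param hits Filtered hit data frame.
#' @return One row per distinct `query_id`.
#' @export
best_hit_per_gene <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue,
               -hits$identity_pct, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# ---- hgcAB validation -------------------------------------------------------

HGCA_MOTIF <- "G[IV]NVWC[ASG][ASG]GK"

#' Test for the conserved hgcA cap-helix motif
#'
#' The corrinoid protein HgcA carries the strictly conserved cap-helix motif
#' G(I/V)NVWC(A/S/G)(A/S/G)GK; homologs lacking it are not considered
#' genuine mercury methylation genes.
#'
#' @param protein_seq Character vector of uppercase amino-acid sequences.
#' @return Logical vector: `TRUE` where the motif occurs.
#' @export
hgca_motif_present <- function(protein_seq) {
  grepl(HGCA_MOTIF, protein_seq)
}

#' Validate hgcA/hgcB candidate assignments on one plasmid
#'
#' hgcA candidates must already have passed the cap-helix motif screen (see
#' [hgca_motif_present()]); this function enforces the pairing rule: an hgcB
#' candidate is retained only if a retained hgcA lies nearby in gene order,
#' with at most `max_sep_genes` genes between them (the same gap constant
#' used for mer cluster detection). Lone hgcB homologs are discarded.
#'
#' @param candidates Assignment data frame (columns `gene_id`, `gene_name`
#'   in `"hgcA"`/`"hgcB"`) for one plasmid.
#' @param plasmid The [plasmid_record()] the candidates live on.
#' @param max_sep_genes Maximum number of genes between hgcB and the nearest
#'   retained hgcA (default 2).
#' @return The retained candidate rows.
#' @export
validate_hgcab <- function(candidates, plasmid, max_sep_genes = 2L) {
  if (!nrow(candidates)) return(candidates)
  ranks <- stats::setNames(plasmid$genes$rank, plasmid$genes$gene_id)
  a_rows <- candidates$gene_name == "hgcA"
  a_ranks <- unname(ranks[candidates$gene_id[a_rows]])
  keep_b <- function(gid) {
    if (!length(a_ranks)) return(FALSE)
    min(abs(a_ranks - ranks[[gid]])) - 1L <= max_sep_genes
  }
  b_keep <- vapply(candidates$gene_id, keep_b, logical(1))
  keep <- a_rows | (candidates$gene_name == "hgcB" & b_keep)
  candidates[keep, , drop = FALSE]
}

# ---- reference catalogues ---------------------------------------------------

#' Construct a reference catalogue
#'
#' A catalogue maps similarity-search subject ids to a gene name (e.g.
#' `merA`) and a class label (for mercury-related genes the class is the gene
#' name; for ARGs it is the resistance class, e.g. `sulfonamide`).
#'
#' @param entries Data frame with columns `subject_id`, `gene_name`,
#'   `class_label` and optionally `source_db`.
#' @return Data frame of class `reference_catalogue`.
#' @export
reference_catalogue <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("subject_id", "gene_name", "class_label")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("catalogue missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(entries$source_db)) entries$source_db <- ""
  if (anyDuplicated(entries$subject_id)) {
    stop("catalogue subject_id not unique: ",
         paste(unique(entries$subject_id[duplicated(entries$subject_id)]),
               collapse = ", "))
  }
  if (any(!nzchar(entries$gene_name)) || any(!nzchar(entries$class_label))) {
    stop("catalogue entries must have nonempty gene_name and class_label")
  }
  rownames(entries) <- NULL
  class(entries) <- c("reference_catalogue", "data.frame")
  entries
}

#' Read a SARG-shaped catalogue (FASTA + list file)
#'
#' The sequence file is a protein FASTA whose headers are
#' `uniqueID annotation`; the list file is tab-delimited with column 1
#' `class__name` (class and gene name separated by two consecutive
#' underscores) and column 2 a comma-separated run of sequence ids.
#'
#' @param fasta_path Protein FASTA path (sequences are not retained).
#' @param list_path List-file path.
#' @param source_db Label recorded for provenance.
#' @return A [reference_catalogue()].
#' @export
read_sarg_catalogue <- function(fasta_path, list_path, source_db = "") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L)
  rows <- parse_arg_list(list_path)
  entries <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    id_vec <- strsplit(rows$ids[i], ",", fixed = TRUE)[[1]]
    data.frame(subject_id = trimws(id_vec), gene_name = rows$arg_name[i],
               class_label = rows$class_name[i], source_db = source_db,
               stringsAsFactors = FALSE)
  }))
  unknown <- setdiff(entries$subject_id, ids)
  if (length(unknown)) {
    stop("list file references ids absent from FASTA: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  reference_catalogue(entries)
}

#' Parse a SARG-shaped list file into (class, name, ids) rows
#'
#' @param path List-file path (no header).
#' @return Data frame with columns `class_name`, `arg_name`, `ids`.
#' @export
parse_arg_list <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           quote = "")
  if (ncol(tab) < 2L) stop("list file ", path, ": expected 2 columns")
  key <- tab[[1]]
  pos <- regexpr("__", key, fixed = TRUE)
  if (any(pos < 0)) {
    stop("list file ", path, ": no '__' separator in '",
         key[which(pos < 0)[1]], "'")
  }
  data.frame(class_name = substr(key, 1, pos - 1L),
             arg_name = substring(key, pos + 2L),
             ids = tab[[2]], stringsAsFactors = FALSE)
}

#' Build a mercury-gene catalogue from a BacMet-format mapping file
#'
#' Utility over the tab-delimited BacMet gene annotation mapping file:
#' selects rows whose `Compound` column contains the keyword (default
#' `"Mercury"`, case-insensitive) and emits a catalogue keyed by the mapping
#' file's sequence ids with the gene name as class label.
#'
#' @param mapping_path Mapping file path (header with at least columns
#'   `Gene_name`, `Compound` and an id column, by default the first).
#' @param keyword Compound keyword to select (substring match).
#' @param id_column Name of the sequence-id column; default first column.
#' @return A [reference_catalogue()].
#' @export
bacmet_keyword_catalogue <- function(mapping_path, keyword = "Mercury",
                                     id_column = NULL) {
  tab <- utils::read.delim(mapping_path, stringsAsFactors = FALSE, quote = "")
  if (is.null(id_column)) id_column <- names(tab)[1]
  need <- c(id_column, "Gene_name", "Compound")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("mapping file missing column(s): ",
                         paste(miss, collapse = ", "))
  sel <- grepl(keyword, tab$Compound, ignore.case = TRUE)
  reference_catalogue(data.frame(
    subject_id = tab[[id_column]][sel], gene_name = tab$Gene_name[sel],
    class_label = tab$Gene_name[sel], source_db = "bacmet",
    stringsAsFactors = FALSE))
}

# ---- ARG class harmonization ------------------------------------------------

#' Harmonize ARG class names of secondary catalogues against a primary one
#'
#' Two-step name matching: (1) an ARG whose name is identical to a
#' primary-catalogue ARG name adopts that primary class ("name-match");
#' (2) any remaining ARG whose raw class name equals a raw class name that
#' was re-mapped in step 1 adopts the same harmonized class
#' ("class-propagation"). ARGs matched by neither step are flagged
#' "similarity-fallback" for [fallback_class_assignment()].
#'
#' If one raw class was re-mapped to several different primary classes in
#' step 1, propagation uses the most frequent target, ties broken
#' lexicographically.
#'
#' @param primary_list Data frame of `(class_name, arg_name, ids)` rows for
#'   the primary catalogue (see [parse_arg_list()]).
#' @param other_lists Named list of such data frames for the secondary
#'   catalogues.
#' @return Data frame (class `class_mapping`) with one row per secondary
#'   ARG: `source_db`, `arg_name`, `class_name_raw`, `class_name_harmonized`,
#'   `rule_applied`.
#' @export
harmonize_arg_classes <- function(primary_list, other_lists) {
  primary_class <- tapply(primary_list$class_name, primary_list$arg_name,
                          function(x) unique(x), simplify = FALSE)
  ambiguous <- names(primary_class)[lengths(primary_class) > 1L]
  if (length(ambiguous)) {
    stop("ARG name(s) mapping to multiple primary classes: ",
         paste(ambiguous, collapse = ", "))
  }
  primary_class <- vapply(primary_class, `[[`, character(1), 1L)
  if (is.null(names(other_lists))) names(other_lists) <- paste0("db", seq_along(other_lists))

  rows <- do.call(rbind, lapply(names(other_lists), function(db) {
    x <- other_lists[[db]]
    data.frame(source_db = db, arg_name = x$arg_name,
               class_name_raw = x$class_name,
               class_name_harmonized = NA_character_,
               rule_applied = NA_character_, stringsAsFactors = FALSE)
  }))

  # step 1: exact ARG-name match to the primary catalogue
  hit1 <- rows$arg_name %in% names(primary_class)
  rows$class_name_harmonized[hit1] <- unname(primary_class[rows$arg_name[hit1]])
  rows$rule_applied[hit1] <- "name-match"

  # step 2: propagate the step-1 class to all other ARGs sharing the raw class
  if (any(hit1)) {
    prop <- rows[hit1, c("class_name_raw", "class_name_harmonized")]
    prop_map <- tapply(prop$class_name_harmonized, prop$class_name_raw,
                       function(y) {
                         tt <- sort(table(y), decreasing = TRUE)
                         top <- names(tt)[tt == max(tt)]
                         sort(top)[1]
                       })
    hit2 <- !hit1 & rows$class_name_raw %in% names(prop_map)
    rows$class_name_harmonized[hit2] <- unname(prop_map[rows$class_name_raw[hit2]])
    rows$rule_applied[hit2] <- "class-propagation"
  }

  rest <- is.na(rows$rule_applied)
  rows$rule_applied[rest] <- "similarity-fallback"
  rownames(rows) <- NULL
  class(rows) <- c("class_mapping", "data.frame")
  rows
}

#' Similarity-based class assignment for unmatched ARGs
#'
#' The residue of the two-step name harmonization is resolved by a
#' similarity search against the primary catalogue under the stringent
#' criteria (e-value <= 1e-5, identity >= 80\%, coverage >= 90\%): each
#' unmatched ARG adopts the class of its best surviving hit, or the class
#' `"unmatched"` when no hit survives.
#'
#' @param unmatched Character vector of ARG names (the hit tables' query
#'   ids) still lacking a class.
#' @param primary_catalogue [reference_catalogue()] of the primary database.
#' @param hits Hit table of the unmatched ARGs queried against the primary
#'   catalogue.
#' @param criteria Acceptance criteria, default stringent.
#' @return Data frame with columns `arg_name`, `class_name_harmonized`,
#'   `rule_applied` (`"similarity-fallback"` or `"unmatched"`).
#' @export
fallback_class_assignment <- function(unmatched, primary_catalogue, hits,
                                      criteria = filter_criteria("stringent")) {
  best <- best_hit_per_gene(filter_hits(validate_hits(hits), criteria))
  cls <- stats::setNames(primary_catalogue$class_label,
                         primary_catalogue$subject_id)
  assigned <- stats::setNames(unname(cls[best$subject_id]), best$query_id)
  out <- data.frame(arg_name = unmatched,
                    class_name_harmonized = unname(assigned[unmatched]),
                    stringsAsFactors = FALSE)
  out$rule_applied <- ifelse(is.na(out$class_name_harmonized), "unmatched",
                             "similarity-fallback")
  out$class_name_harmonized[is.na(out$class_name_harmonized)] <- "unmatched"
  out
}

# ---- dataset annotation -----------------------------------------------------

#' Annotate a plasmid dataset with HRG and ARG assignments
#'
#' Per gene, at most one mercury-related gene (HRG) assignment and at most
#' one antibiotic-resistance gene (ARG) assignment are made (the categories
#' are independent: a gene may carry both). mer-operon genes are called
#' under the stringent criteria; hgcA/hgcB travel the lenient path, with
#' hgcA additionally screened for the cap-helix motif (candidates without a
#' supplied protein sequence or without the motif are discarded) and hgcB
#' retained only near a valid hgcA ([validate_hgcab()]).
#'
#' @param records A [plasmid_set()].
#' @param hrg_hits,arg_hits Hit tables (queries are gene ids of `records`).
#' @param hrg_catalogue,arg_catalogue [reference_catalogue()] objects; hgcA
#'   and hgcB entries are recognized by `gene_name`.
#' @param protein_seqs Named character vector of query protein sequences,
#'   needed only for the hgcA motif screen.
#' @param max_sep_genes hgcB adjacency bound, see [validate_hgcab()].
#' @param coverage_side Passed to [coverage_of()].
#' @return Data frame of assignments: `plasmid_id`, `gene_id`, `category`
#'   (`"HRG"`/`"ARG"`), `gene_name`, `class_label`, `identity`, `coverage`,
#'   `evalue`, `bitscore`.
#' @export
annotate_dataset <- function(records, hrg_hits = NULL, arg_hits = NULL,
                             hrg_catalogue = NULL, arg_catalogue = NULL,
                             protein_seqs = NULL, max_sep_genes = 2L,
                             coverage_side = "query") {
  if (!inherits(records, "plasmid_set")) records <- plasmid_set(records)
  gene_map <- gene_plasmid_map(records)

  out <- list()
  if (!is.null(hrg_hits) && nrow(hrg_hits)) {
    stopifnot(!is.null(hrg_catalogue))
    hrg_hits <- validate_hits(hrg_hits)
    check_known_queries(hrg_hits, gene_map)
    cat_name <- stats::setNames(hrg_catalogue$gene_name,
                                hrg_catalogue$subject_id)
    unknown <- setdiff(hrg_hits$subject_id, names(cat_name))
    if (length(unknown)) stop("HRG hits reference uncatalogued subject(s): ",
                              paste(utils::head(unknown, 5), collapse = ", "))
    is_hgc <- cat_name[hrg_hits$subject_id] %in% c("hgcA", "hgcB")
    mer_ok <- filter_hits(hrg_hits[!is_hgc, , drop = FALSE],
                          filter_criteria("stringent"), coverage_side)
    hgc_ok <- filter_hits(hrg_hits[is_hgc, , drop = FALSE],
                          filter_criteria("lenient"), coverage_side)
    # motif screen on hgcA candidates
    if (nrow(hgc_ok)) {
      is_a <- cat_name[hgc_ok$subject_id] == "hgcA"
      if (any(is_a)) {
        keep <- rep(TRUE, nrow(hgc_ok))
        seqs <- if (is.null(protein_seqs)) {
          rep(NA_character_, sum(is_a))
        } else {
          protein_seqs[hgc_ok$query_id[is_a]]
        }
        keep[which(is_a)] <- !is.na(seqs) & hgca_motif_present(seqs)
        hgc_ok <- hgc_ok[keep, , drop = FALSE]
      }
    }
    best <- best_hit_per_gene(rbind(mer_ok, hgc_ok))
    hrg_asn <- assignments_from_hits(best, hrg_catalogue, gene_map, "HRG",
                                     coverage_side)
    # pairing rule, per plasmid
    if (nrow(hrg_asn)) {
      keep <- unlist(lapply(split(seq_len(nrow(hrg_asn)), hrg_asn$plasmid_id),
                            function(idx) {
        sub <- hrg_asn[idx, , drop = FALSE]
        if (!any(sub$gene_name %in% c("hgcA", "hgcB"))) return(idx)
        valid <- validate_hgcab(sub[sub$gene_name %in% c("hgcA", "hgcB"), ,
                                    drop = FALSE],
                                records[[sub$plasmid_id[1]]], max_sep_genes)
        idx[!(sub$gene_name %in% c("hgcA", "hgcB")) |
              sub$gene_id %in% valid$gene_id]
      }))
      hrg_asn <- hrg_asn[sort(keep), , drop = FALSE]
    }
    out$hrg <- hrg_asn
  }
  if (!is.null(arg_hits) && nrow(arg_hits)) {
    stopifnot(!is.null(arg_catalogue))
    arg_hits <- validate_hits(arg_hits)
    check_known_queries(arg_hits, gene_map)
    unknown <- setdiff(arg_hits$subject_id, arg_catalogue$subject_id)
    if (length(unknown)) stop("ARG hits reference uncatalogued subject(s): ",
                              paste(utils::head(unknown, 5), collapse = ", "))
    best <- best_hit_per_gene(filter_hits(arg_hits,
                                          filter_criteria("stringent"),
                                          coverage_side))
    out$arg <- assignments_from_hits(best, arg_catalogue, gene_map, "ARG",
                                     coverage_side)
  }
  res <- do.call(rbind, c(out, list(empty_assignments())))
  res <- res[order(res$plasmid_id, res$gene_id, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_assignments <- function() {
  data.frame(plasmid_id = character(), gene_id = character(),
             category = character(), gene_name = character(),
             class_label = character(), identity = numeric(),
             coverage = numeric(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

gene_plasmid_map <- function(records) {
  ids <- unlist(lapply(records, function(r) r$genes$gene_id), use.names = FALSE)
  pid <- rep(names(records),
             vapply(records, function(r) nrow(r$genes), integer(1)))
  if (anyDuplicated(ids)) {
    stop("gene ids are not unique across plasmids: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  stats::setNames(pid, ids)
}

check_known_queries <- function(hits, gene_map) {
  unknown <- setdiff(hits$query_id, names(gene_map))
  if (length(unknown)) {
    stop("hit table references unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
}

assignments_from_hits <- function(best, catalogue, gene_map, category,
                                  coverage_side) {
  if (!nrow(best)) return(empty_assignments())
  idx <- match(best$subject_id, catalogue$subject_id)
  data.frame(plasmid_id = unname(gene_map[best$query_id]),
             gene_id = best$query_id, category = category,
             gene_name = catalogue$gene_name[idx],
             class_label = catalogue$class_label[idx],
             identity = best$identity_pct,
             coverage = coverage_of(best, coverage_side),
             evalue = best$evalue, bitscore = best$bitscore,
             stringsAsFactors = FALSE)
}

#' Write an assignments table to TSV
#'
#' @param assignments Assignment data frame from [annotate_dataset()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
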