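# ---- data model -------------------------------------------------------------

GENE_COLS <- c("gene_id", "start", "end", "strand", "product", "rank")

#' Construct a plasmid record
#'
#' A plasmid record bundles the ordered protein-coding gene complement of one
#' plasmid with its replicon length, topology and host metadata. Genes are
#' re-sorted by start coordinate (ties broken by end, then gene id) and given
#' consecutive 0-based ranks, so downstream rank arithmetic (cluster gaps,
#' hgcB adjacency) is well defined.
#'
#' @param plasmid_id Unique plasmid identifier.
#' @param genes Data frame with columns `gene_id`, `start`, `end`, `strand`
#'   (`+1`/`-1` integers or `"+"`/`"-"`), `product`. Coordinates are 1-based
#'   inclusive base pairs, `end >= start`.
#' @param length_bp Replicon length in bp; defaults to the maximum gene end.
#' @param topology `"linear"` or `"circular"`.
#' @param host_species,host_genus,isolation_source Host metadata strings;
#'   empty string when unknown (never invented). `host_species` is the
#'   organism the bacterium was isolated from (the GenBank `/host`
#'   qualifier); `host_genus` is the bacterial genus.
#' @param organism Full bacterial organism name (GenBank ORGANISM line).
#' @return An object of class `plasmid_record`.
#' @export
plasmid_record <- function(plasmid_id, genes,
                           length_bp = NULL,
                           topology = c("linear", "circular"),
                           host_species = "", host_genus = "",
                           isolation_source = "", organism = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(plasmid_id), length(plasmid_id) == 1L,
            nzchar(plasmid_id))
  genes <- normalize_genes(genes, plasmid_id)
  if (is.null(length_bp)) {
    length_bp <- if (nrow(genes)) max(genes$end) else 0L
  }
  length_bp <- as.integer(length_bp)
  if (nrow(genes) && any(genes$end > length_bp)) {
    stop("plasmid '", plasmid_id, "': gene end exceeds length_bp")
  }
  structure(list(plasmid_id = plasmid_id,
                 length_bp = length_bp,
                 topology = topology,
                 genes = genes,
                 host_species = host_species,
                 host_genus = host_genus,
                 isolation_source = isolation_source,
                 organism = organism),
            class = "plasmid_record")
}

# Sort genes by (start, end, gene_id), assign 0-based ranks, coerce types.
normalize_genes <- function(genes, plasmid_id = "?") {
  if (is.null(genes) || nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = integer(),
                      product = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(genes$product)) genes$product <- ""
  genes$gene_id <- as.character(genes$gene_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- parse_strand(genes$strand)
  genes$product <- as.character(genes$product)
  if (anyNA(genes$start) || anyNA(genes$end)) {
    stop("plasmid '", plasmid_id, "': non-integer gene coordinates")
  }
  if (any(genes$start < 1L)) {
    stop("plasmid '", plasmid_id, "': gene start < 1")
  }
  if (any(genes$end < genes$start)) {
    stop("plasmid '", plasmid_id, "': gene end < start")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("plasmid '", plasmid_id, "': duplicated gene_id")
  }
  ord <- order(genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, c("gene_id", "start", "end", "strand", "product"),
                 drop = FALSE]
  genes$rank <- seq_len(nrow(genes)) - 1L
  rownames(genes) <- NULL
  genes
}

parse_strand <- function(x) {
  if (is.numeric(x)) {
    s <- as.integer(x)
  } else {
    x <- as.character(x)
    s <- ifelse(x %in% c("+", "+1", "1"), 1L,
                ifelse(x %in% c("-", "-1"), -1L, NA_integer_))
  }
  if (any(!s %in% c(1L, -1L))) {
    stop("unknown strand symbol: ",
         paste(unique(x[!s %in% c(1L, -1L)]), collapse = ", "))
  }
  s
}

strand_symbol <- function(s) ifelse(s > 0L, "+", "-")

#' @export
print.plasmid_record <- function(x, ...) {
  cat(sprintf("<plasmid_record> %s: %s bp (%s), %d genes\n",
              x$plasmid_id, format(x$length_bp, big.mark = ","),
              x$topology, nrow(x$genes)))
  meta <- c(host = x$host_species, genus = x$host_genus,
            source = x$isolation_source)
  meta <- meta[nzchar(meta)]
  if (length(meta)) {
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = "; "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Bundle plasmid records into a dataset
#'
#' @param records List of [plasmid_record()] objects with unique ids.
#' @param provenance Free-text note on where the records came from.
#' @return Object of class `plasmid_set`: a named list of records with a
#'   `provenance` attribute.
#' @export
plasmid_set <- function(records, provenance = "") {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1), "plasmid_record")
  if (!all(ok)) stop("all elements must be plasmid_record objects")
  ids <- vapply(records, `[[`, character(1), "plasmid_id")
  if (anyDuplicated(ids)) {
    stop("duplicated plasmid_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(records) <- ids
  structure(records, class = "plasmid_set", provenance = provenance)
}

#' @export
print.plasmid_set <- function(x, ...) {
  ng <- sum(vapply(x, function(r) nrow(r$genes), integer(1)))
  cat(sprintf("<plasmid_set> %d plasmids, %d genes\n", length(x), ng))
  invisible(x)
}

#' @export
`[.plasmid_set` <- function(x, i) {
  plasmid_set(unclass(x)[i], provenance = attr(x, "provenance"))
}

# ---- GenBank reader ---------------------------------------------------------

#' Read plasmid annotations from a GenBank flat file
#'
#' Parses one or more LOCUS records, extracting every CDS feature as a gene
#' (compound `join(...)`/`complement(...)` locations collapse to their
#' min..max extent, strand taken from the complement flag) together with the
#' replicon length and topology from the LOCUS line and host metadata from
#' the source feature. Absent qualifiers map to empty strings; metadata is
#' never invented.
#'
#' Gene ids are taken from `/locus_tag`, falling back to `/protein_id` then
#' `/gene`. A record whose CDS coordinates are irreparably inverted is
#' skipped with a warning rather than aborting the whole file.
#'
#' @param path Path to a GenBank flat file (possibly multi-record).
#' @return A [plasmid_set()].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  starts <- grep("^LOCUS ", lines)
  if (!length(starts)) stop("malformed GenBank (no LOCUS line): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  records <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    rec <- tryCatch(parse_genbank_record(chunk),
                    error = function(e) {
                      warning("skipping GenBank record starting at line ",
                              starts[k], ": ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  plasmid_set(records, provenance = paste0("genbank:", path))
}

parse_genbank_record <- function(chunk) {
  locus <- strsplit(trimws(chunk[1]), "[[:space:]]+")[[1]]
  if (length(locus) < 3L) stop("malformed LOCUS line")
  plasmid_id <- locus[2]
  bp_i <- which(locus == "bp")
  length_bp <- if (length(bp_i)) suppressWarnings(as.integer(locus[bp_i[1] - 1L])) else NA_integer_
  if (is.na(length_bp)) stop("record '", plasmid_id, "': no length on LOCUS line")
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  organism <- ""
  org_i <- grep("^  ORGANISM ", chunk)
  if (length(org_i)) organism <- trimws(sub("^  ORGANISM ", "", chunk[org_i[1]]))

  feat_i <- grep("^FEATURES", chunk)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", chunk)
  feats <- character()
  if (length(feat_i)) {
    stop_at <- feat_end[feat_end > feat_i[1]]
    stop_at <- if (length(stop_at)) min(stop_at) - 1L else length(chunk)
    if (stop_at > feat_i[1]) feats <- chunk[(feat_i[1] + 1L):stop_at]
  }

  # split the feature table into individual features (key at column 6)
  keys_i <- grep("^     [A-Za-z']", feats)
  host <- ""; iso <- ""
  genes <- list()
  for (j in seq_along(keys_i)) {
    from <- keys_i[j]
    to <- if (j < length(keys_i)) keys_i[j + 1L] - 1L else length(feats)
    block <- feats[from:to]
    key <- sub("^\\s+", "", substr(block[1], 1, 20))
    key <- strsplit(key, "[[:space:]]+")[[1]][1]
    if (key == "source") {
      q <- genbank_qualifiers(block)
      if (!is.null(q[["host"]])) host <- q[["host"]]
      if (!is.null(q[["isolation_source"]])) iso <- q[["isolation_source"]]
    } else if (key == "CDS") {
      loc_txt <- paste0(sub("^\\s*CDS\\s*", "", block[1]),
                        genbank_location_continuation(block))
      loc <- parse_genbank_location(loc_txt)
      if (loc$end < loc$start) {
        stop("CDS with end < start and no join/complement semantics (",
             loc_txt, ")")
      }
      q <- genbank_qualifiers(block)
      gid <- q[["locus_tag"]]
      if (is.null(gid)) gid <- q[["protein_id"]]
      if (is.null(gid)) gid <- q[["gene"]]
      if (is.null(gid)) stop("CDS at ", loc_txt, " lacks an id qualifier")
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, start = loc$start, end = loc$end,
        strand = loc$strand,
        product = if (is.null(q[["product"]])) "" else q[["product"]],
        stringsAsFactors = FALSE)
    }
  }
  gene_df <- if (length(genes)) do.call(rbind, genes) else NULL
  host_genus <- if (nzchar(organism)) strsplit(organism, "[[:space:]]+")[[1]][1] else ""
  plasmid_record(plasmid_id, gene_df, length_bp = length_bp,
                 topology = topology, host_species = host,
                 host_genus = host_genus, isolation_source = iso,
                 organism = organism)
}

# location text may wrap onto following lines before the first qualifier
genbank_location_continuation <- function(block) {
  if (length(block) < 2L) return("")
  extra <- character()
  for (ln in block[-1]) {
    t <- trimws(ln)
    if (startsWith(t, "/")) break
    extra <- c(extra, t)
  }
  paste(extra, collapse = "")
}

parse_genbank_location <- function(txt) {
  strand <- if (grepl("complement", txt, fixed = TRUE)) -1L else 1L
  nums <- regmatches(txt, gregexpr("[0-9]+", txt))[[1]]
  if (!length(nums)) stop("unparseable location: ", txt)
  nums <- as.numeric(nums)
  has_compound <- grepl("join|complement|order", txt)
  if (!has_compound && length(nums) >= 2 && nums[2] < nums[1]) {
    # literal "500..100": report as inverted, caller decides
    return(list(start = as.integer(nums[2]), end = as.integer(nums[1]),
                strand = strand, inverted = TRUE))
  }
  list(start = as.integer(min(nums)), end = as.integer(max(nums)),
       strand = strand, inverted = FALSE)
}

genbank_qualifiers <- function(block) {
  txt <- trimws(block[-1])
  out <- list()
  cur_key <- NULL; cur_val <- NULL; open <- FALSE
  flush <- function() {
    if (!is.null(cur_key) && is.null(out[[cur_key]])) out[[cur_key]] <<- cur_val
  }
  for (ln in txt) {
    if (startsWith(ln, "/") && !open) {
      flush()
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) {
        cur_key <- substring(ln, 2); cur_val <- ""; open <- FALSE
        next
      }
      cur_key <- substring(ln, 2, eq - 1L)
      val <- substring(ln, eq + 1L)
      if (startsWith(val, "\"")) {
        val <- substring(val, 2)
        if (endsWith(val, "\"")) {
          cur_val <- substring(val, 1, nchar(val) - 1L); open <- FALSE
        } else {
          cur_val <- val; open <- TRUE
        }
      } else {
        cur_val <- val; open <- FALSE
      }
    } else if (open) {
      if (endsWith(ln, "\"")) {
        cur_val <- paste(cur_val, substring(ln, 1, nchar(ln) - 1L))
        open <- FALSE
      } else {
        cur_val <- paste(cur_val, ln)
      }
    }
  }
  flush()
  out
}

# ---- tabular reader / writer ------------------------------------------------

#' Read plasmids from a tab-separated gene table
#'
#' The gene table is the flat interchange format of the package: one row per
#' CDS with columns `plasmid_id`, `gene_id`, `start`, `end`, `strand`
#' (`+`/`-`), `product`. An optional metadata sidecar supplies host strings,
#' topology and replicon length; without it the length defaults to the last
#' gene end and the topology to linear.
#'
#' @param path Gene table path (TSV with header).
#' @param metadata_path Optional metadata sidecar TSV with columns
#'   `plasmid_id`, `host_species`, `host_genus`, `isolation_source`,
#'   `topology`, `length_bp`.
#' @return A [plasmid_set()].
#' @export
read_gene_table <- function(path, metadata_path = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("plasmid_id", "gene_id", "start", "end", "strand", "product")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("gene table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & nzchar(tab[[col]]))
    if (length(bad)) {
      stop("gene table ", path, " line ", bad[1] + 1L,
           ": non-integer ", col, " '", tab[[col]][bad[1]], "'")
    }
    tab[[col]] <- v
  }
  bad <- which(!tab$strand %in% c("+", "-", "+1", "-1", "1"))
  if (length(bad)) {
    stop("gene table ", path, " line ", bad[1] + 1L,
         ": unknown strand symbol '", tab$strand[bad[1]], "'")
  }
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, colClasses = "character",
                              stringsAsFactors = FALSE, quote = "")
    rownames(meta) <- meta$plasmid_id
  }
  ids <- unique(tab$plasmid_id)
  records <- lapply(ids, function(pid) {
    g <- tab[tab$plasmid_id == pid, , drop = FALSE]
    m <- if (!is.null(meta) && pid %in% rownames(meta)) meta[pid, ] else NULL
    get_m <- function(col, default) {
      if (!is.null(m) && col %in% names(m) && nzchar(m[[col]])) m[[col]] else default
    }
    plasmid_record(
      pid, g[, c("gene_id", "start", "end", "strand", "product")],
      length_bp = as.integer(get_m("length_bp", max(g$end))),
      topology = get_m("topology", "linear"),
      host_species = get_m("host_species", ""),
      host_genus = get_m("host_genus", ""),
      isolation_source = get_m("isolation_source", ""),
      organism = get_m("organism", ""))
  })
  plasmid_set(records, provenance = paste0("gene_table:", path))
}

#' Write a plasmid dataset to gene-table (and optional metadata) TSVs
#'
#' Output ordering is deterministic: plasmids by id, genes by start
#' coordinate, so equal datasets produce byte-identical files.
#'
#' @param records A [plasmid_set()] or list of records.
#' @param path Output gene table path.
#' @param metadata_path Optional output path for the metadata sidecar.
#' @export
write_gene_table <- function(records, path, metadata_path = NULL) {
  if (!inherits(records, "plasmid_set")) records <- plasmid_set(records)
  ids <- sort(names(records))
  rows <- lapply(ids, function(pid) {
    g <- records[[pid]]$genes
    if (!nrow(g)) return(NULL)
    data.frame(plasmid_id = pid, gene_id = g$gene_id, start = g$start,
               end = g$end, strand = strand_symbol(g$strand),
               product = g$product, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(
    data.frame(plasmid_id = character(), gene_id = character(),
               start = integer(), end = integer(), strand = character(),
               product = character(), stringsAsFactors = FALSE))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- do.call(rbind, lapply(ids, function(pid) {
      r <- records[[pid]]
      data.frame(plasmid_id = pid, host_species = r$host_species,
                 host_genus = r$host_genus,
                 isolation_source = r$isolation_source,
                 organism = r$organism,
                 topology = r$topology, length_bp = r$length_bp,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Dataset manifest: recomputed totals for a plasmid set
#'
#' @param records A [plasmid_set()].
#' @return List with `n_plasmids`, `n_genes`, `provenance`.
#' @export
dataset_manifest <- function(records) {
  list(n_plasmids = length(records),
       n_genes = sum(vapply(records, function(r) nrow(r$genes), integer(1))),
       provenance = attr(records, "provenance"))
}
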