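# ---- host-source classification ---------------------------------------------

HOST_SOURCE_CATEGORIES <- c("human", "animal", "wastewater and sludge",
                            "miscellaneous sources")

#' Load host-source classification rules
#'
#' Rules are a YAML file listing categories in precedence order, each with
#' lowercase keywords matched as substrings against the host and
#' isolation-source metadata. The packaged default covers the four
#' categories human, animal, wastewater and sludge, miscellaneous sources.
#'
#' @param path YAML path; `NULL` loads the packaged default.
#' @return List of rules, each `list(category, keywords)`.
#' @export
host_source_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "host_source_rules.yaml",
                        package = "plasmidcodist")
  }
  y <- yaml::read_yaml(path)
  rules <- y$rules
  cats <- vapply(rules, `[[`, character(1), "category")
  miss <- setdiff(HOST_SOURCE_CATEGORIES, cats)
  if (length(miss)) {
    stop("rules file must cover categories: ", paste(miss, collapse = ", "))
  }
  rules
}

#' Classify plasmids into host-source categories
#'
#' The first rule (in file order, i.e. human, then animal, then wastewater
#' and sludge, then miscellaneous) whose keyword occurs as a substring of
#' either the host species or the isolation source wins. Nonempty metadata
#' matching no rule falls back to `"miscellaneous sources"`; plasmids with
#' both fields empty get `NA`.
#'
#' @param records A [plasmid_set()] (or single [plasmid_record()]).
#' @param rules Rules from [host_source_rules()].
#' @return Named character vector of categories (`NA` for unknown).
#' @export
classify_host_source <- function(records, rules = host_source_rules()) {
  if (inherits(records, "plasmid_record")) records <- plasmid_set(list(records))
  vapply(records, function(r) {
    hay <- tolower(paste(r$host_species, r$isolation_source, sep = "\n"))
    if (!nzchar(r$host_species) && !nzchar(r$isolation_source)) {
      return(NA_character_)
    }
    for (rule in rules) {
      if (any(vapply(rule$keywords, grepl, logical(1), x = hay,
                     fixed = TRUE))) {
        return(rule$category)
      }
    }
    "miscellaneous sources"
  }, character(1))
}

#' Read a pathogenicity map
#'
#' A static snapshot TSV with columns `species` and `label`
#' (`pathogen` / `non-pathogen`); species not listed classify as
#' `"unknown"`.
#'
#' @param path TSV path.
#' @return Named character vector species -> label.
#' @export
read_pathogenicity_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("species", "label") %in% names(tab)))
  bad <- setdiff(unique(tab$label), c("pathogen", "non-pathogen"))
  if (length(bad)) stop("unknown pathogenicity label(s): ",
                        paste(bad, collapse = ", "))
  stats::setNames(tab$label, tab$species)
}

#' Classify plasmids by host pathogenicity
#'
#' The bacterial species binomial (first two tokens of the organism name)
#' is looked up in the map; unlisted or missing species give `"unknown"`.
#'
#' @param records A [plasmid_set()].
#' @param map Named vector from [read_pathogenicity_map()].
#' @return Named character vector: `pathogen`, `non-pathogen` or `unknown`.
#' @export
classify_pathogenicity <- function(records, map) {
  vapply(records, function(r) {
    if (!nzchar(r$organism)) return("unknown")
    toks <- strsplit(trimws(r$organism), "[[:space:]]+")[[1]]
    sp <- paste(utils::head(toks, 2L), collapse = " ")
    if (sp %in% names(map)) unname(map[[sp]]) else "unknown"
  }, character(1))
}

# ---- rank-based group statistics --------------------------------------------

#' Significance band for a p-value
#'
#' Bands follow the usual figure-caption convention: `ns` (>= 0.05), `*`
#' (< 0.05), `**` (< 0.01), `***` (< 0.001), `****` (< 0.0001).
#'
#' @param p P-value(s).
#' @return Character vector of bands.
#' @export
significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom. When every observation is identical the rank
#' variance vanishes; that degenerate case is reported as H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, each nonempty.
#' @return List of class `group_test_result`: `statistic`, `p_value`, `df`,
#'   `groups`, `method`, `significance_band`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_groups = 2L)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  cfac <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cfac == 0) {
    h <- 0; p <- 1
  } else {
    h <- h / cfac
    p <- stats::pchisq(h, length(groups) - 1L, lower.tail = FALSE)
  }
  group_test_result(h, p, df = length(groups) - 1L,
                    groups = names_or_index(groups),
                    method = "kruskal-wallis")
}

#' Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sample rank-sum statistic W (the Mann-Whitney U of the first
#' sample), with tie-corrected variance and continuity correction, tested
#' against the normal approximation, two-sided.
#'
#' @param x,y Numeric samples.
#' @return A `group_test_result`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  z <- w - nx * ny / 2
  ties <- table(r)
  sigma <- sqrt((nx * ny / 12) *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  if (sigma == 0) {
    p <- 1
  } else {
    zc <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE))
  }
  group_test_result(w, p, df = NA_integer_, groups = c("x", "y"),
                    method = "wilcoxon-rank-sum")
}

#' Pairwise Wilcoxon rank-sum tests after a Kruskal-Wallis gate
#'
#' Runs [kruskal_wallis()] first; the pairwise rank-sum tests are executed
#' only when its p-value passes the gate (default 0.05), mirroring the
#' usual two-stage group comparison.
#'
#' @param groups Named list of numeric vectors.
#' @param gate_p Kruskal-Wallis p-value required to proceed.
#' @return List with `kruskal` (a `group_test_result`) and `pairwise`
#'   (list of `group_test_result`, empty when gated out).
#' @export
pairwise_wilcoxon <- function(groups, gate_p = 0.05) {
  kw <- kruskal_wallis(groups)
  out <- list(kruskal = kw, pairwise = list())
  if (!is.na(kw$p_value) && kw$p_value < gate_p) {
    nm <- names_or_index(groups)
    cmb <- utils::combn(length(groups), 2L)
    out$pairwise <- lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      res <- wilcoxon_rank_sum(groups[[i]], groups[[j]])
      res$groups <- c(nm[i], nm[j])
      res
    })
    names(out$pairwise) <- apply(cmb, 2L,
                                 function(ij) paste(nm[ij], collapse = " vs "))
  } else {
    message("Kruskal-Wallis p = ", format(kw$p_value),
            " >= ", gate_p, "; pairwise tests not run")
  }
  out
}

#' Spearman rank correlation
#'
#' Average-rank (midrank) Spearman coefficient with the t-approximation
#' p-value. Constant input leaves the coefficient undefined; that case is
#' flagged rather than fabricated.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `constant_input`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          constant_input = TRUE),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (is.finite(tstat)) {
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  } else 0
  structure(list(rho = rho, p_value = p, n = n, constant_input = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$constant_input)) {
    cat("<correlation_result> undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("<correlation_result> Spearman rho = %.3f, p = %.3g, n = %d\n",
                x$rho, x$p_value, x$n))
  }
  invisible(x)
}

group_test_result <- function(statistic, p_value, df, groups, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = df, groups = groups, method = method,
                 significance_band = significance_band(p_value)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s (%s): statistic = %.4f, p = %.4g [%s]\n",
              x$method, paste(x$groups, collapse = ", "), x$statistic,
              x$p_value, x$significance_band))
  invisible(x)
}

check_groups <- function(groups, min_groups = 2L) {
  stopifnot(is.list(groups), length(groups) >= min_groups)
  if (any(lengths(groups) == 0L)) stop("empty group supplied")
  invisible(groups)
}

names_or_index <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) as.character(seq_along(groups)) else nm
}

# ---- report tables ----------------------------------------------------------

#' Per-plasmid gene-content table
#'
#' @param records A [plasmid_set()].
#' @param assignments Assignment table from [annotate_dataset()].
#' @return Data frame: `plasmid_id`, `genus`, `n_hrg`, `n_arg`, `has_hrg`,
#'   `has_arg`, `length_bp`.
#' @export
plasmid_gene_content <- function(records, assignments) {
  n_of <- function(category) {
    tab <- table(assignments$plasmid_id[assignments$category == category])
    v <- as.integer(tab[names(records)])
    ifelse(is.na(v), 0L, v)
  }
  data.frame(plasmid_id = names(records),
             genus = vapply(records, `[[`, character(1), "host_genus"),
             n_hrg = n_of("HRG"), n_arg = n_of("ARG"),
             length_bp = vapply(records, `[[`, integer(1), "length_bp"),
             stringsAsFactors = FALSE, row.names = NULL) |>
    within({
      has_hrg <- n_hrg > 0L
      has_arg <- n_arg > 0L
    })
}

#' Taxonomic distribution of HRG- and dual-bearing plasmids
#'
#' Per genus: plasmid count and percent of all plasmids; count and percent
#' of plasmids harboring at least one HRG (denominator: all HRG-bearing
#' plasmids); count and percent harboring both HRGs and ARGs (denominator:
#' all dual-bearing plasmids). Genera with no HRG-bearing plasmid are
#' suppressed by default. Percents are half-up to two decimals.
#'
#' @param content Either a per-plasmid table from [plasmid_gene_content()]
#'   (columns `genus`, `has_hrg`, `has_arg`) or a [plasmid_set()] together
#'   with `assignments`.
#' @param assignments Assignment table, when `content` is a plasmid set.
#' @param suppress_zero_hrg Drop genera with no HRG-bearing plasmid.
#' @return Data frame: `genus`, `n_plasmids`, `pct_plasmids`, `n_hrg`,
#'   `pct_hrg`, `n_dual`, `pct_dual`, sorted by `n_plasmids` descending.
#' @export
taxonomic_summary <- function(content, assignments = NULL,
                              suppress_zero_hrg = TRUE) {
  if (inherits(content, "plasmid_set")) {
    stopifnot(!is.null(assignments))
    content <- plasmid_gene_content(content, assignments)
  }
  stopifnot(all(c("genus", "has_hrg", "has_arg") %in% names(content)))
  dual <- content$has_hrg & content$has_arg
  agg <- function(v) {
    tab <- tapply(v, content$genus, sum)
    as.integer(tab)
  }
  genera <- sort(unique(content$genus))
  out <- data.frame(genus = genera,
                    n_plasmids = agg(rep(1L, nrow(content))),
                    n_hrg = agg(content$has_hrg),
                    n_dual = agg(dual),
                    stringsAsFactors = FALSE)
  pct <- function(num, den) {
    if (den > 0) round_half_up(100 * num / den) else NA_real_
  }
  out$pct_plasmids <- vapply(out$n_plasmids, pct, numeric(1), nrow(content))
  out$pct_hrg <- vapply(out$n_hrg, pct, numeric(1), sum(content$has_hrg))
  out$pct_dual <- vapply(out$n_dual, pct, numeric(1), sum(dual))
  if (suppress_zero_hrg) out <- out[out$n_hrg > 0L, , drop = FALSE]
  out <- out[order(-out$n_plasmids, out$genus),
             c("genus", "n_plasmids", "pct_plasmids", "n_hrg", "pct_hrg",
               "n_dual", "pct_dual")]
  rownames(out) <- NULL
  out
}

#' Headline resistome ratios
#'
#' Formats the dataset-level percentages (two decimals, half-up): the share
#' of plasmids carrying HRGs or ARGs, the dual-bearing share against each
#' denominator, and the share of the HRG/ARG gene totals concentrated on
#' dual-bearing plasmids. Zero denominators yield `NA`.
#'
#' @param counts Named list/vector with `n_plasmids`, `n_hrg_plasmids`,
#'   `n_arg_plasmids`, `n_dual_plasmids`, `n_hrgs`, `n_args`,
#'   `n_hrgs_dual`, `n_args_dual`.
#' @return Data frame with columns `quantity`, `value`.
#' @export
headline_ratios <- function(counts) {
  counts <- as.list(counts)
  need <- c("n_plasmids", "n_hrg_plasmids", "n_arg_plasmids",
            "n_dual_plasmids", "n_hrgs", "n_args", "n_hrgs_dual",
            "n_args_dual")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count(s): ", paste(miss, collapse = ", "))
  pct <- function(num, den) {
    if (is.na(den) || den == 0) NA_real_ else round_half_up(100 * num / den)
  }
  with(counts, data.frame(
    quantity = c("hrg_plasmid_pct", "arg_plasmid_pct", "dual_of_all_pct",
                 "dual_of_hrg_pct", "dual_of_arg_pct", "hrg_in_dual_pct",
                 "arg_in_dual_pct"),
    value = c(pct(n_hrg_plasmids, n_plasmids),
              pct(n_arg_plasmids, n_plasmids),
              pct(n_dual_plasmids, n_plasmids),
              pct(n_dual_plasmids, n_hrg_plasmids),
              pct(n_dual_plasmids, n_arg_plasmids),
              pct(n_hrgs_dual, n_hrgs),
              pct(n_args_dual, n_args)),
    stringsAsFactors = FALSE))
}

#' Resistome counts of a dataset
#'
#' Computes the count vector consumed by [headline_ratios()] from a plasmid
#' set and its assignment table.
#'
#' @param records A [plasmid_set()].
#' @param assignments Assignment table.
#' @return Named list of counts.
#' @export
resistome_counts <- function(records, assignments) {
  content <- plasmid_gene_content(records, assignments)
  dual <- content$has_hrg & content$has_arg
  list(n_plasmids = nrow(content),
       n_hrg_plasmids = sum(content$has_hrg),
       n_arg_plasmids = sum(content$has_arg),
       n_dual_plasmids = sum(dual),
       n_hrgs = sum(content$n_hrg),
       n_args = sum(content$n_arg),
       n_hrgs_dual = sum(content$n_hrg[dual]),
       n_args_dual = sum(content$n_arg[dual]))
}
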