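# ---- physical genetic distance ----------------------------------------------

# gap in bp strictly between two intervals; overlap or abutment -> 0
linear_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

#' Physical genetic distance between two gene features
#'
#' The distance is the number of base pairs strictly between the two gene
#' extents: overlapping or abutting genes are at distance 0. On a circular
#' plasmid with `circular_aware = TRUE` the shorter way around the origin is
#' taken.
#'
#' @param a,b Gene features: lists or one-row data frames with `start` and
#'   `end` (1-based inclusive bp).
#' @param plasmid The [plasmid_record()] carrying both features (required
#'   for the circular path).
#' @param circular_aware Honor circular topology (default `FALSE`).
#' @return Distance in bp (integer, >= 0).
#' @export
feature_distance <- function(a, b, plasmid = NULL, circular_aware = FALSE) {
  d <- linear_gap(a$start, a$end, b$start, b$end)
  if (circular_aware && !is.null(plasmid) && plasmid$topology == "circular") {
    lo_s <- pmin(a$start, b$start)
    hi_e <- pmax(a$end, b$end)
    wrap <- pmax(0L, plasmid$length_bp - (hi_e - lo_s + 1L))
    d <- pmin(d, wrap)
  }
  d
}

# all ARG-HRG pair distances on one plasmid; rows = ARG gene ids, cols = HRGs
pair_distance_matrix <- function(plasmid, arg_ids, hrg_ids,
                                 circular_aware = FALSE) {
  g <- plasmid$genes
  ai <- match(arg_ids, g$gene_id)
  hi <- match(hrg_ids, g$gene_id)
  if (anyNA(ai) || anyNA(hi)) {
    stop("assignment references gene absent from plasmid ",
         plasmid$plasmid_id)
  }
  m <- matrix(0L, length(ai), length(hi),
              dimnames = list(arg_ids, hrg_ids))
  for (j in seq_along(hi)) {
    m[, j] <- feature_distance(
      list(start = g$start[ai], end = g$end[ai]),
      list(start = g$start[hi[j]], end = g$end[hi[j]]),
      plasmid, circular_aware)
  }
  m
}

# split assignments by category for one plasmid
plasmid_categories <- function(assignments, pid) {
  sub <- assignments[assignments$plasmid_id == pid, , drop = FALSE]
  list(arg = sub[sub$category == "ARG", , drop = FALSE],
       hrg = sub[sub$category == "HRG", , drop = FALSE])
}

dual_plasmid_ids <- function(assignments) {
  has_arg <- unique(assignments$plasmid_id[assignments$category == "ARG"])
  has_hrg <- unique(assignments$plasmid_id[assignments$category == "HRG"])
  sort(intersect(has_arg, has_hrg))
}

# ---- A-H-incidence_ave ------------------------------------------------------

#' Average ARG incidence within a distance of HRGs
#'
#' For every threshold d on the grid (0 to `max_bp` in steps of `step_bp`,
#' endpoints inclusive), the curve value is the total number of ARGs lying
#' within d bp of any HRG on their plasmid, divided by the number of
#' contributing plasmids. Only plasmids carrying at least one HRG and one
#' ARG contribute, and each ARG is counted at most once per threshold (the
#' statistic counts ARGs, not ARG-HRG pairs).
#'
#' @param records A [plasmid_set()].
#' @param assignments Assignment table from [annotate_dataset()].
#' @param step_bp Grid step (default 200).
#' @param max_bp Grid maximum (default 100000, i.e. 501 grid points).
#' @param circular_aware Passed to [feature_distance()].
#' @param group_label Label stored on the curve.
#' @return Data frame of class `incidence_curve` with columns
#'   `threshold_bp`, `value`, and attributes `n_plasmids`, `group_label`.
#' @export
ah_incidence_curve <- function(records, assignments, step_bp = 200L,
                               max_bp = 100000L, circular_aware = FALSE,
                               group_label = "all") {
  pids <- dual_plasmid_ids(assignments)
  if (!length(pids)) {
    stop("no plasmid carries both an HRG and an ARG")
  }
  mins <- unlist(lapply(pids, function(pid) {
    cats <- plasmid_categories(assignments, pid)
    m <- pair_distance_matrix(records[[pid]], cats$arg$gene_id,
                              cats$hrg$gene_id, circular_aware)
    apply(m, 1L, min)
  }), use.names = FALSE)
  grid <- seq.int(0L, max_bp, by = step_bp)
  mins <- sort(mins)
  counts <- findInterval(grid, mins)  # number of ARG minima <= threshold
  out <- data.frame(threshold_bp = grid, value = counts / length(pids))
  attr(out, "n_plasmids") <- length(pids)
  attr(out, "group_label") <- group_label
  class(out) <- c("incidence_curve", "data.frame")
  out
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat(sprintf("<incidence_curve> '%s': %d thresholds, %d plasmids, value(max) = %.3f\n",
              attr(x, "group_label"), nrow(x), attr(x, "n_plasmids"),
              x$value[nrow(x)]))
  invisible(x)
}

# ---- A-H-distance_min -------------------------------------------------------

#' Per-plasmid minimum ARG-HRG distance, by ARG class
#'
#' For each ARG class on the plasmid, the minimum physical genetic distance
#' between any ARG of that class and any HRG. The HRGs are first
#' de-redundanted so each HRG class is represented once, by its
#' distance-minimizing instance; this selection cannot change a minimum and
#' is property-tested as such. The plasmid-level minimum is the smallest
#' per-class value.
#'
#' @param plasmid A [plasmid_record()] carrying both categories.
#' @param assignments Assignment table (rows of other plasmids are ignored).
#' @param circular_aware Passed to [feature_distance()].
#' @return List of class `min_distance_record`: `plasmid_id`,
#'   `per_arg_class_min` (named numeric, bp), `plasmid_min` (bp).
#' @export
ah_distance_min <- function(plasmid, assignments, circular_aware = FALSE) {
  cats <- plasmid_categories(assignments, plasmid$plasmid_id)
  if (!nrow(cats$arg) || !nrow(cats$hrg)) {
    stop("plasmid ", plasmid$plasmid_id,
         " lacks an HRG or an ARG assignment")
  }
  m <- pair_distance_matrix(plasmid, cats$arg$gene_id, cats$hrg$gene_id,
                            circular_aware)
  # de-redundancy: per ARG class, each HRG class contributes one instance,
  # the one minimizing the distance to that ARG class -- a selection that
  # cannot change the minimum (property-tested against the plain pair min)
  hrg_class <- cats$hrg$class_label
  arg_class <- cats$arg$class_label
  per_class <- vapply(split(seq_along(arg_class), arg_class), function(ai) {
    per_hrg_class <- vapply(split(seq_along(hrg_class), hrg_class),
                            function(hi) min(m[ai, hi, drop = FALSE]),
                            numeric(1))
    min(per_hrg_class)
  }, numeric(1))
  structure(list(plasmid_id = plasmid$plasmid_id,
                 per_arg_class_min = per_class,
                 plasmid_min = min(per_class)),
            class = "min_distance_record")
}

#' @export
print.min_distance_record <- function(x, ...) {
  cat(sprintf("<min_distance_record> %s: plasmid_min = %d bp over %d ARG class(es)\n",
              x$plasmid_id, as.integer(x$plasmid_min),
              length(x$per_arg_class_min)))
  invisible(x)
}

#' Minimum-distance table across a dataset
#'
#' Runs [ah_distance_min()] on every plasmid carrying both categories.
#'
#' @inheritParams ah_incidence_curve
#' @return Data frame: `plasmid_id`, `arg_class`, `min_bp`,
#'   `plasmid_min_bp`.
#' @export
min_distance_table <- function(records, assignments, circular_aware = FALSE) {
  pids <- dual_plasmid_ids(assignments)
  rows <- lapply(pids, function(pid) {
    r <- ah_distance_min(records[[pid]], assignments, circular_aware)
    data.frame(plasmid_id = pid, arg_class = names(r$per_arg_class_min),
               min_bp = unname(r$per_arg_class_min),
               plasmid_min_bp = r$plasmid_min, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    plasmid_id = character(), arg_class = character(), min_bp = numeric(),
    plasmid_min_bp = numeric(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

# ---- nearest ARG class preference -------------------------------------------

#' Preference of HRGs for specific ARG classes
#'
#' Each plasmid carrying both categories contributes one count: the ARG
#' class achieving the plasmid-level minimum distance, after removing the
#' excluded classes (multidrug resistance genes by default, whose ubiquity
#' would swamp the tally). Distance ties between classes go to the
#' lexicographically smallest class name and are reported via `message()`;
#' plasmids whose only ARGs are excluded are skipped likewise.
#'
#' @inheritParams ah_incidence_curve
#' @param excluded_classes ARG classes removed before the argmin (default
#'   `"multidrug"`).
#' @return Data frame of class `preference_tally`: `arg_class`,
#'   `plasmid_count`, `percent` (two decimals), sorted by count descending;
#'   attribute `n_plasmids` is the number of contributing plasmids.
#' @export
nearest_class_preference <- function(records, assignments,
                                     excluded_classes = "multidrug",
                                     circular_aware = FALSE) {
  pids <- dual_plasmid_ids(assignments)
  winners <- character()
  for (pid in pids) {
    r <- ah_distance_min(records[[pid]], assignments, circular_aware)
    pc <- r$per_arg_class_min
    pc <- pc[!names(pc) %in% excluded_classes]
    if (!length(pc)) {
      message("plasmid ", pid, ": only excluded ARG classes; skipped")
      next
    }
    best <- names(pc)[pc == min(pc)]
    if (length(best) > 1L) {
      message("plasmid ", pid, ": distance tie between ",
              paste(sort(best), collapse = ", "),
              "; keeping ", sort(best)[1])
    }
    winners <- c(winners, sort(best)[1])
  }
  if (length(winners)) {
    tt <- table(winners)
    out <- data.frame(arg_class = names(tt), plasmid_count = as.integer(tt),
                      stringsAsFactors = FALSE)
    out$percent <- round_half_up(100 * out$plasmid_count /
                                   sum(out$plasmid_count))
    out <- out[order(-out$plasmid_count, out$arg_class), , drop = FALSE]
  } else {
    out <- data.frame(arg_class = character(), plasmid_count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_plasmids") <- length(winners)
  class(out) <- c("preference_tally", "data.frame")
  out
}

# ---- grouped curves ---------------------------------------------------------

#' Incidence curves per metadata group
#'
#' Splits the dual-bearing plasmids by a per-plasmid label (host-source
#' category or pathogenicity) and computes one [ah_incidence_curve()] per
#' group. Plasmids labelled `NA` are excluded; empty groups are omitted
#' with a warning.
#'
#' @inheritParams ah_incidence_curve
#' @param labels Named character vector mapping plasmid ids to group labels
#'   (`NA` to exclude).
#' @return Named list of `incidence_curve` objects.
#' @export
group_curves <- function(records, assignments, labels, step_bp = 200L,
                         max_bp = 100000L, circular_aware = FALSE) {
  groups <- sort(unique(labels[!is.na(labels)]))
  out <- list()
  for (gl in groups) {
    pids <- names(labels)[!is.na(labels) & labels == gl]
    sub <- assignments[assignments$plasmid_id %in% pids, , drop = FALSE]
    if (!length(dual_plasmid_ids(sub))) {
      warning("group '", gl, "': no dual-bearing plasmid; omitted")
      next
    }
    out[[gl]] <- ah_incidence_curve(records, sub, step_bp, max_bp,
                                    circular_aware, group_label = gl)
  }
  out
}

#' Plot incidence curves
#'
#' @param curves List of `incidence_curve` objects (or a single one).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_incidence_curves <- function(curves, ...) {
  if (inherits(curves, "incidence_curve")) curves <- list(curves)
  x <- curves[[1]]$threshold_bp / 1000
  y <- vapply(curves, `[[`, numeric(length(x)), "value")
  graphics::matplot(x, y, type = "l", lty = 1, lwd = 2,
                    xlab = "distance from HRG (kb)",
                    ylab = "average ARG count within distance", ...)
  labs <- vapply(curves, function(cv) attr(cv, "group_label"), character(1))
  graphics::legend("topleft", legend = labs, lty = 1, lwd = 2,
                   col = seq_along(curves), bty = "n")
  invisible(curves)
}
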