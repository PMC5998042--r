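# Per-image aggregation, control-basal normalization and the plate-level
# statistical toolkit.  The image (field), not the cell, is the unit of
# statistical analysis: per-cell values are averaged per image first.

# Readouts carried from the cell panel into image summaries and subject
# to control-basal normalization.
READOUT_COLUMNS <- c("mean_intensity_cell", "mean_intensity_mito",
                     "n_mito", "mean_mito_area_px",
                     "total_mito_area_fraction", "aspect_ratio",
                     "major_axis_len_px")

#' Aggregate per-cell records to per-image summaries
#'
#' Unweighted means over the live cells of each field, per readout
#' (missing per-cell morphology values are dropped from the mean).
#' Fields with fewer live cells than \code{minCells} are excluded, with
#' a message stating how many were dropped.
#'
#' @param records per-cell data.frame (\code{\link{measureCells}}).
#' @param minCells minimum live cells for a field to enter statistics.
#' @return data.frame with one row per retained field: provenance,
#'   annotation, \code{n_cells_live}, \code{pct_dead} and the readout
#'   panel means.
#' @export
aggregatePerImage <- function(records, minCells = 5L) {
  stopifnot(is.data.frame(records))
  dt <- data.table::as.data.table(records)
  summ <- dt[, {
    liveRows <- .SD[live == TRUE]
    means <- lapply(READOUT_COLUMNS, function(cl)
      if (nrow(liveRows)) mean(liveRows[[cl]], na.rm = TRUE) else NA_real_)
    names(means) <- READOUT_COLUMNS
    c(list(cell_line = cell_line[1], treatment = treatment[1],
           n_cells_live = nrow(liveRows),
           pct_dead = if (.N > 0) 100 * sum(!live) / .N else NA_real_),
      means)
  }, by = c("plate_id", "well", "field")]
  summ <- as.data.frame(summ)
  keep <- summ$n_cells_live >= minCells
  if (any(!keep))
    message(sprintf("aggregatePerImage: dropped %d field(s) with < %d live cells",
                    sum(!keep), minCells))
  summ[keep, , drop = FALSE]
}

#' Normalize image summaries to the control-basal group
#'
#' Per experiment (plate) and per readout, every value is divided by the
#' central value (median by default) of the control-basal group of that
#' experiment.  Normalization is never pooled across experiments.  The
#' control group's own normalized central value is 1 by construction,
#' and the operation is idempotent.
#'
#' @param summaries data.frame from \code{\link{aggregatePerImage}}.
#' @param layout optional \linkS4class{PlateLayout}; required unless
#'   \code{summaries} already has a logical \code{control_basal} column.
#' @param center "median" (default, matching median-based reporting) or
#'   "mean".
#' @param readouts readout columns to normalize.
#' @return \code{summaries} with the readout columns normalized and a
#'   \code{control_basal} column attached.
#' @export
normalizeToControl <- function(summaries, layout = NULL,
                               center = c("median", "mean"),
                               readouts = READOUT_COLUMNS) {
  center <- match.arg(center)
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  if (!"control_basal" %in% names(summaries)) {
    if (is.null(layout))
      stop("a PlateLayout (or a control_basal column) is required",
           call. = FALSE)
    w <- layoutWells(layout)
    summaries$control_basal <-
      summaries$well %in% w$well[w$control_basal]
  }
  if (!any(summaries$control_basal))
    stop("validation error: no control-basal well in the layout/summaries",
         call. = FALSE)
  centerFun <- if (center == "median") function(x) median(x, na.rm = TRUE)
    else function(x) mean(x, na.rm = TRUE)
  readouts <- intersect(readouts, names(summaries))
  out <- split(summaries, summaries$plate_id)
  out <- lapply(out, function(s) {
    ctrl <- s[s$control_basal, , drop = FALSE]
    if (!nrow(ctrl))
      stop(sprintf("validation error: plate '%s' has no control-basal images",
                   s$plate_id[1]), call. = FALSE)
    for (cl in readouts) {
      cv <- centerFun(ctrl[[cl]])
      if (is.na(cv)) next
      if (cv == 0)
        stop(sprintf("control-basal center is 0 for readout '%s'", cl),
             call. = FALSE)
      s[[cl]] <- s[[cl]] / cv
    }
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Rank-based H with tie correction and the chi-squared approximation
#' (k - 1 df), as \code{stats::kruskal.test}; identical values across
#' all groups give H = 0, p = 1.  Pairwise post-hoc comparisons use
#' Dunn's z statistics on the joint ranks with Holm adjustment.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length (>= 2 levels).
#' @return list with \code{statistic} (H), \code{p.value}, \code{df}
#'   and \code{posthoc}, a data.frame of pairwise Dunn comparisons
#'   (z, p, p_adj).
#' @examples
#' kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$statistic
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            all(table(groups) >= 1), length(values) >= 3)
  if (length(unique(values)) == 1L) {
    lev <- levels(groups)
    cmb <- utils::combn(lev, 2)
    posthoc <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                          z = 0, p = 1, p_adj = 1)
    return(list(statistic = 0, p.value = 1,
                df = nlevels(groups) - 1L, posthoc = posthoc))
  }
  kt <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- as.numeric(table(groups))
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tieCorr
  lev <- levels(groups)
  cmb <- utils::combn(seq_along(lev), 2)
  z <- (rbar[cmb[1, ]] - rbar[cmb[2, ]]) /
    sqrt(s2 * (1 / ni[cmb[1, ]] + 1 / ni[cmb[2, ]]))
  p <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(group1 = lev[cmb[1, ]], group2 = lev[cmb[2, ]],
                        z = as.numeric(z), p = as.numeric(p),
                        p_adj = stats::p.adjust(as.numeric(p),
                                                method = "holm"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter), posthoc = posthoc)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided D = sup |ECDF_a - ECDF_b| with the asymptotic p-value.
#'
#' @param a,b nonempty numeric vectors.
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
ksTwoSample <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1) divided by the mean.  At the
#' "well" level the per-cell (or per-image) values are first averaged
#' per well; at the "cell" level the values are used as given.
#'
#' @param values numeric vector.
#' @param level "cell" or "well".
#' @param wells well identifier per value (required for level "well").
#' @return the CoV (dimensionless).
#' @export
coefficientOfVariation <- function(values, level = c("cell", "well"),
                                   wells = NULL) {
  level <- match.arg(level)
  if (level == "well") {
    stopifnot(!is.null(wells), length(wells) == length(values))
    values <- as.numeric(tapply(values, wells, mean, na.rm = TRUE))
  }
  values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined: mean is 0",
                   call. = FALSE)
  sd(values) / m
}

#' Relative and cumulative frequency distribution
#'
#' Values are binned into the half-open intervals defined by
#' \code{binEdges} (the last bin is closed).  Relative frequencies are
#' over the in-range values and sum to 1; the cumulative column is their
#' nondecreasing running sum ending at 1.
#'
#' @param values nonempty numeric vector.
#' @param binEdges strictly increasing numeric vector of edges.
#' @return data.frame with columns \code{bin_start}, \code{bin_end},
#'   \code{count}, \code{relative}, \code{cumulative}.
#' @export
frequencyDistribution <- function(values, binEdges) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("frequencyDistribution: no values", call. = FALSE)
  if (length(binEdges) < 2 || any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing with >= 2 entries",
         call. = FALSE)
  nb <- length(binEdges) - 1L
  bin <- findInterval(values, binEdges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nb] <- NA_integer_
  counts <- tabulate(bin[!is.na(bin)], nbins = nb)
  tot <- sum(counts)
  if (tot == 0) stop("no values fall inside the bins", call. = FALSE)
  rel <- counts / tot
  data.frame(bin_start = binEdges[-length(binEdges)],
             bin_end = binEdges[-1], count = counts,
             relative = rel, cumulative = cumsum(rel))
}

#' One-way ANOVA (thin wrapper)
#'
#' Standard one-way analysis of variance via \code{stats::aov}; provided
#' as a plain comparison utility (used e.g. for viability comparisons),
#' not part of the bespoke pipeline.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return list with \code{statistic} (F) and \code{p.value}.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
}

#' Two-sample t test (thin wrapper)
#'
#' @param a,b numeric vectors.
#' @param paired logical.
#' @return list with \code{statistic} (t) and \code{p.value}.
#' @export
tTestGroups <- function(a, b, paired = FALSE) {
  tt <- stats::t.test(a, b, paired = paired)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Statistical report over normalized summaries
#'
#' Runs, per readout: Kruskal-Wallis across cell-line/treatment groups
#' (with Dunn post hoc) on the per-image values.  Returns a tidy table.
#'
#' @param normalized data.frame from \code{\link{normalizeToControl}}.
#' @param groupBy column(s) defining the comparison groups.
#' @param readouts readout columns to test.
#' @return data.frame with columns \code{readout}, \code{test},
#'   \code{group1}, \code{group2}, \code{statistic}, \code{p},
#'   \code{p_adj}.
#' @export
statsReport <- function(normalized, groupBy = c("cell_line", "treatment"),
                        readouts = READOUT_COLUMNS) {
  readouts <- intersect(readouts, names(normalized))
  grp <- interaction(normalized[groupBy], drop = TRUE, sep = "/")
  rows <- list()
  for (cl in readouts) {
    v <- normalized[[cl]]
    keep <- !is.na(v)
    if (length(unique(grp[keep])) < 2 || sum(keep) < 3) next
    kw <- kruskalWallis(v[keep], droplevels(grp[keep]))
    rows[[length(rows) + 1L]] <- data.frame(
      readout = cl, test = "kruskal-wallis", group1 = "all", group2 = "all",
      statistic = kw$statistic, p = kw$p.value, p_adj = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      readout = cl, test = "dunn", group1 = kw$posthoc$group1,
      group2 = kw$posthoc$group2, statistic = kw$posthoc$z,
      p = kw$posthoc$p, p_adj = kw$posthoc$p_adj)
  }
  if (!length(rows))
    return(data.frame(readout = character(0), test = character(0),
                      group1 = character(0), group2 = character(0),
                      statistic = numeric(0), p = numeric(0),
                      p_adj = numeric(0)))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
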