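#' Median and interquartile range of establishment counts by group
#'
#' For each count column, per group: the median, the 25th and 75th percentiles
#' (SPSS convention, quantile type 6), and the percentage of rows with at
#' least one establishment. Empty groups are dropped with a warning.
#'
#' @param counts data frame of non-negative counts (one row per school or
#'   neighborhood, one column per category).
#' @param group factor of the same length as `nrow(counts)`; use a constant
#'   factor for an overall summary.
#' @return data frame: `group`, `category`, `median`, `p25`, `p75`,
#'   `pct_at_least_one`.
#' @export
summarize_counts <- function(counts, group) {
  counts <- as.data.frame(counts)
  group <- as.factor(group)
  stopifnot(nrow(counts) == length(group))
  if (any(as.matrix(counts) < 0)) stop("counts must be non-negative")
  empty <- setdiff(levels(group), unique(as.character(group)))
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  res <- expand.grid(group = levels(group), category = names(counts),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  stats_for <- function(g, cat) {
    v <- counts[[cat]][group == g]
    q <- qs(v)
    c(median = q[2], p25 = q[1], p75 = q[3],
      pct_at_least_one = 100 * mean(v >= 1))
  }
  vals <- t(mapply(stats_for, res$group, res$category))
  cbind(res, as.data.frame(vals))
}

#' Contingency table of a binary flag by stratum
#'
#' @param levels character vector of stratum labels (rows).
#' @param flagged integer vector: schools with the flag, per stratum.
#' @param totals integer vector: all schools per stratum.
#' @return object of class `contingency_table` with fields `levels`,
#'   `flagged`, `totals`, `prevalence` (percent, 1 decimal) and `cells`
#'   (matrix: flagged / not flagged).
#' @export
contingency_table <- function(levels, flagged, totals) {
  stopifnot(length(levels) == length(flagged),
            length(levels) == length(totals))
  flagged <- as.integer(flagged)
  totals <- as.integer(totals)
  if (any(flagged < 0) || any(totals < 0)) stop("negative cell counts")
  if (any(flagged > totals)) stop("flagged counts exceed row totals")
  cells <- cbind(flagged = flagged, not_flagged = totals - flagged)
  rownames(cells) <- as.character(levels)
  structure(list(levels = as.character(levels), flagged = flagged,
                 totals = totals,
                 prevalence = round(100 * flagged / totals, 1),
                 cells = cells),
            class = "contingency_table")
}

#' Cross-tabulate a school-level flag by stratum
#'
#' Counts schools per stratum level and per flag state and reports the
#' prevalence (percentage flagged) per stratum to one decimal.
#'
#' @param stratum factor (or coercible) with one entry per school; `NA` is an
#'   error (ids listed).
#' @param flag logical vector, one entry per school.
#' @param ids optional school identifiers used in error messages.
#' @return a [contingency_table].
#' @export
crosstab <- function(stratum, flag, ids = NULL) {
  stopifnot(length(stratum) == length(flag))
  if (anyNA(stratum)) {
    bad <- which(is.na(stratum))
    lab <- if (!is.null(ids)) ids[bad] else bad
    stop("missing stratum for school(s): ",
         paste(utils::head(lab, 10), collapse = ", "))
  }
  if (anyNA(flag)) stop("missing flag values")
  stratum <- as.factor(stratum)
  flag <- as.logical(flag)
  totals <- as.integer(table(stratum))
  flagged <- as.integer(tapply(flag, stratum, sum))
  flagged[is.na(flagged)] <- 0L
  contingency_table(levels(stratum), flagged, totals)
}

#' @export
print.contingency_table <- function(x, ...) {
  df <- data.frame(n = x$totals, flagged = x$flagged,
                   prevalence = sprintf("%.1f%%", x$prevalence),
                   row.names = x$levels)
  print(df, ...)
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson test (no Yates continuity correction): statistic
#' \eqn{\sum (O-E)^2/E}, df = (rows-1)(cols-1), upper-tail chi-square p-value.
#' Zero expected counts are an error.
#'
#' @param table a [contingency_table] or a numeric matrix of cell counts.
#' @return list of class `chi_square_result`: `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table) {
  m <- if (inherits(table, "contingency_table")) table$cells else as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2x2 table")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("degenerate table: zero expected cell count")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.3f, df = %d, p = %s\n",
              x$statistic, as.integer(x$df), format_p_value(x$p_value)))
  invisible(x)
}

#' Format a p-value for tabular output
#'
#' Three decimals; values below 0.0005 render as `"< 0.001"`.
#'
#' @param p numeric p-value(s) in (0, 1].
#' @return character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.0005, "< 0.001", sprintf("%.3f", p))
}
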