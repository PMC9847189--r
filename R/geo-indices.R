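#' Aggregate census tracts to neighborhoods
#'
#' Neighborhoods are aggregates of census tracts. Population and total income
#' are summed; the proportion of household heads earning 0-3 minimum wages is
#' pooled (sum of numerators over sum of denominators); the three deprivation
#' indicators (share of households below half a minimum wage, illiteracy rate
#' among residents aged 7+, share of residents with inadequate sanitation) are
#' computed per tract and then averaged, unweighted, over the neighborhood's
#' tracts.
#'
#' @param tracts data frame with columns `tract_id`, `neighborhood_id`,
#'   `population`, `total_income`, `household_heads_total`,
#'   `household_heads_0_3_mw`, `households_below_half_mw`, `persons_7plus`,
#'   `illiterate_7plus`, `persons_inadequate_sanitation`.
#'
#' @return data frame, one row per neighborhood: `neighborhood_id`,
#'   `population`, `total_income`, `per_capita_income`, `prop_heads_0_3_mw`,
#'   and the averaged deprivation inputs `prop_below_half_mw`,
#'   `prop_illiterate`, `prop_inadequate_sanitation`.
#' @export
aggregate_tracts <- function(tracts) {
  need <- c("tract_id", "neighborhood_id", "population", "total_income",
            "household_heads_total", "household_heads_0_3_mw",
            "households_below_half_mw", "persons_7plus", "illiterate_7plus",
            "persons_inadequate_sanitation")
  miss <- setdiff(need, names(tracts))
  if (length(miss)) stop("tracts missing column(s): ", paste(miss, collapse = ", "))
  cnt <- c("population", "household_heads_total", "household_heads_0_3_mw",
           "households_below_half_mw", "persons_7plus", "illiterate_7plus",
           "persons_inadequate_sanitation")
  for (col in cnt) {
    if (any(tracts[[col]] < 0)) stop("negative counts in column ", col)
  }
  if (any(tracts$household_heads_0_3_mw > tracts$household_heads_total) ||
      any(tracts$households_below_half_mw > tracts$household_heads_total) ||
      any(tracts$illiterate_7plus > tracts$persons_7plus) ||
      any(tracts$persons_inadequate_sanitation > tracts$population)) {
    stop("part counts exceed their totals")
  }

  prop <- function(num, den) ifelse(den > 0, num / den, 0)
  tr <- tracts
  tr$p_half <- prop(tr$households_below_half_mw, tr$household_heads_total)
  tr$p_illit <- prop(tr$illiterate_7plus, tr$persons_7plus)
  tr$p_sanit <- prop(tr$persons_inadequate_sanitation, tr$population)

  g <- factor(tr$neighborhood_id, levels = unique(tr$neighborhood_id))
  agg_sum <- function(v) as.numeric(tapply(v, g, sum))
  agg_mean <- function(v) as.numeric(tapply(v, g, mean))

  out <- data.frame(
    neighborhood_id = levels(g),
    population = agg_sum(tr$population),
    total_income = agg_sum(tr$total_income),
    stringsAsFactors = FALSE
  )
  if (any(out$population <= 0)) {
    stop("neighborhood(s) with zero population: ",
         paste(out$neighborhood_id[out$population <= 0], collapse = ", "))
  }
  out$per_capita_income <- out$total_income / out$population
  heads <- agg_sum(tr$household_heads_total)
  if (any(heads <= 0)) {
    stop("neighborhood(s) with no household heads: ",
         paste(out$neighborhood_id[heads <= 0], collapse = ", "))
  }
  out$prop_heads_0_3_mw <- agg_sum(tr$household_heads_0_3_mw) / heads
  out$prop_below_half_mw <- agg_mean(tr$p_half)
  out$prop_illiterate <- agg_mean(tr$p_illit)
  out$prop_inadequate_sanitation <- agg_mean(tr$p_sanit)
  out
}

#' Per-capita income terciles
#'
#' Splits neighborhoods into three income classes at the empirical 33 1/3 and
#' 66 2/3 percentiles of the per-capita-income distribution (linear
#' interpolation between order statistics). A value tied with a boundary is
#' assigned to the lower class.
#'
#' @param income numeric vector of neighborhood per-capita incomes (positive).
#' @return list with `category` (factor: `Lowest`, `Middle`, `Highest`) and
#'   `boundaries` (the two percentile cut points).
#' @export
income_terciles <- function(income) {
  if (length(income) < 3) stop("need at least 3 neighborhoods for terciles")
  if (any(!is.finite(income)) || any(income <= 0)) {
    stop("per-capita incomes must be finite and positive")
  }
  if (diff(range(income)) == 0) stop("degenerate distribution: all incomes identical")
  b <- stats::quantile(income, probs = c(1, 2) / 3, type = 7, names = FALSE)
  cat <- ifelse(income <= b[1], "Lowest", ifelse(income <= b[2], "Middle", "Highest"))
  list(category = factor(cat, levels = c("Lowest", "Middle", "Highest")),
       boundaries = b)
}

#' Getis-Ord Gi* local spatial statistic
#'
#' Computes the self-inclusive local Gi* Z-score for each unit:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}{S \sqrt{(n S_{1i} - W_i^2)/(n-1)}}}
#' where the weights include \eqn{w_{ii} = 1}, \eqn{W_i = \sum_j w_{ij}},
#' \eqn{S_{1i} = \sum_j w_{ij}^2}, and \eqn{\bar{X}} and \eqn{S} are the global
#' mean and population standard deviation of `x`. With binary weights the
#' result is the standard-normal hotspot Z-score: large positive values mark
#' local concentrations of high `x`.
#'
#' @param x numeric vector, one value per unit of `w` (same order as `w$ids`).
#' @param w a [spatial_weights] object (binary scheme, self-inclusive).
#' @return named numeric vector of Z-scores.
#' @export
gi_star <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  if (length(x) != n) {
    stop("length of x (", length(x), ") does not match number of units (", n, ")")
  }
  if (any(!is.finite(x))) stop("x must be finite")
  if (w$scheme != "binary") {
    stop("gi_star requires binary weights (the Z-score form assumes 0/1 weights)")
  }
  if (n < 2) stop("need at least 2 units")
  xbar <- mean(x)
  s2 <- mean(x^2) - xbar^2           # population variance
  if (s2 <= 0) stop("zero variance: x is constant")
  s <- sqrt(s2)
  xv <- stats::setNames(x, w$ids)
  self <- if (w$include_self) 1 else 0
  z <- numeric(n)
  for (i in seq_len(n)) {
    nb <- w$neighbors[[w$ids[i]]]
    wi <- length(nb) + self                   # sum of weights (binary)
    s1 <- wi                                  # sum of squared weights (binary)
    num <- sum(xv[nb]) + self * x[i] - xbar * wi
    den2 <- (n * s1 - wi^2) / (n - 1)
    if (den2 <= 0) {
      stop("degenerate weights for unit ", w$ids[i],
           ": connected to every unit")
    }
    z[i] <- num / (s * sqrt(den2))
  }
  stats::setNames(z, w$ids)
}

#' Categorize Gi* segregation Z-scores
#'
#' Three classes from the Z-score distribution: `High` for Z at or above the
#' upper cut point (default 1.96, the two-sided 5\% normal critical value),
#' `Medium` for Z in `[0, 1.96)`, and `Low` for negative Z.
#'
#' @param z numeric vector of Gi* Z-scores (finite).
#' @param cutpoints numeric length-2, `c(low, high)`; defaults `c(0, 1.96)`.
#' @return factor with levels `Low`, `Medium`, `High`.
#' @export
categorize_segregation <- function(z, cutpoints = c(0, 1.96)) {
  if (any(!is.finite(z))) stop("non-finite Z-score")
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2])
  cat <- ifelse(z >= cutpoints[2], "High",
                ifelse(z >= cutpoints[1], "Medium", "Low"))
  factor(cat, levels = c("Low", "Medium", "High"))
}

#' Composite neighborhood deprivation index
#'
#' Combines three area-level indicators — share of households below half a
#' minimum wage, illiteracy rate among residents aged 7+, and share of
#' residents with inadequate sanitation — into one score: each indicator is
#' z-standardized across neighborhoods (population SD) and the three are
#' averaged. Categories use the mean of the score plus/minus `half_width`
#' standard deviations: above the upper threshold is `High` deprivation, below
#' the lower threshold `Low`, `Medium` between.
#'
#' @param inputs data frame or matrix with three columns of proportions, one
#'   row per neighborhood (order: below-half-MW, illiteracy, sanitation; any
#'   three indicators oriented so larger = more deprived work).
#' @param half_width half-width of the Medium band in SD units (default 0.5).
#' @return list with `score` (numeric), `category` (factor `Low`/`Medium`/
#'   `High`), and `thresholds` (lower and upper cut points).
#' @export
deprivation_index <- function(inputs, half_width = 0.5) {
  m <- as.matrix(inputs)
  if (ncol(m) != 3) stop("expected exactly three deprivation indicators")
  if (any(!is.finite(m))) stop("non-finite deprivation indicator values")
  if (nrow(m) < 2) stop("need at least 2 neighborhoods")
  sd_pop <- function(v) sqrt(mean(v^2) - mean(v)^2)
  for (k in seq_len(ncol(m))) {
    s <- sd_pop(m[, k])
    if (s == 0) {
      stop("zero variance in indicator ",
           if (!is.null(colnames(m))) colnames(m)[k] else k)
    }
    m[, k] <- (m[, k] - mean(m[, k])) / s
  }
  score <- rowMeans(m)
  mu <- mean(score)
  s <- sd_pop(score)
  thr <- c(lower = mu - half_width * s, upper = mu + half_width * s)
  cat <- ifelse(score > thr["upper"], "High",
                ifelse(score < thr["lower"], "Low", "Medium"))
  list(score = score,
       category = factor(cat, levels = c("Low", "Medium", "High")),
       thresholds = thr)
}
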