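#' Classify establishments into subcategory counts per neighborhood
#'
#' Each establishment is assigned exactly one subcategory by longest-prefix
#' match of its activity code, or `non_food` when no prefix matches (unknown
#' codes are permitted and reported via attribute `n_unknown`). Counts are
#' returned for every subcategory, zeros included, and for every neighborhood
#' in `neighborhood_ids` (defaults to those present in the registry).
#'
#' @param establishments data frame with columns `establishment_id`,
#'   `neighborhood_id`, `activity_code`.
#' @param map a [category_map].
#' @param neighborhood_ids optional character vector of all neighborhoods to
#'   report (so empty neighborhoods get zero rows).
#' @return data frame: `neighborhood_id`, one count column per subcategory,
#'   plus `non_food`.
#' @export
classify_establishments <- function(establishments, map = default_category_map(),
                                    neighborhood_ids = NULL) {
  stopifnot(inherits(map, "category_map"))
  need <- c("establishment_id", "neighborhood_id", "activity_code")
  miss <- setdiff(need, names(establishments))
  if (length(miss)) stop("establishments missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(establishments$establishment_id)) {
    stop("duplicate establishment ids")
  }
  if (is.null(neighborhood_ids)) {
    neighborhood_ids <- sort(unique(as.character(establishments$neighborhood_id)))
  }
  subs <- c(subcategories(map), "non_food")
  sub <- match_subcategory(as.character(establishments$activity_code), map)
  tab <- table(factor(as.character(establishments$neighborhood_id),
                      levels = neighborhood_ids),
               factor(sub, levels = subs))
  out <- data.frame(neighborhood_id = neighborhood_ids, stringsAsFactors = FALSE)
  for (s in subs) out[[s]] <- as.integer(tab[, s])
  attr(out, "n_unknown") <- sum(sub == "non_food")
  out
}

#' Food-environment metrics per neighborhood
#'
#' Computes healthy-establishment counts and densities, food-desert and
#' food-swamp flags, and the modified Retail Food Environment Index.
#' Healthy establishments are the sum of `in_natura` and `mixed` counts; the
#' density is per 10,000 inhabitants. A neighborhood is a food desert when its
#' healthy density falls strictly below the `desert_percentile`-th percentile
#' of the city-wide density distribution, and a food swamp when its count over
#' the map's swamp subcategories exceeds `swamp_threshold`.
#'
#' @param counts output of [classify_establishments()] (all neighborhoods).
#' @param population named numeric vector or data frame
#'   (`neighborhood_id`, `population`) with positive populations.
#' @param map the [category_map] used for classification.
#' @param desert_percentile percentile (0-100) defining the desert threshold.
#' @param swamp_threshold swamp flag requires strictly more than this count.
#' @return data frame: `neighborhood_id`, `healthy_count`, `healthy_density`,
#'   `desert`, `swamp_count`, `swamp`, `desert_and_swamp`, `mrfei`; the desert
#'   density threshold is attached as attribute `desert_threshold`.
#' @export
food_env_metrics <- function(counts, population, map = default_category_map(),
                             desert_percentile = 25, swamp_threshold = 4) {
  stopifnot(inherits(map, "category_map"))
  if (is.data.frame(population)) {
    population <- stats::setNames(population$population,
                                  population$neighborhood_id)
  }
  pop <- population[counts$neighborhood_id]
  if (any(is.na(pop))) stop("population missing for some neighborhoods")
  if (any(pop <= 0)) stop("population must be positive for every neighborhood")

  cls <- map$macro_class
  count_over <- function(subs) {
    m <- as.matrix(counts[, subs, drop = FALSE])
    as.integer(rowSums(m))
  }
  healthy <- count_over(names(cls)[cls %in% c("in_natura", "mixed")])
  unhealthy <- count_over(names(cls)[cls == "ultraprocessed"])
  density <- 10000 * healthy / pop

  des <- desert_flags(density, desert_percentile)
  sw <- swamp_flags(counts, map, swamp_threshold)

  out <- data.frame(
    neighborhood_id = counts$neighborhood_id,
    healthy_count = healthy,
    healthy_density = as.numeric(density),
    desert = des$desert,
    swamp_count = sw$swamp_count,
    swamp = sw$swamp,
    stringsAsFactors = FALSE
  )
  out$desert_and_swamp <- out$desert & out$swamp
  out$mrfei <- mrfei(healthy, unhealthy)
  attr(out, "desert_threshold") <- des$threshold
  out
}

#' Food-desert flags from healthy-establishment densities
#'
#' The threshold is the empirical `percentile`-th percentile (linear
#' interpolation between order statistics) of the density distribution over
#' all neighborhoods; deserts are strictly below it. With all densities equal
#' no neighborhood is a desert.
#'
#' @param density numeric vector of healthy densities (finite).
#' @param percentile percentile in \[0, 100).
#' @return list with logical `desert` and numeric `threshold`.
#' @export
desert_flags <- function(density, percentile = 25) {
  if (length(density) < 4) stop("need at least 4 neighborhoods")
  if (any(!is.finite(density))) stop("densities must be finite")
  if (percentile < 0 || percentile >= 100) stop("percentile must be in [0, 100)")
  threshold <- stats::quantile(density, percentile / 100, type = 7, names = FALSE)
  list(desert = density < threshold, threshold = threshold)
}

#' Food-swamp flags from subcategory counts
#'
#' Sums the counts over the map's swamp subcategories (default: convenience
#' stores, cafeterias / snack bars, mini markets, candy shops); a neighborhood
#' with strictly more than `threshold` such establishments is a swamp.
#'
#' @param counts output of [classify_establishments()].
#' @param map a [category_map].
#' @param threshold swamp cut-off; flag requires `swamp_count > threshold`.
#' @return list with integer `swamp_count` and logical `swamp`.
#' @export
swamp_flags <- function(counts, map = default_category_map(), threshold = 4) {
  stopifnot(inherits(map, "category_map"))
  m <- as.matrix(counts[, map$swamp_subcategories, drop = FALSE])
  swamp_count <- as.integer(rowSums(m))
  list(swamp_count = swamp_count, swamp = swamp_count > threshold)
}

#' Modified Retail Food Environment Index
#'
#' `mRFEI = 100 * healthy / (healthy + unhealthy)`, the percentage of healthy
#' outlets among healthy plus less-healthy outlets. Undefined (`NA`, not zero)
#' when a neighborhood has no outlets in either group.
#'
#' @param healthy_count,unhealthy_count non-negative integer vectors.
#' @return numeric vector in \[0, 100\] with `NA` where undefined.
#' @export
mrfei <- function(healthy_count, unhealthy_count) {
  stopifnot(length(healthy_count) == length(unhealthy_count))
  if (any(healthy_count < 0) || any(unhealthy_count < 0)) {
    stop("counts must be non-negative")
  }
  den <- healthy_count + unhealthy_count
  ifelse(den > 0, 100 * healthy_count / den, NA_real_)
}
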