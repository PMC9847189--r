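#' Scenario configuration for the synthetic-city generator
#'
#' Describes a city on a rectangular lattice of neighborhoods, each composed of
#' census tracts, with an optional planted low-income cluster, an establishment
#' registry drawn from Poisson rates, and a school roster. All randomness is
#' governed by `seed`, which is expanded into independent substreams per
#' component (population, income, deprivation, establishments, schools), so
#' e.g. changing the school settings does not perturb establishment draws.
#'
#' Household-head income is lognormal; within each stratum the log-scale mean
#' is solved so that the probability of earning at most `3 * min_wage` equals
#' the configured low-income proportion (background or cluster). Proportions
#' are clamped to `[0.001, 0.999]` for this inversion.
#'
#' @param grid_rows,grid_cols lattice dimensions (neighborhoods), >= 1.
#' @param tracts_per_neighborhood census tracts per neighborhood, >= 1.
#' @param population_per_tract expected residents per tract (Poisson mean).
#' @param households_per_tract expected household heads per tract
#'   (Poisson mean).
#' @param min_wage monthly minimum wage in the city's currency (default 510,
#'   the 2010 Brazilian value).
#' @param income_sdlog lognormal sd of log household-head income.
#' @param low_income_prop background proportion of household heads earning
#'   0-3 minimum wages.
#' @param cluster_cells two-column matrix (row, col) of lattice cells forming
#'   the planted low-income cluster, or `NULL`.
#' @param cluster_low_income_prop elevated 0-3 MW proportion inside the
#'   cluster.
#' @param establishment_rates named numeric vector of expected establishment
#'   counts per neighborhood, one entry per subcategory of `map`.
#' @param rate_overrides named list: neighborhood id -> replacement rate
#'   vector (used by [plant_desert_swamp()]).
#' @param schools_per_neighborhood schools in every neighborhood, >= 1.
#' @param public_fraction probability a school is public.
#' @param prop_professional_only,prop_special_only probabilities that a school
#'   is tagged professional-education-only / special-education-only (exclusion
#'   tags consumed by [filter_schools()]).
#' @param map the [category_map] whose subcategories the rates refer to.
#' @param seed integer random seed.
#' @return object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(grid_rows = 5, grid_cols = 5,
                            tracts_per_neighborhood = 3,
                            population_per_tract = 800,
                            households_per_tract = 250,
                            min_wage = 510,
                            income_sdlog = 0.8,
                            low_income_prop = 0.3,
                            cluster_cells = NULL,
                            cluster_low_income_prop = 0.7,
                            establishment_rates = default_establishment_rates(),
                            rate_overrides = list(),
                            schools_per_neighborhood = 2,
                            public_fraction = 0.55,
                            prop_professional_only = 0,
                            prop_special_only = 0,
                            map = default_category_map(),
                            seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
      stop("invalid ", nm, ": must be a single integer >= 1")
    }
  }
  chk_prop <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop("invalid ", nm, ": must be a proportion in [0, 1]")
    }
  }
  chk_count(grid_rows, "grid_rows"); chk_count(grid_cols, "grid_cols")
  chk_count(tracts_per_neighborhood, "tracts_per_neighborhood")
  chk_count(schools_per_neighborhood, "schools_per_neighborhood")
  chk_count(population_per_tract, "population_per_tract")
  chk_count(households_per_tract, "households_per_tract")
  chk_prop(low_income_prop, "low_income_prop")
  chk_prop(cluster_low_income_prop, "cluster_low_income_prop")
  chk_prop(public_fraction, "public_fraction")
  chk_prop(prop_professional_only, "prop_professional_only")
  chk_prop(prop_special_only, "prop_special_only")
  if (!is.finite(min_wage) || min_wage <= 0) stop("invalid min_wage")
  if (!is.finite(income_sdlog) || income_sdlog <= 0) stop("invalid income_sdlog")
  stopifnot(inherits(map, "category_map"))
  subs <- subcategories(map)
  if (!setequal(names(establishment_rates), subs)) {
    stop("invalid establishment_rates: need one rate per subcategory (",
         paste(subs, collapse = ", "), ")")
  }
  if (any(!is.finite(establishment_rates)) || any(establishment_rates < 0)) {
    stop("invalid establishment_rates: rates must be finite and >= 0")
  }
  if (!is.null(cluster_cells)) {
    cluster_cells <- as.matrix(cluster_cells)
    if (ncol(cluster_cells) != 2) stop("invalid cluster_cells: need (row, col) pairs")
    if (any(cluster_cells[, 1] < 1) || any(cluster_cells[, 1] > grid_rows) ||
        any(cluster_cells[, 2] < 1) || any(cluster_cells[, 2] > grid_cols)) {
      stop("invalid cluster_cells: coordinates outside the lattice")
    }
  }
  for (nm in names(rate_overrides)) {
    r <- rate_overrides[[nm]]
    if (!setequal(names(r), subs) || any(!is.finite(r)) || any(r < 0)) {
      stop("invalid rate_overrides for ", nm)
    }
  }
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed)) {
    stop("invalid seed")
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    tracts_per_neighborhood = as.integer(tracts_per_neighborhood),
    population_per_tract = population_per_tract,
    households_per_tract = households_per_tract,
    min_wage = min_wage, income_sdlog = income_sdlog,
    low_income_prop = low_income_prop,
    cluster_cells = cluster_cells,
    cluster_low_income_prop = cluster_low_income_prop,
    establishment_rates = establishment_rates[subs],
    rate_overrides = rate_overrides,
    schools_per_neighborhood = as.integer(schools_per_neighborhood),
    public_fraction = public_fraction,
    prop_professional_only = prop_professional_only,
    prop_special_only = prop_special_only,
    map = map,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Default expected establishment counts per neighborhood
#'
#' Free parameters of the generator (no public registry to calibrate
#' against); set so the relative abundance across subcategories resembles a
#' dense Brazilian metropolis at the neighborhood scale — cafeterias and mini
#' markets common, seafood and convenience stores sparse.
#'
#' @return named numeric vector, one rate per subcategory.
#' @export
default_establishment_rates <- function() {
  c(butchery = 1, seafood = 0.3, fruits_vegetables = 0.7,
    street_vendor = 0.5, bar = 1, cafeteria = 5, convenience = 0.3,
    candy = 0.8,
    hypermarket_supermarket = 2, food_store = 1, mini_market = 3,
    bakery = 1, restaurant = 2.5)
}

#' Plant food-desert and food-swamp neighborhoods in a scenario
#'
#' Returns a modified configuration whose establishment rates make the given
#' lattice cells deserts (healthy-category rates scaled by `desert_scale`,
#' default 0, driving the healthy density below the city-wide percentile
#' threshold) or swamps (rates over the map's swamp subcategories replaced so
#' they total `swamp_rate`, comfortably above the >4 swamp cut-off). With both
#' cell sets empty the configuration is returned unchanged.
#'
#' @param config a [scenario_config].
#' @param desert_cells,swamp_cells two-column matrices (row, col) of lattice
#'   cells, or `NULL`. A cell may not appear in both sets.
#' @param desert_scale multiplier applied to healthy-category rates in desert
#'   cells.
#' @param swamp_rate total expected swamp-subcategory count in swamp cells.
#' @return a modified [scenario_config].
#' @export
plant_desert_swamp <- function(config, desert_cells = NULL, swamp_cells = NULL,
                               desert_scale = 0, swamp_rate = 12) {
  stopifnot(inherits(config, "scenario_config"))
  as_cells <- function(x) {
    if (is.null(x) || (is.matrix(x) && nrow(x) == 0)) return(NULL)
    x <- matrix(as.numeric(x), ncol = 2)
    if (any(x < 1) || any(x[, 1] > config$grid_rows) ||
        any(x[, 2] > config$grid_cols) || any(x != round(x))) {
      stop("invalid cell coordinates")
    }
    x
  }
  desert_cells <- as_cells(desert_cells)
  swamp_cells <- as_cells(swamp_cells)
  if (is.null(desert_cells) && is.null(swamp_cells)) return(config)
  key <- function(m) paste(m[, 1], m[, 2], sep = ",")
  if (!is.null(desert_cells) && !is.null(swamp_cells) &&
      length(intersect(key(desert_cells), key(swamp_cells)))) {
    stop("overlapping cells: a cell may not be planted as both desert and swamp")
  }
  map <- config$map
  healthy <- names(map$macro_class)[map$macro_class %in% c("in_natura", "mixed")]
  cell_id <- function(r, c) sprintf("N%03d", (r - 1L) * config$grid_cols + c)
  ov <- config$rate_overrides
  if (!is.null(desert_cells)) {
    for (k in seq_len(nrow(desert_cells))) {
      id <- cell_id(desert_cells[k, 1], desert_cells[k, 2])
      r <- if (!is.null(ov[[id]])) ov[[id]] else config$establishment_rates
      r[healthy] <- r[healthy] * desert_scale
      ov[[id]] <- r
    }
  }
  if (!is.null(swamp_cells)) {
    sw <- map$swamp_subcategories
    for (k in seq_len(nrow(swamp_cells))) {
      id <- cell_id(swamp_cells[k, 1], swamp_cells[k, 2])
      r <- if (!is.null(ov[[id]])) ov[[id]] else config$establishment_rates
      r[sw] <- swamp_rate / length(sw)
      ov[[id]] <- r
    }
  }
  config$rate_overrides <- ov
  config
}

# expand one master seed into independent component substreams
component_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 5),
                  c("population", "income", "deprivation",
                    "establishments", "schools"))
}

#' Generate a synthetic city
#'
#' Builds the full bundle a real-city analysis would read: census tracts with
#' socioeconomic microdata, lattice neighborhoods with rook adjacency, a food
#' establishment registry with activity codes, and a school roster. The
#' deprivation indicators are coupled to each tract's low-income proportion,
#' so planted income clusters are also deprivation hot spots.
#'
#' @param config a [scenario_config].
#' @return object of class `synthetic_city`: list with `config`, `tracts`,
#'   `neighborhoods`, `adjacency` (a [spatial_weights]), `establishments`,
#'   `schools`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- component_seeds(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  n_nb <- nr * nc
  nb_ids <- sprintf("N%03d", seq_len(n_nb))
  nb_row <- rep(seq_len(nr), each = nc)
  nb_col <- rep(seq_len(nc), times = nr)

  in_cluster <- rep(FALSE, n_nb)
  if (!is.null(config$cluster_cells)) {
    idx <- (config$cluster_cells[, 1] - 1L) * nc + config$cluster_cells[, 2]
    in_cluster[idx] <- TRUE
  }

  tpn <- config$tracts_per_neighborhood
  n_tr <- n_nb * tpn
  tract_nb <- rep(nb_ids, each = tpn)
  tract_cluster <- rep(in_cluster, each = tpn)

  # population & households
  set.seed(seeds["population"])
  population <- pmax(1L, stats::rpois(n_tr, config$population_per_tract))
  heads <- pmax(1L, stats::rpois(n_tr, config$households_per_tract))
  persons_7plus <- pmax(1L, round(0.9 * population))

  # household-head income: lognormal, meanlog solved from the target 0-3 MW share
  set.seed(seeds["income"])
  p_low <- ifelse(tract_cluster, config$cluster_low_income_prop,
                  config$low_income_prop)
  p_low <- pmin(pmax(p_low, 0.001), 0.999)
  cut3 <- 3 * config$min_wage
  meanlog <- log(cut3) - config$income_sdlog * stats::qnorm(p_low)
  total_income <- numeric(n_tr)
  heads_0_3 <- integer(n_tr)
  for (i in seq_len(n_tr)) {
    inc <- stats::rlnorm(heads[i], meanlog[i], config$income_sdlog)
    total_income[i] <- sum(inc)
    heads_0_3[i] <- sum(inc <= cut3)
  }

  # deprivation indicators, coupled to the tract's low-income propensity
  set.seed(seeds["deprivation"])
  below_half <- stats::rbinom(n_tr, heads, 0.05 + 0.35 * p_low)
  illiterate <- stats::rbinom(n_tr, persons_7plus, 0.01 + 0.08 * p_low)
  bad_sanit <- stats::rbinom(n_tr, population, 0.02 + 0.25 * p_low)

  tracts <- data.frame(
    tract_id = sprintf("T%05d", seq_len(n_tr)),
    neighborhood_id = tract_nb,
    population = population,
    total_income = total_income,
    household_heads_total = heads,
    household_heads_0_3_mw = heads_0_3,
    households_below_half_mw = below_half,
    persons_7plus = persons_7plus,
    illiterate_7plus = illiterate,
    persons_inadequate_sanitation = bad_sanit,
    stringsAsFactors = FALSE
  )

  neighborhoods <- data.frame(
    neighborhood_id = nb_ids, row = nb_row, col = nb_col,
    in_cluster = in_cluster,
    population = as.integer(tapply(population,
                                   factor(tract_nb, levels = nb_ids), sum)),
    stringsAsFactors = FALSE
  )

  # establishments: Poisson counts per neighborhood x subcategory
  set.seed(seeds["establishments"])
  subs <- subcategories(config$map)
  # one representative full code per subcategory, from the map's prefixes
  codes <- stats::setNames(names(config$map$code_prefixes),
                           unname(config$map$code_prefixes))[subs]
  est_nb <- character(0); est_code <- character(0)
  for (i in seq_len(n_nb)) {
    rates <- config$rate_overrides[[nb_ids[i]]]
    if (is.null(rates)) rates <- config$establishment_rates
    k <- stats::rpois(length(subs), rates[subs])
    if (sum(k) > 0) {
      est_nb <- c(est_nb, rep(nb_ids[i], sum(k)))
      est_code <- c(est_code, rep(codes, k))
    }
  }
  establishments <- data.frame(
    establishment_id = if (length(est_nb)) sprintf("E%05d", seq_along(est_nb))
                       else character(0),
    neighborhood_id = est_nb,
    activity_code = est_code,
    stringsAsFactors = FALSE
  )

  # schools
  set.seed(seeds["schools"])
  n_sch <- n_nb * config$schools_per_neighborhood
  schools <- data.frame(
    school_id = sprintf("S%04d", seq_len(n_sch)),
    neighborhood_id = rep(nb_ids, each = config$schools_per_neighborhood),
    sector = ifelse(stats::runif(n_sch) < config$public_fraction,
                    "Public", "Private"),
    professional_only = stats::runif(n_sch) < config$prop_professional_only,
    special_only = stats::runif(n_sch) < config$prop_special_only,
    stringsAsFactors = FALSE
  )

  structure(list(config = config,
                 tracts = tracts,
                 neighborhoods = neighborhoods,
                 adjacency = lattice_rook_weights(nr, nc, ids = nb_ids),
                 establishments = establishments,
                 schools = schools),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("Synthetic city:",
      nrow(x$neighborhoods), "neighborhoods (",
      x$config$grid_rows, "x", x$config$grid_cols, "lattice ),",
      nrow(x$tracts), "tracts\n")
  cat("  population:", sum(x$tracts$population),
      "| establishments:", nrow(x$establishments),
      "| schools:", nrow(x$schools), "\n")
  invisible(x)
}
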