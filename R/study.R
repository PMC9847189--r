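#' End-to-end neighborhood food-environment inequality analysis
#'
#' Runs the full pipeline on a city bundle (generated by [generate_city()] or
#' read by [read_city()]): tract aggregation, the three inequality measures
#' (income terciles, Gi* segregation over the city's rook adjacency, the
#' composite deprivation index), establishment classification, desert/swamp
#' flagging, school-roster filtering, and the stratified prevalence tables
#' with Pearson chi-square tests.
#'
#' @param city a city bundle: `tracts`, `neighborhoods`, `adjacency`,
#'   `establishments`, `schools`.
#' @param map a [category_map].
#' @param desert_percentile desert threshold percentile (default 25).
#' @param swamp_threshold swamp flag requires strictly more than this many
#'   swamp-subcategory establishments (default 4).
#' @param seg_cutpoints Gi* category cut points, `c(low, high)`
#'   (default `c(0, 1.96)`).
#' @param deprivation_half_width half-width (in SD) of the Medium deprivation
#'   band (default 0.5).
#' @param gi_level unit at which the Gi* statistic is computed.
#'   `"neighborhood"` (default) scores each neighborhood on neighborhood
#'   adjacency; `"tract"` scores tracts (tracts of the same or of adjacent
#'   neighborhoods are neighbors) and assigns each neighborhood the majority
#'   tract category, with its mean tract Z-score kept for reference.
#' @return object of class `city_study` with components `neighborhoods`
#'   (indexed data frame), `food_env`, `schools` (retained roster with
#'   inherited categories and flags), `filter_audit`, `table1`, `table2`,
#'   `table3`, `thresholds`, and `params`.
#' @export
city_study <- function(city,
                       map = default_category_map(),
                       desert_percentile = 25,
                       swamp_threshold = 4,
                       seg_cutpoints = c(0, 1.96),
                       deprivation_half_width = 0.5,
                       gi_level = c("neighborhood", "tract")) {
  gi_level <- match.arg(gi_level)

  nb <- run_stage("geo_indices", aggregate_tracts(city$tracts))
  w <- city$adjacency
  if (!setequal(w$ids, nb$neighborhood_id)) {
    stop("geo_indices: adjacency ids do not match aggregated neighborhoods")
  }
  nb <- nb[match(w$ids, nb$neighborhood_id), , drop = FALSE]
  rownames(nb) <- NULL

  ter <- run_stage("geo_indices", income_terciles(nb$per_capita_income))
  nb$tercile <- ter$category

  if (gi_level == "neighborhood") {
    nb$segregation_z <- run_stage("geo_indices",
                                  gi_star(nb$prop_heads_0_3_mw, w))
    nb$segregation_cat <- categorize_segregation(nb$segregation_z, seg_cutpoints)
  } else {
    seg <- run_stage("geo_indices",
                     tract_level_segregation(city$tracts, w, seg_cutpoints))
    nb$segregation_z <- seg$mean_z[nb$neighborhood_id]
    nb$segregation_cat <- seg$category[nb$neighborhood_id]
  }

  dep <- run_stage("geo_indices", deprivation_index(
    nb[, c("prop_below_half_mw", "prop_illiterate",
           "prop_inadequate_sanitation")],
    half_width = deprivation_half_width))
  nb$deprivation_score <- dep$score
  nb$deprivation_cat <- dep$category

  counts <- run_stage("food_environment", classify_establishments(
    city$establishments, map, neighborhood_ids = nb$neighborhood_id))
  fe <- run_stage("food_environment", food_env_metrics(
    counts, stats::setNames(nb$population, nb$neighborhood_id), map,
    desert_percentile = desert_percentile, swamp_threshold = swamp_threshold))

  sch <- city$schools
  idx <- match(sch$neighborhood_id, nb$neighborhood_id)
  if (anyNA(idx)) stop("schools reference unknown neighborhoods")
  sch$tercile <- nb$tercile[idx]
  sch$deprivation_cat <- nb$deprivation_cat[idx]
  sch$segregation_cat <- nb$segregation_cat[idx]
  fidx <- match(sch$neighborhood_id, fe$neighborhood_id)
  sch$desert <- fe$desert[fidx]
  sch$swamp <- fe$swamp[fidx]
  sch$desert_and_swamp <- fe$desert_and_swamp[fidx]

  flt <- run_stage("cli_io", filter_schools(sch))
  sch <- flt$schools

  strata <- list(
    sector = factor(sch$sector, levels = c("Public", "Private")),
    income_tercile = factor(sch$tercile, levels = c("Lowest", "Middle", "Highest")),
    deprivation = factor(sch$deprivation_cat, levels = c("High", "Medium", "Low")),
    segregation = factor(sch$segregation_cat, levels = c("High", "Medium", "Low"))
  )
  strata <- lapply(strata, droplevels)

  table1 <- do.call(rbind, lapply(names(strata), function(v) {
    tab <- table(strata[[v]])
    data.frame(stratum_var = v, level = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / nrow(sch), 1),
               stringsAsFactors = FALSE)
  }))

  table2 <- run_stage("stats_tabulation",
                      school_count_summaries(sch, counts, map))

  flags <- c("desert", "swamp", "desert_and_swamp")
  table3 <- do.call(rbind, lapply(flags, function(fl) {
    do.call(rbind, lapply(names(strata), function(v) {
      ct <- run_stage("stats_tabulation", crosstab(strata[[v]], sch[[fl]],
                                                   ids = sch$school_id))
      p <- if (length(ct$levels) >= 2 && sum(ct$flagged) > 0 &&
               sum(ct$flagged) < sum(ct$totals)) {
        run_stage("stats_tabulation", chi_square(ct))$p_value
      } else NA_real_
      data.frame(flag = fl, stratum_var = v, level = ct$levels,
                 n = ct$totals, flagged = ct$flagged,
                 prevalence = ct$prevalence,
                 p_value = p, p_label = format_p_value(p),
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    neighborhoods = nb,
    food_env = fe,
    establishment_counts = counts,
    schools = sch,
    filter_audit = flt$audit,
    table1 = table1, table2 = table2, table3 = table3,
    thresholds = list(desert_density = attr(fe, "desert_threshold"),
                      tercile_boundaries = ter$boundaries,
                      deprivation = dep$thresholds),
    params = list(desert_percentile = desert_percentile,
                  swamp_threshold = swamp_threshold,
                  seg_cutpoints = seg_cutpoints,
                  deprivation_half_width = deprivation_half_width,
                  gi_level = gi_level)
  ), class = "city_study")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

# Tract-level Gi* mode: tracts inherit adjacency from their neighborhoods
# (same neighborhood, or rook-adjacent neighborhoods), each tract is scored,
# and every neighborhood takes the majority category of its tracts
# (ties broken toward the more segregated category).
tract_level_segregation <- function(tracts, w, seg_cutpoints) {
  nb_of <- tracts$neighborhood_id
  ids <- tracts$tract_id
  nbrs <- lapply(seq_along(ids), function(i) {
    ok <- nb_of == nb_of[i] | nb_of %in% w$neighbors[[nb_of[i]]]
    setdiff(ids[ok], ids[i])
  })
  tw <- spatial_weights(ids, stats::setNames(nbrs, ids))
  x <- ifelse(tracts$household_heads_total > 0,
              tracts$household_heads_0_3_mw / tracts$household_heads_total, 0)
  z <- gi_star(x, tw)
  cat <- categorize_segregation(z, seg_cutpoints)
  g <- factor(nb_of, levels = unique(nb_of))
  majority <- tapply(cat, g, function(v) {
    tab <- table(factor(v, levels = c("High", "Medium", "Low")))
    names(tab)[which.max(tab)]       # ties -> High before Medium before Low
  })
  list(mean_z = tapply(z, g, mean),
       category = stats::setNames(
         factor(as.character(majority), levels = c("Low", "Medium", "High")),
         levels(g)))
}

# School-level establishment-count summaries (each school carries its
# neighborhood's counts): per subcategory, per macro class, and in total,
# for all schools together and by sector.
school_count_summaries <- function(schools, counts, map) {
  idx <- match(schools$neighborhood_id, counts$neighborhood_id)
  subs <- subcategories(map)
  sc <- counts[idx, subs, drop = FALSE]
  for (cl in c("in_natura", "ultraprocessed", "mixed")) {
    sc[[cl]] <- rowSums(sc[, subs[map$macro_class == cl], drop = FALSE])
  }
  sc$total <- rowSums(sc[, subs, drop = FALSE])
  overall <- summarize_counts(sc, factor(rep("Total", nrow(sc))))
  by_sector <- summarize_counts(sc, factor(schools$sector,
                                           levels = c("Public", "Private")))
  rbind(overall, by_sector)
}

#' @export
print.city_study <- function(x, ...) {
  n_nb <- nrow(x$neighborhoods)
  cat("Neighborhood food-environment inequality study\n")
  cat("  neighborhoods:", n_nb,
      "| schools retained:", nrow(x$schools), "\n")
  cat(sprintf("  food deserts: %d (%.1f%%) | food swamps: %d (%.1f%%)\n",
              sum(x$food_env$desert), 100 * mean(x$food_env$desert),
              sum(x$food_env$swamp), 100 * mean(x$food_env$swamp)))
  cat(sprintf("  desert density threshold (p%g): %.2f per 10,000\n",
              x$params$desert_percentile, x$thresholds$desert_density))
  invisible(x)
}

#' @export
summary.city_study <- function(object, ...) {
  cat("School prevalence of food deserts / swamps by stratum\n\n")
  t3 <- object$table3
  for (fl in unique(t3$flag)) {
    cat("==", fl, "==\n")
    sub <- t3[t3$flag == fl, c("stratum_var", "level", "n", "flagged",
                               "prevalence", "p_label")]
    print(sub, row.names = FALSE)
    cat("\n")
  }
  invisible(object)
}

#' @param x a `city_study` object.
#' @param flag which flag to plot (`"desert"`, `"swamp"`,
#'   `"desert_and_swamp"`).
#' @param ... passed to [graphics::barplot()].
#' @rdname city_study
#' @export
plot.city_study <- function(x, flag = "desert", ...) {
  t3 <- x$table3[x$table3$flag == flag, ]
  graphics::barplot(t3$prevalence,
                    names.arg = paste(t3$stratum_var, t3$level, sep = ":"),
                    las = 2, ylab = "prevalence (%)",
                    main = paste("School prevalence:", flag), ...)
  invisible(x)
}

#' Write study outputs to disk
#'
#' Writes `table1.csv` (sample composition), `table2.csv` (establishment
#' count summaries), `table3.csv` (stratified prevalence with chi-square
#' p-values), `neighborhoods_indexed.csv`, `food_environment.csv`, and a
#' machine-readable `results.json`. Output is deterministic: rerunning the
#' same study writes byte-identical files.
#'
#' @param study a `city_study` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(study, dir) {
  stopifnot(inherits(study, "city_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(study$table1, "table1.csv")
  wr(study$table2, "table2.csv")
  wr(study$table3, "table3.csv")
  nb <- study$neighborhoods
  nb$tercile <- as.character(nb$tercile)
  nb$segregation_cat <- as.character(nb$segregation_cat)
  nb$deprivation_cat <- as.character(nb$deprivation_cat)
  wr(nb, "neighborhoods_indexed.csv")
  wr(study$food_env, "food_environment.csv")
  res <- list(
    thresholds = study$thresholds,
    params = study$params[c("desert_percentile", "swamp_threshold",
                            "seg_cutpoints", "deprivation_half_width",
                            "gi_level")],
    filter_audit = study$filter_audit,
    n_neighborhoods = nrow(study$neighborhoods),
    n_schools = nrow(study$schools),
    desert_prevalence_pct = round(100 * mean(study$schools$desert), 1),
    swamp_prevalence_pct = round(100 * mean(study$schools$swamp), 1),
    both_prevalence_pct = round(100 * mean(study$schools$desert_and_swamp), 1),
    table3 = study$table3
  )
  writeLines(jsonlite::toJSON(res, auto_unbox = TRUE, digits = 10, na = "null",
                              pretty = TRUE),
             file.path(dir, "results.json"))
  invisible(dir)
}
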