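# Independent brute-force oracle for the Gi* statistic: explicit dense weight
# matrix, literal evaluation of the Z-score formula. Deliberately shares no
# code with gi_star().
weights_matrix <- function(w) {
  n <- length(w$ids)
  m <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in w$ids) m[i, w$neighbors[[i]]] <- 1
  if (w$include_self) diag(m) <- 1
  m
}

gi_star_oracle <- function(x, wmat) {
  n <- length(x)
  xbar <- sum(x) / n
  s <- sqrt(sum((x - xbar)^2) / n)          # population SD
  z <- numeric(n)
  for (i in seq_len(n)) {
    wi <- sum(wmat[i, ])
    s1 <- sum(wmat[i, ]^2)
    num <- sum(wmat[i, ] * x) - xbar * wi
    z[i] <- num / (s * sqrt((n * s1 - wi^2) / (n - 1)))
  }
  z
}

# Monte-Carlo null for the Pearson statistic: tables drawn multinomially with
# cell probabilities under independence (margins estimated from the observed
# table); degenerate draws (a zero margin) count as extreme.
multinomial_null_p <- function(m, observed_stat, reps = 1e5) {
  n <- sum(m)
  pr <- as.vector(outer(rowSums(m), colSums(m)) / n^2)
  draws <- stats::rmultinom(reps, n, pr)
  stats_mc <- apply(draws, 2, function(v) {
    t <- matrix(v, nrow(m))
    e <- outer(rowSums(t), colSums(t)) / sum(t)
    if (any(e == 0)) return(Inf)
    sum((t - e)^2 / e)
  })
  mean(stats_mc >= observed_stat - 1e-9)
}

# small hand-built tract table
make_tracts <- function(neighborhood_id, population, total_income,
                        heads = population %/% 3,
                        heads_0_3 = heads %/% 2,
                        below_half = 0, persons7 = population,
                        illiterate = 0, bad_sanit = 0) {
  n <- length(neighborhood_id)
  rec <- function(v) rep_len(v, n)
  data.frame(
    tract_id = sprintf("T%03d", seq_len(n)),
    neighborhood_id = neighborhood_id,
    population = rec(population), total_income = rec(total_income),
    household_heads_total = rec(heads), household_heads_0_3_mw = rec(heads_0_3),
    households_below_half_mw = rec(below_half), persons_7plus = rec(persons7),
    illiterate_7plus = rec(illiterate),
    persons_inadequate_sanitation = rec(bad_sanit),
    stringsAsFactors = FALSE
  )
}

# registry rows for a single neighborhood from subcategory counts
make_registry <- function(counts_by_code, neighborhood_id = "N001",
                          start_id = 1L) {
  codes <- rep(names(counts_by_code), counts_by_code)
  data.frame(
    establishment_id = sprintf("E%04d", seq_along(codes) + start_id - 1L),
    neighborhood_id = neighborhood_id,
    activity_code = codes,
    stringsAsFactors = FALSE
  )
}

# GeoJSON FeatureCollection for a unit-square polygon grid
grid_geojson <- function(nrow, ncol) {
  feats <- list()
  k <- 1L
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      ring <- list(list(c - 1, r - 1), list(c, r - 1), list(c, r),
                   list(c - 1, r), list(c - 1, r - 1))
      feats[[k]] <- list(
        type = "Feature",
        properties = list(neighborhood_id = sprintf("N%03d", k)),
        geometry = list(type = "Polygon", coordinates = list(ring)))
      k <- k + 1L
    }
  }
  list(type = "FeatureCollection", features = feats)
}
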