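test_that("tract aggregation sums, pools and averages correctly", {
  # two identical tracts: per-capita income is total/total
  tr <- make_tracts(c("A", "A"), population = 100, total_income = 50000)
  nb <- aggregate_tracts(tr)
  expect_equal(nb$per_capita_income, 500)
  expect_equal(nb$population, 200)

  # deprivation inputs are tract proportions averaged unweighted
  tr <- make_tracts(c("A", "A"), population = c(100, 200),
                    total_income = 1000, heads = c(10, 10),
                    below_half = c(2, 4))
  nb <- aggregate_tracts(tr)
  expect_equal(nb$prop_below_half_mw, 0.3)

  # 0-3 MW head share is pooled, not tract-averaged
  tr <- make_tracts(c("A", "A", "A"), population = 100, total_income = 1000,
                    heads = c(50, 50, 100), heads_0_3 = c(10, 20, 0))
  nb <- aggregate_tracts(tr)
  expect_equal(nb$prop_heads_0_3_mw, 30 / 200)

  expect_error(aggregate_tracts(
    make_tracts("A", population = 0, total_income = 0)),
    "zero population")
  expect_error(aggregate_tracts(
    make_tracts("A", population = 10, total_income = 1,
                heads = 5, heads_0_3 = 7)),
    "exceed")
})

test_that("income terciles split, break ties downward, and balance counts", {
  t1 <- income_terciles(1:9)
  expect_equal(as.character(t1$category),
               rep(c("Lowest", "Middle", "Highest"), each = 3))

  # a value tied with the lower boundary goes to the lower tercile
  x <- c(1, 2, 3, 3, 5, 6, 7, 8, 9)
  t2 <- income_terciles(x)
  expect_equal(unname(t2$boundaries[1]), 3)
  expect_equal(as.character(t2$category[x == 3]), c("Lowest", "Lowest"))

  set.seed(42)
  x <- rlnorm(300, meanlog = 6.5, sdlog = 0.6)
  t3 <- income_terciles(x)
  expect_equal(as.integer(table(t3$category)), c(100, 100, 100))

  expect_error(income_terciles(rep(5, 10)), "degenerate")
  expect_error(income_terciles(c(1, 2)), "at least 3")
})

test_that("gi_star matches the brute-force oracle", {
  # fixed 3x3 case at tight tolerance
  w <- lattice_rook_weights(3, 3)
  x <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(gi_star(x, w)), gi_star_oracle(x, weights_matrix(w)),
               tolerance = 1e-10)

  # random values on random-size lattices
  set.seed(123)
  for (k in 1:5) {
    w <- lattice_rook_weights(6, 6)
    x <- rnorm(36)
    expect_equal(unname(gi_star(x, w)), gi_star_oracle(x, weights_matrix(w)),
                 tolerance = 1e-8)
  }
})

test_that("a spike at an isolated unit yields the maximum positive Z", {
  nb <- list(a = c("b"), b = c("a", "c"), c = c("b"), d = character(0))
  w <- spatial_weights(c("a", "b", "c", "d"), nb)
  z <- gi_star(c(0, 0, 0, 1), w)
  expect_gt(z[["d"]], 0)
  expect_equal(names(which.max(z)), "d")
})

test_that("a planted high-value cluster is a Gi* hotspot, far corners cold", {
  w <- lattice_rook_weights(5, 5)
  x <- rep(0, 25)
  inside <- with(expand.grid(col = 1:5, row = 1:5),
                 row >= 2 & row <= 4 & col >= 2 & col <= 4)
  x[inside] <- 1
  z <- gi_star(x, w)
  center <- which(w$ids == "N013")     # row 3, col 3
  expect_gt(z[center], 1.96)
  expect_lt(z[1], 0)                   # far corner
  expect_equal(unname(z), gi_star_oracle(x, weights_matrix(w)),
               tolerance = 1e-8)
})

test_that("Gi* numerators sum to zero when every unit has equal total weight", {
  set.seed(99)
  w <- lattice_rook_weights(4, 5, torus = TRUE)
  x <- rnorm(20)
  n <- 20; wi <- 5                      # 4 rook neighbors + self
  s <- sqrt(mean(x^2) - mean(x)^2)
  den <- s * sqrt((n * wi - wi^2) / (n - 1))
  numerators <- gi_star(x, w) * den
  expect_equal(sum(numerators), 0, tolerance = 1e-10)
})

test_that("gi_star rejects degenerate inputs", {
  w <- lattice_rook_weights(3, 3)
  expect_error(gi_star(rep(1, 9), w), "zero variance")
  expect_error(gi_star(1:5, w), "does not match")
})

test_that("segregation Z-scores categorize at the 1.96 and 0 cut points", {
  z <- c(1.96, 2.5, 0, 1.95, -0.01, -3)
  expect_equal(as.character(categorize_segregation(z)),
               c("High", "High", "Medium", "Medium", "Low", "Low"))
  expect_error(categorize_segregation(NaN), "non-finite")
})

test_that("shuffling the input destroys planted-cluster High categories", {
  w <- lattice_rook_weights(5, 5)
  x <- rep(0.2, 25)
  inside <- with(expand.grid(col = 1:5, row = 1:5),
                 row >= 2 & row <= 4 & col >= 2 & col <= 4)
  x[inside] <- 0.9
  center <- which(w$ids == "N013")
  expect_equal(as.character(
    categorize_segregation(gi_star(x, w))[center]), "High")

  set.seed(7)
  hits <- replicate(100, {
    zc <- gi_star(sample(x), w)[center]
    zc >= 1.96
  })
  base_rate <- mean(replicate(100, {
    z <- gi_star(sample(x), w)
    mean(z >= 1.96)
  }))
  # cluster location is no longer special: hit rate near the global base rate
  expect_lt(abs(mean(hits) - base_rate), 0.1)
})

test_that("deprivation index standardizes, averages and categorizes at +-1/2 SD", {
  # extreme point lands in High
  m <- rbind(c(0.9, 0.8, 0.95), matrix(runif(30, 0, 0.3), ncol = 3))
  d <- deprivation_index(m)
  expect_equal(as.character(d$category[1]), "High")
  expect_equal(length(d$score), nrow(m))

  # all-identical inputs are degenerate
  expect_error(deprivation_index(matrix(0.5, nrow = 4, ncol = 3)),
               "zero variance")

  # with a normal score distribution the shares follow the +-0.5 SD normal areas
  set.seed(11)
  m <- matrix(rnorm(3 * 20000), ncol = 3)
  d <- deprivation_index(m)
  shares <- as.numeric(table(d$category) / 20000)   # Low, Medium, High
  expect_equal(shares, c(0.3085, 0.383, 0.3085), tolerance = 0.02)
})
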