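test_that("count summaries use median and SPSS-style interquartile range", {
  counts <- data.frame(shops = c(0, 0, 1, 2, 3))
  s <- summarize_counts(counts, factor(rep("All", 5)))
  expect_equal(s$median, 1)
  expect_equal(s$p25, 0)
  expect_equal(s$p75, 2.5)
  expect_equal(s$pct_at_least_one, 60)

  s0 <- summarize_counts(data.frame(shops = rep(0, 4)), factor(rep("All", 4)))
  expect_equal(unlist(s0[, c("median", "p25", "p75", "pct_at_least_one")]),
               c(median = 0, p25 = 0, p75 = 0, pct_at_least_one = 0))

  s1 <- summarize_counts(data.frame(shops = 7), factor("All"))
  expect_equal(unlist(s1[, c("median", "p25", "p75")]),
               c(median = 7, p25 = 7, p75 = 7))

  expect_warning(
    summarize_counts(data.frame(x = 1:3),
                     factor(c("a", "a", "a"), levels = c("a", "b"))),
    "empty group")
})

test_that("crosstab counts schools and reports 1-decimal prevalence", {
  flag <- rep(c(TRUE, FALSE), c(295, 1737 - 295))
  ct <- crosstab(factor(rep("Public", 1737)), flag)
  expect_equal(ct$prevalence, 17.0)
  expect_equal(ct$totals, 1737L)

  # all flagged: 100% everywhere
  ct <- crosstab(factor(c("a", "a", "b")), c(TRUE, TRUE, TRUE))
  expect_equal(ct$prevalence, c(100, 100))

  # order invariance
  set.seed(3)
  strat <- factor(sample(c("x", "y", "z"), 200, replace = TRUE))
  fl <- runif(200) < 0.3
  p <- sample(200)
  expect_equal(crosstab(strat, fl)$cells, crosstab(strat[p], fl[p])$cells)

  expect_error(crosstab(factor(c("a", NA)), c(TRUE, FALSE),
                        ids = c("s1", "s2")),
               "s2")
})

test_that("chi-square is uncorrected Pearson with upper-tail p", {
  # both-flags by school sector from the published Rio counts
  ct <- contingency_table(c("Public", "Private"), c(224, 156), c(1737, 1422))
  res <- chi_square(ct)
  expect_equal(round(res$p_value, 3), 0.098)
  expect_equal(res$df, 1)

  # identical row proportions: statistic 0, p 1
  res0 <- chi_square(rbind(c(10, 90), c(20, 180)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(chi_square(rbind(c(0, 5), c(0, 3))), "degenerate")
})

test_that("chi-square p agrees with a 1e5-replicate multinomial null", {
  set.seed(17)
  tables <- list(rbind(c(8, 5, 4), c(3, 6, 4)),
                 rbind(c(9, 2, 5), c(4, 7, 3)))
  for (m in tables) {
    obs <- chi_square(m)
    p_mc <- multinomial_null_p(m, obs$statistic, reps = 1e5)
    # Monte-Carlo error plus the asymptotic approximation error at n ~ 30
    expect_lt(abs(obs$p_value - p_mc), 0.05)
  }
})

test_that("chi-square is permutation-invariant and scales with cell size", {
  m <- rbind(c(12, 30, 8), c(20, 14, 16))
  base <- chi_square(m)
  expect_equal(chi_square(m[2:1, c(3, 1, 2)])$statistic, base$statistic)
  expect_equal(chi_square(3 * m)$statistic, 3 * base$statistic)
})

test_that("p-values format to 3 decimals with < 0.001 below 0.0005", {
  expect_equal(format_p_value(c(0.0979, 0.000578, 0.0004999, 1)),
               c("0.098", "0.001", "< 0.001", "1.000"))
})

test_that("the pipeline reproduces every published prevalence and p-value", {
  counts <- rio_reference_counts()
  flags <- c(desert = "n_desert", swamp = "n_swamp", both = "n_both")
  # printed prevalences, 1 decimal, in file row order
  printed <- list(
    n_desert = c(17.0, 12.6, 34.5, 9.2, 8.7, 32.7, 11.6, 10.7, 34.1, 12.6, 12.0),
    n_swamp = c(95.9, 98.3, 89.6, 99.6, 99.1, 92.8, 97.4, 99.3, 90.3, 97.1, 98.8),
    n_both = c(12.9, 11.0, 24.2, 8.7, 7.8, 25.7, 9.0, 10.1, 24.4, 9.7, 10.9))
  for (fl in names(flags)) {
    got <- unlist(lapply(split(counts, counts$stratum_var)[
      unique(counts$stratum_var)], function(g) {
        counts_to_table(g, flags[[fl]])$prevalence
      }), use.names = FALSE)
    expect_equal(got, printed[[flags[[fl]]]], info = fl)
  }
  # city-wide totals
  tot <- colSums(counts[counts$stratum_var == "sector",
                        c("n_schools", "n_desert", "n_swamp", "n_both")])
  expect_equal(round(100 * tot[-1] / tot[1], 1),
               c(n_desert = 15.0, n_swamp = 97.0, n_both = 12.0))

  # school-level chi-square p-values that the printed table supports
  p_of <- function(var, fl) {
    chi_square(counts_to_table(counts[counts$stratum_var == var, ], fl))$p_value
  }
  expect_equal(format_p_value(p_of("sector", "n_desert")), "0.001")
  expect_equal(format_p_value(p_of("sector", "n_both")), "0.098")
  expect_equal(format_p_value(p_of("sector", "n_swamp")), "< 0.001")
  for (var in c("income_tercile", "deprivation", "segregation")) {
    expect_equal(format_p_value(p_of(var, "n_desert")), "< 0.001")
    expect_equal(format_p_value(p_of(var, "n_both")), "< 0.001")
  }
})

test_that("desert-and-swamp counts nest within desert and swamp counts", {
  counts <- rio_reference_counts()
  expect_true(all(counts$n_both <= pmin(counts$n_desert, counts$n_swamp)))
  # and column sums are conserved across stratifications of the same flag
  sums <- aggregate(cbind(n_schools, n_desert, n_swamp, n_both) ~ stratum_var,
                    counts, sum)
  for (col in c("n_schools", "n_desert", "n_swamp", "n_both")) {
    expect_true(length(unique(sums[[col]])) == 1)
  }
})
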