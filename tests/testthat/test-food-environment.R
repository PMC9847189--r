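test_that("establishments classify into per-neighborhood subcategory counts", {
  reg <- make_registry(c("4722-9/01" = 3, "5611-2/01" = 2))
  counts <- classify_establishments(reg)
  expect_equal(counts$butchery, 3L)
  expect_equal(counts$restaurant, 2L)
  expect_equal(sum(counts[, setdiff(names(counts), "neighborhood_id")]), 5)

  m <- default_category_map()
  cls <- m$macro_class
  healthy <- rowSums(counts[, names(cls)[cls %in% c("in_natura", "mixed")]])
  expect_equal(unname(healthy), 5)

  # empty registry: all-zero counts for every requested neighborhood
  empty <- reg[0, ]
  z <- classify_establishments(empty, neighborhood_ids = c("N001", "N002"))
  expect_equal(nrow(z), 2)
  expect_true(all(z[, -1] == 0))

  expect_error(classify_establishments(rbind(reg, reg)), "duplicate")
})

test_that("classification is order-invariant and unknown codes fall to non_food", {
  set.seed(5)
  codes <- sample(names(default_category_map()$code_prefixes), 1000,
                  replace = TRUE)
  codes[1:25] <- "9999-9/99"
  reg <- data.frame(establishment_id = sprintf("E%04d", 1:1000),
                    neighborhood_id = sample(c("N001", "N002", "N003"), 1000,
                                             replace = TRUE),
                    activity_code = codes, stringsAsFactors = FALSE)
  a <- classify_establishments(reg)
  b <- classify_establishments(reg[sample(1000), ])
  expect_equal(a, b, ignore_attr = TRUE)
  expect_equal(sum(a$non_food), 25)
  expect_equal(attr(a, "n_unknown"), 25L)
})

test_that("the YAML category map round-trips the default taxonomy", {
  path <- system.file("extdata", "category_map.yaml", package = "foodscape")
  m <- read_category_map(path)
  d <- default_category_map()
  expect_equal(m$macro_class[sort(names(m$macro_class))],
               d$macro_class[sort(names(d$macro_class))])
  expect_setequal(m$swamp_subcategories, d$swamp_subcategories)
  expect_setequal(names(m$code_prefixes), names(d$code_prefixes))
})

test_that("category map validation rejects bad taxonomies", {
  d <- default_category_map()
  expect_error(category_map(d$code_prefixes, d$macro_class[-1],
                            d$swamp_subcategories), "cover exactly")
  expect_error(category_map(d$code_prefixes, d$macro_class,
                            c("butchery")), "ultraprocessed or mixed")
})

test_that("desert threshold is the interpolated percentile, strictly below", {
  d <- desert_flags(c(10, 20, 30, 40), 25)
  expect_equal(d$threshold, 17.5)
  expect_equal(d$desert, c(TRUE, FALSE, FALSE, FALSE))

  # ties saturate: all equal densities, no deserts
  d <- desert_flags(rep(30, 6), 25)
  expect_false(any(d$desert))

  # percentile 0: threshold at the minimum, nothing strictly below
  d <- desert_flags(c(5, 8, 2, 9), 0)
  expect_false(any(d$desert))

  expect_error(desert_flags(c(1, 2, 3), 25), "at least 4")
})

test_that("desert prevalence is about 25% under continuous densities", {
  set.seed(31)
  for (n in c(100, 400)) {
    dens <- rlnorm(n, 3, 0.5)
    d <- desert_flags(dens, 25)
    expect_equal(mean(d$desert), 0.25, tolerance = 0.01 + 1 / n)
  }
})

test_that("swamp flag crosses strictly between counts 4 and 5", {
  m <- default_category_map()
  counts <- classify_establishments(
    rbind(make_registry(c("5611-2/03" = 4), "N001"),
          make_registry(c("5611-2/03" = 5), "N002", start_id = 10L),
          make_registry(c("4722-9/01" = 8), "N003", start_id = 30L)),
    m)
  sw <- swamp_flags(counts, m)
  expect_equal(sw$swamp_count, c(4L, 5L, 0L))
  expect_equal(sw$swamp, c(FALSE, TRUE, FALSE))
})

test_that("mRFEI is the healthy share, undefined on empty neighborhoods", {
  expect_equal(mrfei(5, 5), 50)
  expect_equal(mrfei(3, 9), 25)
  expect_true(is.na(mrfei(0, 0)))
  expect_equal(mrfei(c(5, 0, 3), c(5, 0, 9)), c(50, NA, 25))
})

test_that("desert flags are invariant to common scaling of counts and population", {
  set.seed(8)
  pop <- sample(500:2000, 12)
  healthy <- rpois(12, 8)
  f1 <- desert_flags(10000 * healthy / pop)
  f2 <- desert_flags(10000 * (healthy * 3) / (pop * 3))
  expect_equal(f1$desert, f2$desert)
})

test_that("adding establishments moves flags monotonically", {
  set.seed(13)
  m <- default_category_map()
  pop <- stats::setNames(rep(1000L, 8), sprintf("N%03d", 1:8))
  regs <- lapply(1:8, function(i) {
    make_registry(c("4722-9/01" = rpois(1, 3), "5611-2/03" = rpois(1, 5)),
                  sprintf("N%03d", i), start_id = i * 100L)
  })
  reg <- do.call(rbind, regs)
  counts <- classify_establishments(reg, m, names(pop))
  fe1 <- food_env_metrics(counts, pop, m)

  # one extra healthy establishment in a non-desert neighborhood
  target <- which(!fe1$desert)[1]
  counts2 <- counts
  counts2$butchery[target] <- counts2$butchery[target] + 1L
  fe2 <- food_env_metrics(counts2, pop, m)
  expect_false(fe2$desert[target])

  # extra swamp-category establishments never clear existing swamp flags
  counts3 <- counts
  counts3$cafeteria <- counts3$cafeteria + 2L
  fe3 <- food_env_metrics(counts3, pop, m)
  expect_true(all(fe3$swamp[fe1$swamp]))
})
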