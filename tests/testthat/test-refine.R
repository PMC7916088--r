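test_that("the canonical trimodal sodium histogram yields modes 135/405/675 and cuts 270/540", {
  counts <- c(30, 120, 40, 35, 140, 45, 40, 130, 35, 20, 10, 5)
  v <- values_for_counts(counts, lo = 0, hi = 1080)
  d <- detect_modes(v)
  expect_equal(d$breaks, seq(0, 1080, by = 90))
  expect_equal(d$counts, counts)
  expect_equal(which(d$potential), c(2, 5, 8))
  expect_equal(d$modes, c(135, 405, 675))
  expect_equal(d$cuts, c(270, 540))
})

test_that("convexity flags match a direct evaluation of the predicate", {
  withr::with_seed(11, {
    for (i in 1:40) {
      counts <- rpois(12, lambda = sample(c(2, 10, 60), 1))
      counts[1] <- max(counts[1], 1)
      counts[12] <- max(counts[12], 1)
      v <- values_for_counts(counts, lo = 0, hi = 12)
      d <- detect_modes(v)
      expect_equal(d$counts, counts)
      expect_identical(d$potential, oracle_potential_modes(counts))
      expect_equal(length(d$cuts), max(0, length(d$modes) - 1))
      if (length(d$modes) > 1) {
        expect_true(all(diff(d$modes) > 0))
        expect_true(all(d$cuts > head(d$modes, -1) &
                          d$cuts < tail(d$modes, -1)))
      }
    }
  })
})

test_that("adjacent potential-mode bins merge into one mode over their span", {
  # bins 4 and 5 both convex: one mode at the midpoint of their union
  counts <- c(1, 2, 3, 30, 32, 3, 3, 3, 3, 3, 3, 3)
  expect_identical(which(oracle_potential_modes(counts)), c(4L, 5L))
  v <- values_for_counts(counts, lo = 0, hi = 120)
  d <- detect_modes(v)
  expect_equal(which(d$potential), c(4, 5))
  expect_equal(d$modes, (30 + 50) / 2)  # union spans [30, 50)
  expect_length(d$cuts, 0)
})

test_that("degenerate and single-peak inputs are unimodal with no cuts", {
  # convexly decaying histogram: only the first (edge) bin is a mode
  counts <- c(40, 20, 10, 5, 3, 2, 1, 1, 1, 1, 1, 1)
  expect_identical(which(oracle_potential_modes(counts)), 1L)
  d <- detect_modes(values_for_counts(counts, lo = 0, hi = 12))
  expect_length(d$modes, 1)
  expect_length(d$cuts, 0)
  # a single populated bin is the only convex one
  expect_identical(which(oracle_potential_modes(c(0, 10, rep(0, 10)))), 2L)
  same <- detect_modes(rep(3.3, 8))
  expect_equal(same$modes, 3.3)
  expect_length(same$cuts, 0)
  expect_error(detect_modes(numeric(0)), "no values")
})

test_that("anchor_zero reproduces round-number bin edges", {
  v <- values_for_counts(c(2, 10, rep(2, 10)), lo = 0, hi = 1080)
  v <- v[v > 0]  # drop the pinned zero; anchoring restores the 0 edge
  d <- detect_modes(v, anchor_zero = TRUE)
  expect_equal(d$breaks, seq(0, 1080, by = 90))
  expect_equal(d$modes, 135)
})

test_that("category splits form the Cartesian product of per-nutrient intervals", {
  withr::with_seed(5, {
    sodium <- runif(60, 0, 1)
    satfat <- runif(60, 0, 30)
  })
  p <- solid_products(total_sodium = sodium, saturated_fat = satfat)
  # sodium trimodal (2 cuts), sat fat unimodal (no cuts): 1 x 3 = 3
  s3 <- split_category(p, list(total_sodium = c(0.27, 0.54),
                               saturated_fat = numeric(0)))
  expect_equal(dplyr::n_distinct(s3$subcategory), 3)
  expect_equal(attr(s3, "partition")$n_cells, 3)
  # sat fat bimodal (1 cut) and sodium trimodal (2 cuts): 2 x 3 = 6
  s6 <- split_category(p, list(saturated_fat = 15,
                               total_sodium = c(0.27, 0.54)))
  expect_equal(attr(s6, "partition")$n_cells, 6)
  expect_equal(dplyr::n_distinct(s6$subcategory), 6)
  expect_equal(sum(attr(s6, "partition")$sizes$n_products), nrow(p))
})

test_that("interval membership at a cut point is left-closed", {
  p <- solid_products(total_sodium = c(0.300, 0.270, 0.269, 0.540, 0.8))
  s <- split_category(p, list(total_sodium = c(0.270, 0.540)))
  bands <- s$subcategory
  expect_equal(bands[1], bands[2])              # 300 and 270 both "medium"
  expect_false(bands[3] == bands[2])            # 269 is "low"
  expect_match(bands[4], "3/3")                 # exactly at 540: upper group
  expect_equal(bands[4], bands[5])
  # assignment is deterministic and conserves products
  s2 <- split_category(p[sample(5), ], list(total_sodium = c(0.270, 0.540)))
  expect_equal(sort(s2$subcategory), sort(s$subcategory))
})

test_that("planted trimodal mixtures are recovered within one bin width", {
  hits <- 0L
  n_seeds <- 100
  means <- c(0.135, 0.405, 0.675)
  mids <- c(0.27, 0.54)
  for (s in seq_len(n_seeds)) {
    spec <- category_spec("m", "solid", 1000, nutrients = list(
      total_sodium = list(mean = means, sd = c(0.03, 0.035, 0.04))))
    m <- generate_products(spec, seed = s)
    d <- detect_modes(m$total_sodium)
    bw <- diff(d$breaks)[1]
    ok <- length(d$cuts) == 2 &&
      all(abs(d$cuts - mids) <= bw) &&
      all(d$cuts > means[1:2] & d$cuts < means[2:3])
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("fewer bins never yields more modes on the fixture family", {
  for (s in 1:20) {
    spec <- category_spec("m", "solid", 800, nutrients = list(
      total_sodium = list(mean = c(0.135, 0.405, 0.675),
                          sd = c(0.03, 0.035, 0.04))))
    v <- generate_products(spec, seed = s)$total_sodium
    m6 <- length(detect_modes(v, n_bins = 6)$modes)
    m12 <- length(detect_modes(v, n_bins = 12)$modes)
    expect_lte(m6, m12)
  }
})
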