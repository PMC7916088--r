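test_that("a single disqualifying nutrient at x = 50 gives the empirical median", {
  p <- solid_products(total_sodium = (1:40) / 20)
  ts <- derive_thresholds(p, "total_sodium", x = 50, clamp = FALSE)
  expect_equal(ts$threshold, sort(p$total_sodium)[20])
  expect_equal(attr(ts, "p"), 50)
  expect_equal(attr(ts, "coverage"), 0.5)
})

test_that("search matches the exhaustive order-statistic oracle", {
  withr::with_seed(99, {
    combos <- list(
      c("total_sodium"),
      c("saturated_fat", "total_sodium"),
      c("saturated_fat", "protein"),
      c("saturated_fat", "total_sodium", "protein")
    )
    for (rep in 1:8) {
      nutrients <- combos[[sample(length(combos), 1)]]
      n <- sample(20:200, 1)
      x <- sample(c(5, 15, 33, 50, 80, 97), 1)
      vals <- list(
        saturated_fat = rlnorm(n, log(10), 0.6),
        total_sodium = rlnorm(n, log(0.6), 0.5),
        protein = rlnorm(n, log(9), 0.4)
      )
      p <- do.call(solid_products, vals[nutrients])
      ts <- derive_thresholds(p, nutrients, x, clamp = FALSE)
      mat <- as.matrix(p[nutrients])
      oracle <- oracle_min_level(mat, nutrient_direction(nutrients), x)
      expect_equal(attr(ts, "p"), oracle$p)
      expect_equal(ts$threshold, oracle$cuts)
      expect_equal(attr(ts, "coverage"), oracle$coverage)
      # coverage count exactness and grid minimality
      n_comply <- sum(complies(p, ts))
      expect_gte(n_comply, ceiling(x / 100 * n))
      if (oracle$k > 1) {
        # one grid step down, coverage must fall below the target
        k1 <- oracle$k - 1
        dirs <- nutrient_direction(nutrients)
        prev_cuts <- sapply(seq_along(nutrients), function(j) {
          s <- sort(mat[, j])
          s[if (dirs[j] == "disqualifying") k1 else max(1, n - k1)]
        })
        below <- mean(complies(p, tibble::tibble(
          nutrient = nutrients, direction = dirs, threshold = prev_cuts)))
        expect_lt(below, x / 100)
      }
    }
  })
})

test_that("two independent uniforms at x = 50 need roughly the 70.7th percentile", {
  withr::with_seed(123, {
    n <- 20000
    p <- solid_products(saturated_fat = runif(n), total_sodium = runif(n))
  })
  ts <- derive_thresholds(p, c("saturated_fat", "total_sodium"), x = 50,
                          clamp = FALSE)
  expect_equal(attr(ts, "p"), 100 * sqrt(0.5), tolerance = 0.01)
})

test_that("thresholds tighten monotonically as the target shrinks", {
  withr::with_seed(17, {
    p <- solid_products(saturated_fat = rlnorm(150, log(8), 0.5),
                        total_sodium = rlnorm(150, log(0.5), 0.6),
                        protein = rlnorm(150, log(10), 0.4))
  })
  nutrients <- c("saturated_fat", "total_sodium", "protein")
  fam <- threshold_family(p, nutrients, x = c(5, 15, 30, 50, 70, 90, 100),
                          clamp = FALSE)
  for (i in seq_len(length(fam) - 1)) {
    a <- fam[[i]]; b <- fam[[i + 1]]   # a: smaller x, stricter
    disq <- a$direction == "disqualifying"
    expect_true(all(a$threshold[disq] <= b$threshold[disq]))
    expect_true(all(a$threshold[!disq] >= b$threshold[!disq]))
  }
})

test_that("1-D thresholds equal the nearest-rank quantile for every x", {
  withr::with_seed(31, v <- rlnorm(73, log(0.5), 0.7))
  p <- solid_products(total_sodium = v)
  s <- sort(v)
  for (x in c(1, 7, 25, 50, 64, 99, 100)) {
    ts <- derive_thresholds(p, "total_sodium", x, clamp = FALSE)
    expect_equal(ts$threshold, s[ceiling(x / 100 * 73)])
  }
})

test_that("clamping raises thresholds below the claim limit and reruns", {
  # identity when nothing crosses a limit
  withr::with_seed(8, {
    p <- solid_products(saturated_fat = rlnorm(60, log(10), 0.4),
                        total_sodium = rlnorm(60, log(0.6), 0.4))
  })
  unclamped <- derive_thresholds(p, c("saturated_fat", "total_sodium"), 50,
                                 clamp = FALSE)
  clamped <- derive_thresholds(p, c("saturated_fat", "total_sodium"), 50)
  expect_equal(clamped$threshold, unclamped$threshold)
  expect_false(any(clamped$clamped))

  # sodium mostly below its low-in limit: target would undercut the limit,
  # so it is set to 0.120 and the level re-searched on saturated fat alone
  withr::with_seed(9, {
    q <- solid_products(saturated_fat = rlnorm(80, log(10), 0.5),
                        total_sodium = rlnorm(80, log(0.03), 0.4))
  })
  ts <- derive_thresholds(q, c("saturated_fat", "total_sodium"), x = 50)
  expect_true(ts$clamped[ts$nutrient == "total_sodium"])
  expect_equal(ts$threshold[ts$nutrient == "total_sodium"], 0.120)
  expect_gte(attr(ts, "coverage"), 0.5)
  # equals the oracle with the sodium coordinate fixed at the limit
  oracle <- oracle_min_level(as.matrix(q[c("saturated_fat", "total_sodium")]),
                             c("disqualifying", "disqualifying"), 50,
                             fixed = list(total_sodium = 0.120))
  expect_equal(ts$threshold[ts$nutrient == "saturated_fat"], oracle$cuts)
  expect_equal(attr(ts, "p"), oracle$p)
})

test_that("qualifying clamp follows the raise-to-limit rule, switchable to cap", {
  # protein threshold below the 5.0 source-of limit gets raised (stricter)
  withr::with_seed(10, {
    p <- solid_products(saturated_fat = rlnorm(100, log(10), 0.4),
                        protein = rlnorm(100, log(4), 0.3))
  })
  raised <- derive_thresholds(p, c("saturated_fat", "protein"), x = 30)
  expect_true(raised$clamped[raised$nutrient == "protein"])
  expect_equal(raised$threshold[raised$nutrient == "protein"], 5.0)
  capped <- derive_thresholds(p, c("saturated_fat", "protein"), x = 30,
                              qualifying_clamp = "cap")
  expect_false(capped$clamped[capped$nutrient == "protein"])
  # under "cap", a derived protein threshold above 5.0 is lowered to 5.0
  withr::with_seed(12, {
    q <- solid_products(saturated_fat = rlnorm(100, log(10), 0.4),
                        protein = rlnorm(100, log(12), 0.3))
  })
  ts <- derive_thresholds(q, c("saturated_fat", "protein"), x = 10,
                          qualifying_clamp = "cap")
  if (any(ts$clamped)) {
    expect_equal(ts$threshold[ts$nutrient == "protein"], 5.0)
  }
})

test_that("an all-clamped set reports achieved coverage with a flag", {
  withr::with_seed(13, {
    p <- solid_products(total_sodium = rlnorm(50, log(0.02), 0.3),
                        saturated_fat = rlnorm(50, log(0.2), 0.3))
  })
  ts <- derive_thresholds(p, c("saturated_fat", "total_sodium"), x = 50)
  expect_true(all(ts$clamped))
  expect_true(is.na(attr(ts, "p")))
  expect_equal(attr(ts, "coverage"),
               mean(p$saturated_fat <= 1.50 & p$total_sodium <= 0.120))
})

test_that("small categories are refused", {
  p <- solid_products(total_sodium = runif(10))
  expect_error(derive_thresholds(p, "total_sodium", 50), "fewer than")
  expect_s3_class(derive_thresholds(p, "total_sodium", 50, min_n = 5,
                                    clamp = FALSE),
                  "threshold_set")
})

test_that("threshold reports render signed integer relative changes", {
  expect_equal(relative_change_pct(560, 412), -26L)
  expect_equal(relative_change_pct(5.0, 4.0), -20L)
  expect_equal(relative_change_pct(7.6, 9.3), 22L)
  expect_equal(relative_change_pct(10, 10), 0L)
  expect_true(is.na(relative_change_pct(0, 5)))
  ts1 <- derive_thresholds(solid_products(total_sodium = (1:40) / 20),
                           "total_sodium", 50, clamp = FALSE)
  ts2 <- derive_thresholds(solid_products(total_sodium = (1:40) / 20),
                           "total_sodium", 15, clamp = FALSE)
  rep <- threshold_report(ts1, ts2)
  expect_equal(rep$rel_change_pct, -70L)
  expect_match(rep$label, "^-70%$")
})
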