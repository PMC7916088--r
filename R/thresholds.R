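# Nearest-rank empirical percentile: the ceil(p/100 * n)-th order statistic,
# so thresholds are always observed values. p = 0 maps to the minimum. The
# rounding guard keeps p-values that are exact multiples of 100/n (the whole
# search grid) from spilling into the next rank through floating point.
nearest_rank <- function(sorted, p) {
  n <- length(sorted)
  sorted[max(1L, ceiling(p / 100 * n - 1e-9))]
}

# Per-nutrient cut at grid level k of n (common percentile p = 100 k / n):
# a disqualifying nutrient is cut at its p-th percentile, the k-th order
# statistic (compliance <=); a qualifying nutrient at its (100-p)-th
# percentile, the (n-k)-th order statistic (compliance >=), mirroring the
# disqualifying construction.
cuts_at_rank <- function(sorted_list, directions, k) {
  vapply(seq_along(sorted_list), function(j) {
    n <- length(sorted_list[[j]])
    if (directions[j] == "disqualifying") {
      sorted_list[[j]][k]
    } else {
      sorted_list[[j]][max(1L, n - k)]
    }
  }, numeric(1))
}

joint_ok <- function(mat, directions, cuts, base_ok) {
  ok <- base_ok
  for (j in seq_along(cuts)) {
    ok <- ok & if (directions[j] == "disqualifying") {
      mat[, j] <= cuts[j]
    } else {
      mat[, j] >= cuts[j]
    }
  }
  ok
}

# Minimal common percentile search over the grid of attainable levels
# p_k = 100 k / n, k = 1..n. Joint coverage is a nondecreasing step function
# of k (disqualifying cuts loosen, qualifying cuts loosen), so binary search
# over k is exact. `base_ok` carries compliance with already-fixed (clamped)
# thresholds. Returns k = n with a shortfall flag if even the loosest level
# cannot reach the target.
search_min_level <- function(mat, directions, x, base_ok = NULL) {
  n <- nrow(mat)
  if (is.null(base_ok)) base_ok <- rep(TRUE, n)
  sorted <- lapply(seq_len(ncol(mat)), function(j) sort(mat[, j]))
  target <- x / 100
  cov_at <- function(k) {
    cuts <- cuts_at_rank(sorted, directions, k)
    mean(joint_ok(mat, directions, cuts, base_ok))
  }
  if (cov_at(n) < target - 1e-12) {
    k <- n
    shortfall <- TRUE
  } else {
    lo <- 1L
    hi <- n
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (cov_at(mid) >= target - 1e-12) hi <- mid else lo <- mid + 1L
    }
    k <- lo
    shortfall <- FALSE
  }
  p <- 100 * k / n
  cuts <- cuts_at_rank(sorted, directions, k)
  list(p = p, k = k, cuts = cuts,
       coverage = mean(joint_ok(mat, directions, cuts, base_ok)),
       shortfall = shortfall)
}

#' Derive joint "best x%" nutrient thresholds for a category
#'
#' Finds the minimal common percentile level `p` such that the per-nutrient
#' cuts taken simultaneously — the empirical `p`-th percentile of each
#' disqualifying nutrient (compliance `<=`) and the `(100 - p)`-th
#' percentile of each qualifying nutrient (compliance `>=`) — are met by at
#' least a fraction `x`% of the category's products *jointly*. Percentiles
#' use the nearest-rank convention, so every threshold is an observed
#' value; `p` is searched over the attainable grid of order-statistic
#' levels by exact bisection (coverage is a monotone step function of `p`).
#'
#' With `clamp = TRUE` (default), any derived threshold below its claim
#' limit is set to that limit — a reformulation target should not demand
#' less than the "low in" level of a disqualifying nutrient, and a
#' qualifying target below the "source of" level is raised to the
#' claimable minimum. Clamped nutrients become fixed constraints and the
#' level `p` is re-searched over the remaining nutrients so joint coverage
#' still meets `x`; this repeats until no new nutrient is clamped. If every
#' nutrient ends up clamped (or a raised qualifying clamp caps attainable
#' coverage below `x`), the achieved coverage is reported with a shortfall
#' flag instead. `qualifying_clamp = "cap"` selects the alternative
#' convention in which a qualifying threshold *above* the source-of limit
#' is lowered to it (never strict beyond the claimable level), mirroring
#' the disqualifying rule.
#'
#' @param products A single (sub-)category's product tibble; every product
#'   must declare all `nutrients` (see [analyzable_subset()]).
#' @param nutrients Character vector of category-relevant nutrient ids.
#' @param x Target top fraction, percent (0 < x <= 100).
#' @param min_n Minimum category size below which threshold derivation is
#'   refused (order-statistic thresholds are too unstable to publish from
#'   small categories).
#' @param clamp Apply claim-limit clamping and re-run.
#' @param limits Claim-limit table, see [claim_limits()].
#' @param qualifying_clamp `"raise"` (default): a qualifying threshold
#'   below its source-of limit is raised to the limit; `"cap"`: a
#'   qualifying threshold above the limit is lowered to it.
#' @return A `threshold_set`: a tibble of per-nutrient rows (`nutrient`,
#'   `direction`, `threshold`, `clamped`) with attributes `x`, `p` (common
#'   percentile level, `NA` if all nutrients clamped), `coverage` (achieved
#'   joint fraction), `n`, and `coverage_shortfall`.
#' @export
#' @examples
#' p <- tibble::tibble(basis = "solid", total_sodium = (1:40) / 20)
#' derive_thresholds(p, "total_sodium", x = 50)
derive_thresholds <- function(products, nutrients, x, min_n = 20,
                              clamp = TRUE, limits = claim_limits(),
                              qualifying_clamp = c("raise", "cap")) {
  qualifying_clamp <- match.arg(qualifying_clamp)
  check_nutrient(nutrients)
  stopifnot(length(nutrients) >= 1, x > 0, x <= 100)
  n <- nrow(products)
  if (n < min_n) {
    stop("category has ", n, " products, fewer than the minimum of ", min_n,
         " required for stable thresholds", call. = FALSE)
  }
  mat <- as.matrix(products[nutrients])
  if (anyNA(mat)) {
    stop("all products must declare every relevant nutrient; ",
         "use analyzable_subset() first", call. = FALSE)
  }
  directions <- nutrient_direction(nutrients)
  basis <- unique(products$basis)
  if (clamp && length(basis) != 1) {
    stop("clamping needs a single declaration basis per category",
         call. = FALSE)
  }

  fixed <- rep(NA_real_, length(nutrients))
  names(fixed) <- nutrients
  res <- NULL
  repeat {
    free <- is.na(fixed)
    base_ok <- if (all(free)) {
      rep(TRUE, n)
    } else {
      joint_ok(mat[, !free, drop = FALSE], directions[!free],
               fixed[!free], rep(TRUE, n))
    }
    if (!any(free)) {
      res <- list(p = NA_real_, cuts = numeric(0), coverage = mean(base_ok),
                  shortfall = mean(base_ok) < x / 100 - 1e-12)
      break
    }
    res <- search_min_level(mat[, free, drop = FALSE], directions[free],
                            x, base_ok)
    if (!clamp) break
    thr <- res$cuts
    newly <- logical(sum(free))
    for (j in seq_along(thr)) {
      nut <- nutrients[free][j]
      lim <- claim_limit(nut, basis, limits)
      newly[j] <- if (directions[free][j] == "disqualifying") {
        thr[j] < lim
      } else if (qualifying_clamp == "raise") {
        thr[j] < lim
      } else {
        thr[j] > lim
      }
      if (newly[j]) fixed[nut] <- lim
    }
    if (!any(newly)) break
  }

  thresholds <- fixed
  thresholds[is.na(fixed)] <- res$cuts
  new_threshold_set(
    tibble::tibble(
      nutrient = nutrients,
      direction = directions,
      threshold = unname(thresholds),
      clamped = !is.na(fixed)
    ),
    x = x, p = res$p, coverage = res$coverage, n = n,
    coverage_shortfall = res$shortfall
  )
}

#' Threshold families over a grid of target fractions
#'
#' Computes one [derive_thresholds()] result per target fraction, typically
#' the integer grid `x = 1..100` used for product scoring. Thresholds for a
#' smaller `x` are nutrient-wise at least as strict as for a larger `x`.
#'
#' @inheritParams derive_thresholds
#' @param x Numeric vector of target fractions (percent).
#' @return A named list of `threshold_set` objects, names `as.character(x)`.
#' @export
threshold_family <- function(products, nutrients, x = 1:100, min_n = 20,
                             clamp = TRUE, limits = claim_limits(),
                             qualifying_clamp = c("raise", "cap")) {
  qualifying_clamp <- match.arg(qualifying_clamp)
  fam <- lapply(x, function(xi) {
    derive_thresholds(products, nutrients, xi, min_n = min_n, clamp = clamp,
                      limits = limits, qualifying_clamp = qualifying_clamp)
  })
  names(fam) <- as.character(x)
  fam
}

#' Compare thresholds at two target fractions
#'
#' Reports, per nutrient, the relative change needed to move from the
#' `x1`% thresholds to the (stricter) `x2`% thresholds, as a signed integer
#' percent (rounded half away from zero). A zero-valued baseline threshold
#' has no defined relative change and is rendered `"n/a"`.
#'
#' @param ts1,ts2 `threshold_set` objects for the same sub-category at two
#'   target fractions (e.g. 50 and 15).
#' @return A tibble: `nutrient`, `direction`, `threshold_1`, `threshold_2`,
#'   `rel_change_pct` (integer, `NA` when undefined) and `label` (e.g.
#'   `"412 (-26%)"` style signed-percent rendering).
#' @export
threshold_report <- function(ts1, ts2) {
  stopifnot(identical(ts1$nutrient, ts2$nutrient))
  rel <- relative_change_pct(ts1$threshold, ts2$threshold)
  tibble::tibble(
    nutrient = ts1$nutrient,
    direction = ts1$direction,
    threshold_1 = ts1$threshold,
    threshold_2 = ts2$threshold,
    rel_change_pct = rel,
    label = ifelse(is.na(rel), "n/a",
                   sprintf("%+d%%", rel))
  )
}

#' @rdname threshold_report
#' @param from,to Numeric baseline and new threshold values.
#' @return `relative_change_pct()`: integer percent change
#'   `(to - from) / from * 100`, rounded half away from zero; `NA` for a
#'   zero baseline.
#' @export
relative_change_pct <- function(from, to) {
  raw <- ifelse(from == 0, NA_real_, (to - from) / from * 100)
  as.integer(sign(raw) * floor(abs(raw) + 0.5))
}
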