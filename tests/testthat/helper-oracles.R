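# Independent brute-force oracles and small fixture builders. These are kept
# deliberately naive (explicit loops, no code shared with the package
# internals) so they can stand as references for the fast implementations.

# Build a value vector whose 12-bin histogram over [lo, hi] has exactly the
# given counts: points at bin midpoints, with one point pinned to each range
# end so detect_modes()'s [min, max] convention reproduces the intended bins.
values_for_counts <- function(counts, lo = 0, hi = length(counts) * 90) {
  stopifnot(counts[1] >= 1, counts[length(counts)] >= 1)
  width <- (hi - lo) / length(counts)
  mids <- lo + (seq_along(counts) - 0.5) * width
  v <- rep(mids, counts)
  v[1] <- lo
  v[length(v)] <- hi
  v
}

# Direct evaluation of the convexity predicate over all bins.
oracle_potential_modes <- function(counts) {
  nb <- length(counts)
  flags <- logical(nb)
  for (i in seq_len(nb)) {
    flags[i] <- if (i == 1) {
      counts[1] > counts[2]
    } else if (i == nb) {
      counts[nb] > counts[nb - 1]
    } else {
      counts[i] > (counts[i - 1] + counts[i + 1]) / 2
    }
  }
  flags
}

# Exhaustive scan over all order-statistic levels k = 1..n for the minimal
# common percentile: nearest-rank cuts, inclusive joint compliance.
oracle_min_level <- function(mat, directions, x, fixed = NULL) {
  n <- nrow(mat)
  base <- rep(TRUE, n)
  if (!is.null(fixed)) {
    for (nm in names(fixed)) {
      j <- match(nm, colnames(mat))
      base <- base & if (directions[j] == "disqualifying") {
        mat[, j] <= fixed[[nm]]
      } else {
        mat[, j] >= fixed[[nm]]
      }
    }
  }
  free <- if (is.null(fixed)) seq_len(ncol(mat)) else
    which(!colnames(mat) %in% names(fixed))
  for (k in 1:n) {
    p <- 100 * k / n
    cuts <- numeric(length(free))
    ok <- base
    for (jj in seq_along(free)) {
      j <- free[jj]
      s <- sort(mat[, j])
      # nearest-rank indices at p = 100 k / n, kept in exact integers:
      # ceil(p n / 100) = k and ceil((100 - p) n / 100) = n - k
      idx <- if (directions[j] == "disqualifying") k else max(1, n - k)
      cuts[jj] <- s[idx]
      ok <- ok & if (directions[j] == "disqualifying") {
        mat[, j] <= cuts[jj]
      } else {
        mat[, j] >= cuts[jj]
      }
    }
    if (mean(ok) >= x / 100) {
      return(list(k = k, p = p, cuts = cuts, coverage = mean(ok)))
    }
  }
  list(k = n, p = 100, cuts = cuts, coverage = mean(ok))
}

# A bare single-category product table on a solid basis.
solid_products <- function(...) {
  vals <- list(...)
  n <- length(vals[[1]])
  out <- tibble::tibble(
    product_id = sprintf("T%03d", seq_len(n)),
    category = "test", basis = "solid",
    saturated_fat = NA_real_, total_sugars = NA_real_,
    total_sodium = NA_real_, protein = NA_real_, fiber = NA_real_
  )
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}
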