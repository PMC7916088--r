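new_threshold_set <- function(thresholds, x, p, coverage, n,
                              coverage_shortfall = FALSE) {
  stopifnot(is.data.frame(thresholds),
            all(c("nutrient", "direction", "threshold", "clamped") %in%
                  names(thresholds)))
  structure(
    tibble::as_tibble(thresholds),
    x = x, p = p, coverage = coverage, n = n,
    coverage_shortfall = coverage_shortfall,
    class = c("threshold_set", class(tibble::tibble()))
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> target top %g%% | common percentile p = %s | coverage %.1f%% of n = %d%s\n",
    attr(x, "x"),
    if (is.na(attr(x, "p"))) "n/a (all clamped)" else sprintf("%.4g", attr(x, "p")),
    100 * attr(x, "coverage"), attr(x, "n"),
    if (isTRUE(attr(x, "coverage_shortfall"))) " [coverage shortfall]" else ""
  ))
  print(tibble::as_tibble(unclass_ts(x)))
  invisible(x)
}

unclass_ts <- function(x) {
  attr(x, "x") <- NULL; attr(x, "p") <- NULL; attr(x, "coverage") <- NULL
  attr(x, "n") <- NULL; attr(x, "coverage_shortfall") <- NULL
  class(x) <- setdiff(class(x), "threshold_set")
  x
}

#' Tidy and summarize threshold sets
#'
#' `tidy()` returns the per-nutrient rows (threshold, compliance direction,
#' clamped flag); `glance()` returns a one-row summary with the target
#' fraction `x`, the common percentile level `p`, the achieved joint
#' coverage, and the number of products the set was derived from.
#'
#' @param x A `threshold_set` from [derive_thresholds()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.threshold_set <- function(x, ...) {
  out <- tibble::as_tibble(unclass_ts(x))
  out$compliance <- ifelse(out$direction == "disqualifying", "<=", ">=")
  out
}

#' @rdname tidy.threshold_set
#' @exportS3Method generics::glance
glance.threshold_set <- function(x, ...) {
  ts <- x
  tibble::tibble(
    x = attr(ts, "x"),
    p = attr(ts, "p"),
    coverage = attr(ts, "coverage"),
    n = attr(ts, "n"),
    n_nutrients = nrow(ts),
    n_clamped = sum(ts$clamped),
    coverage_shortfall = attr(ts, "coverage_shortfall")
  )
}

#' Does a product comply with a set of nutrient thresholds?
#'
#' A product complies when every disqualifying nutrient (saturated fat, total
#' sugars, total sodium) is at or below its threshold and every qualifying
#' nutrient (protein, fiber) is at or above its threshold. Comparisons are
#' inclusive: a product sitting exactly on every threshold complies. A
#' product missing a declared value for any nutrient in the set is not
#' assessable and yields `NA` rather than `FALSE`.
#'
#' @param products A product tibble (see [read_products()] for the column
#'   contract); only the nutrient columns named in `thresholds` are used.
#' @param thresholds A `threshold_set` (from [derive_thresholds()]) or a data
#'   frame with columns `nutrient`, `direction`, `threshold`.
#' @return A logical vector, one element per product row: `TRUE`, `FALSE`,
#'   or `NA` (not assessable).
#' @export
#' @examples
#' ts <- tibble::tibble(nutrient = "total_sodium",
#'                      direction = "disqualifying", threshold = 0.5)
#' complies(tibble::tibble(total_sodium = c(0.4, 0.5, 0.6, NA)), ts)
complies <- function(products, thresholds) {
  stopifnot(is.data.frame(products), is.data.frame(thresholds))
  ok <- rep(TRUE, nrow(products))
  assessable <- rep(TRUE, nrow(products))
  for (i in seq_len(nrow(thresholds))) {
    nut <- thresholds$nutrient[i]
    if (!nut %in% names(products)) {
      stop("products table lacks a column for nutrient '", nut, "'",
           call. = FALSE)
    }
    v <- products[[nut]]
    assessable <- assessable & !is.na(v)
    cmp <- if (thresholds$direction[i] == "disqualifying") {
      v <= thresholds$threshold[i]
    } else {
      v >= thresholds$threshold[i]
    }
    ok <- ok & cmp
  }
  # a product missing any thresholded nutrient is not assessable, even if an
  # already-declared nutrient fails: NA, never FALSE
  ok[!assessable] <- NA
  ok
}
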