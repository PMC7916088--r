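#' Detect major modes of a nutrient distribution by histogram convexity
#'
#' Deliberately less sensitive than formal modality tests, the detector
#' bins the values into a histogram with exactly `n_bins` equal-width bins
#' and flags a bin as a *potential mode* when it is locally convex: it
#' counts strictly more products than the average of its two neighbour
#' bins. An edge bin, having one neighbour, is a potential mode when it
#' counts strictly more than that neighbour. An isolated potential-mode
#' bin places a mode at its midpoint; a run of consecutive potential-mode
#' bins places a single mode at the midpoint of the run's full span.
#' Split cut points are the means of consecutive mode locations.
#'
#' The histogram spans `[min, max]` of the values by default; bins are
#' half-open `[lo, hi)` with the last bin closed. `anchor_zero = TRUE`
#' anchors the range at 0 instead, which reproduces round-number bin edges
#' (e.g. 0, 90, 180, ... mg) when the data maximum is a round multiple of
#' the bin count. Fewer bins means lower sensitivity and, in practice,
#' fewer modes; `n_bins` is the method's single tuning knob.
#'
#' @param values Numeric vector of declared nutrient contents (`NA`
#'   dropped). All-identical values are unimodal by definition.
#' @param n_bins Number of histogram bins (default 12).
#' @param anchor_zero Anchor the histogram range at zero instead of
#'   `min(values)`.
#' @return A `mode_detection` object: a list with `breaks` (bin edges),
#'   `counts`, `potential` (per-bin convexity flags), `modes` (locations,
#'   strictly increasing), `cuts` (split points, one fewer than modes),
#'   `n_bins` and `n` (values used). Methods: [tidy.mode_detection()],
#'   [glance.mode_detection()], [autoplot.mode_detection()], `print`.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(100, 135, 25), rnorm(100, 405, 25), rnorm(100, 675, 25))
#' d <- detect_modes(v)
#' d$modes
#' d$cuts
detect_modes <- function(values, n_bins = 12, anchor_zero = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("no values to analyse", call. = FALSE)
  stopifnot(n_bins >= 3)
  lo <- if (anchor_zero) 0 else min(values)
  hi <- max(values)
  if (hi <= lo) {
    # all values identical (or at the zero anchor): unimodal by definition
    out <- list(breaks = c(lo, hi), counts = length(values),
                potential = TRUE, modes = hi, cuts = numeric(0),
                n_bins = n_bins, n = length(values), degenerate = TRUE)
    class(out) <- "mode_detection"
    return(out)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  potential <- logical(n_bins)
  potential[1] <- counts[1] > counts[2]
  potential[n_bins] <- counts[n_bins] > counts[n_bins - 1]
  inner <- 2:(n_bins - 1)
  potential[inner] <- counts[inner] >
    (counts[inner - 1] + counts[inner + 1]) / 2
  runs <- rle(potential)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  modes <- (breaks[starts[runs$values]] + breaks[ends[runs$values] + 1]) / 2
  cuts <- if (length(modes) >= 2) {
    (modes[-1] + modes[-length(modes)]) / 2
  } else {
    numeric(0)
  }
  out <- list(breaks = breaks, counts = counts, potential = potential,
              modes = modes, cuts = cuts, n_bins = n_bins,
              n = length(values), degenerate = FALSE)
  class(out) <- "mode_detection"
  out
}

#' @export
print.mode_detection <- function(x, ...) {
  cat(sprintf("<mode_detection> %d values, %d bins; %d mode(s)",
              x$n, x$n_bins, length(x$modes)))
  if (length(x$modes) > 0) {
    cat(" at ", paste(signif(x$modes, 4), collapse = ", "), sep = "")
  }
  if (length(x$cuts) > 0) {
    cat("; cuts at ", paste(signif(x$cuts, 4), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Tidy a mode detection
#'
#' `tidy()` returns one row per histogram bin; `glance()` a one-row
#' summary.
#'
#' @param x A `mode_detection` from [detect_modes()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.mode_detection <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    return(tibble::tibble(bin = 1L, lower = x$breaks[1], upper = x$breaks[2],
                          count = x$counts, potential_mode = TRUE))
  }
  tibble::tibble(
    bin = seq_len(x$n_bins),
    lower = x$breaks[-length(x$breaks)],
    upper = x$breaks[-1],
    count = x$counts,
    potential_mode = x$potential
  )
}

#' @rdname tidy.mode_detection
#' @exportS3Method generics::glance
glance.mode_detection <- function(x, ...) {
  tibble::tibble(n = x$n, n_bins = x$n_bins, n_modes = length(x$modes),
                 n_cuts = length(x$cuts),
                 bin_width = if (isTRUE(x$degenerate)) 0 else diff(x$breaks)[1])
}

#' Plot a mode detection
#'
#' Histogram with potential-mode bins highlighted, mode locations (solid)
#' and split cut points (dashed).
#'
#' @param object A `mode_detection`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mode_detection <- function(object, ...) {
  bins <- tidy(object)
  ggplot2::ggplot(bins) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$lower, xmax = .data$upper, ymin = 0, ymax = .data$count,
      fill = .data$potential_mode), colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$modes, linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$cuts, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey80"),
                               name = "potential mode") +
    ggplot2::labs(x = "declared content", y = "products") +
    ggplot2::theme_minimal()
}

#' Split a category into nutritionally homogeneous sub-categories
#'
#' Each relevant nutrient with a multimodal distribution contributes its
#' cut points; the final sub-categories are the Cartesian product of the
#' per-nutrient intervals, and each product is assigned by its declared
#' values. Interval membership is left-closed: a product exactly at a cut
#' point belongs to the upper interval. Cells of the grid with no products
#' are counted in the report but produce no output rows.
#'
#' @param products A single category's analyzable product tibble (all
#'   products declare every nutrient in `detections`).
#' @param detections Named list, nutrient id -> `mode_detection` (or a bare
#'   numeric vector of cut points).
#' @return The tibble with an added `subcategory` column; attribute
#'   `partition` holds a summary list: per-nutrient cuts, the theoretical
#'   number of cells (the product of per-nutrient interval counts), the
#'   number of populated cells, and per-subcategory sizes.
#' @export
split_category <- function(products, detections) {
  stopifnot(length(detections) == 0 || !is.null(names(detections)))
  check_nutrient(names(detections))
  cuts <- lapply(detections, function(d) {
    if (inherits(d, "mode_detection")) d$cuts else as.numeric(d)
  })
  base_label <- if ("initial_category" %in% names(products) &&
                    nrow(products) > 0) {
    products$initial_category[1]
  } else if ("category" %in% names(products) && nrow(products) > 0) {
    products$category[1]
  } else {
    "category"
  }
  label <- rep(base_label, nrow(products))
  n_intervals <- integer(0)
  for (nut in names(cuts)) {
    k <- length(cuts[[nut]]) + 1L
    n_intervals[nut] <- k
    if (k == 1L) next
    # left-closed intervals: value == cut goes to the upper interval
    band <- findInterval(products[[nut]], cuts[[nut]]) + 1L
    label <- paste0(label, " | ", nut, " ", band, "/", k)
  }
  products$subcategory <- label
  sizes <- dplyr::count(products, .data$subcategory, name = "n_products")
  partition <- list(
    category = base_label,
    cuts = cuts,
    n_cells = prod(n_intervals),
    n_populated = nrow(sizes),
    sizes = sizes
  )
  attr(products, "partition") <- partition
  products
}
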