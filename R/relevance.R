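#' Identify category-relevant nutrients
#'
#' A nutrient is relevant to a category when more than half of the
#' category's products have a declared content strictly exceeding the
#' nutrient's claim limit — the "low in" limit for disqualifying nutrients,
#' the "source of" limit for qualifying ones. The denominator is all
#' products in the category: a missing declaration counts as
#' non-exceeding, and a product exactly at the limit is claimable
#' ("low in" / "source of"), hence not evidence of relevance. A category
#' in which no nutrient is relevant cannot be rated.
#'
#' @param products A product tibble; each category must have a single
#'   resolved basis (`solid` or `liquid`). With `by = NULL` the whole table
#'   is treated as one category.
#' @param limits A claim-limit table from [claim_limits()].
#' @param by Name of the column defining categories (default
#'   `"initial_category"` if present, else all rows as one category).
#' @return A tibble with one row per category x nutrient: `n` products,
#'   `n_exceeding` the claim limit, `exceed_fraction`, and the logical
#'   `relevant`.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   product_id = as.character(1:4), category = "spread", basis = "solid",
#'   saturated_fat = c(10, 20, 15, 1.2), total_sugars = c(1, 2, 1, 1),
#'   total_sodium = c(0.5, 0.6, 0.1, 0.7), protein = c(1, 2, NA, 1),
#'   fiber = c(NA, NA, 0.5, 0.2))
#' nutrient_relevance(p)
nutrient_relevance <- function(products, limits = claim_limits(), by = NULL) {
  if (is.null(by)) {
    by <- if ("initial_category" %in% names(products)) "initial_category" else NULL
  }
  if (is.null(by)) {
    products$.cat <- "all"
    by <- ".cat"
  }
  if (nrow(products) == 0) stop("empty product table", call. = FALSE)
  long <- tidyr::pivot_longer(
    products[c(by, "basis", nutrient_ids())],
    cols = dplyr::all_of(nutrient_ids()),
    names_to = "nutrient", values_to = "value"
  )
  long <- dplyr::left_join(long, limits[c("nutrient", "basis", "limit")],
                           by = c("nutrient", "basis"))
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "nutrient")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_exceeding = sum(!is.na(.data$value) & .data$value > .data$limit),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      exceed_fraction = .data$n_exceeding / .data$n,
      relevant = .data$n_exceeding > 0.5 * .data$n
    )
  names(out)[1] <- if (by == ".cat") "category" else by
  out
}

#' @rdname nutrient_relevance
#' @return `relevant_nutrients()`: the character vector of relevant
#'   nutrient identifiers for a single-category table, in canonical order.
#' @export
relevant_nutrients <- function(products, limits = claim_limits()) {
  rel <- nutrient_relevance(products, limits = limits, by = NULL)
  cats <- unique(rel[[1]])
  if (length(cats) > 1) {
    stop("relevant_nutrients() expects a single category; got ",
         length(cats), " — use nutrient_relevance() for grouped tables",
         call. = FALSE)
  }
  intersect(nutrient_ids(), rel$nutrient[rel$relevant])
}

#' Select the analyzable subset of a category
#'
#' Keeps exactly the products with declared values for *all* the
#' category-relevant nutrients; missingness in irrelevant nutrients is
#' ignored. This is the subset on which modes, thresholds and scores are
#' computed.
#'
#' @param products A single category's product tibble.
#' @param relevant Character vector of relevant nutrients (non-empty; an
#'   empty set means the category is unrated and has no subset).
#' @return The retained rows, with attribute `n_dropped`.
#' @export
analyzable_subset <- function(products, relevant) {
  check_nutrient(relevant)
  if (length(relevant) == 0) {
    stop("no relevant nutrients: category is unrated, no analyzable subset",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(products))
  for (nut in relevant) keep <- keep & !is.na(products[[nut]])
  out <- products[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
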