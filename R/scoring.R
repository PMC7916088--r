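#' Score products 0-100% against their category
#'
#' A product's score is the proportion of products in its (sub-)category
#' that are less nutritious than it, expressed through the threshold
#' family: the score is `100 - x_min`, where `x_min` is the smallest
#' target fraction `x` (on the integer grid) whose thresholds the product
#' complies with. A product that complies with the 13% thresholds but not
#' the 12% thresholds therefore scores 87%. Products failing even the
#' loosest (100%) thresholds — possible after claim-limit clamping — score
#' 0 by convention. Products missing any relevant nutrient are not
#' assessable. Products identical on all relevant nutrients share `x_min`
#' and hence the score; there is no tie-breaking.
#'
#' @param products A product tibble (rows to score; must carry the
#'   relevant nutrient columns).
#' @param family A threshold family from [threshold_family()], computed on
#'   the products' own sub-category.
#' @return A tibble: `product_id` (if present), `score` (integer percent,
#'   `NA` when not assessable), `x_min` (smallest compliant level, `NA` if
#'   none or not assessable), `assessable`.
#' @export
#' @examples
#' p <- tibble::tibble(product_id = as.character(1:40),
#'                     basis = "solid", total_sodium = (1:40) / 20)
#' fam <- threshold_family(p, "total_sodium", x = 1:100)
#' score_products(p, fam)
score_products <- function(products, family) {
  stopifnot(length(family) >= 1)
  xs <- as.numeric(names(family))
  stopifnot(!anyNA(xs))
  ord <- order(xs)
  nutrients <- family[[1]]$nutrient
  n <- nrow(products)
  assessable <- rep(TRUE, n)
  for (nut in nutrients) assessable <- assessable & !is.na(products[[nut]])
  x_min <- rep(NA_real_, n)
  for (i in ord) {
    ok <- complies(products, family[[i]])
    hit <- is.na(x_min) & !is.na(ok) & ok
    x_min[hit] <- xs[i]
  }
  score <- ifelse(is.na(x_min), 0, 100 - x_min)
  score[!assessable] <- NA_real_
  x_min[!assessable] <- NA_real_
  out <- tibble::tibble(score = score, x_min = x_min,
                        assessable = assessable)
  if ("product_id" %in% names(products)) {
    out <- dplyr::bind_cols(tibble::tibble(product_id = products$product_id),
                            out)
  }
  out
}

#' @rdname score_products
#' @param product A single-row product tibble.
#' @return `score_product()`: a one-row score tibble.
#' @export
score_product <- function(product, family) {
  stopifnot(nrow(product) == 1)
  score_products(product, family)
}
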