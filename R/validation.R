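#' Weighted Spearman rank correlation
#'
#' Pearson correlation of the rank-transformed pairs (midranks for ties)
#' with observation weights: both columns are converted to midranks, then
#' a weighted Pearson correlation with the supplied weights is computed.
#' With uniform weights this reduces exactly to the classical Spearman
#' coefficient. Used to compare the continuous 0-100% score against an
#' external ordinal rating whose class distribution may be far from
#' uniform (hence the weights, see [class_balance_weights()]).
#'
#' @param x,y Paired numeric vectors, length >= 3. Pairs with an `NA` in
#'   either are dropped.
#' @param w Positive weights, one per pair (default uniform).
#' @return The correlation in `[-1, 1]`, or `NA` (with a warning) when
#'   either ranking has zero variance.
#' @export
#' @examples
#' weighted_spearman(1:10, (1:10)^2)          # 1: monotone
#' weighted_spearman(1:10, -(1:10), w = runif(10, 0.5, 2))
weighted_spearman <- function(x, y, w = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w > 0 | is.na(x) | is.na(y)))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sw <- sum(w)
  mx <- sum(w * rx) / sw
  my <- sum(w * ry) / sw
  vx <- sum(w * (rx - mx)^2)
  vy <- sum(w * (ry - my)^2)
  if (vx == 0 || vy == 0) {
    warning("zero variance in a ranking; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sum(w * (rx - mx) * (ry - my)) / sqrt(vx * vy)
}

#' Inverse-class-frequency weights for an ordinal rating
#'
#' Gives each product a weight proportional to the reciprocal of its
#' rating class's frequency, normalized to mean 1 (so the weights sum to
#' the number of products). This counteracts a non-uniform rating
#' distribution when correlating scores against the rating: each rating
#' class contributes equally in aggregate.
#'
#' @param ratings Vector of ordinal ratings (any type with well-defined
#'   equality; `NA`s get weight `NA`).
#' @return Numeric weights, mean 1 over non-missing ratings.
#' @export
#' @examples
#' class_balance_weights(c(1, 1, 1, 2))  # 4/6, 4/6, 4/6, 2
class_balance_weights <- function(ratings) {
  ok <- !is.na(ratings)
  f <- table(ratings[ok])
  w <- rep(NA_real_, length(ratings))
  w[ok] <- 1 / as.numeric(f[as.character(ratings[ok])])
  w[ok] <- w[ok] * sum(ok) / sum(w[ok])
  w
}

#' Summarize agreement between scores and an external rating
#'
#' Per rating class, the five-number summary of the scores (the numbers
#' behind a boxplot-per-class display), plus a list of discordant
#' products: low rating but high score, or high rating but low score,
#' beyond configurable cut-offs.
#'
#' @param data A tibble with the score and rating columns.
#' @param score_col,rating_col Column names (strings).
#' @param low_rating,high_score A product rated `<= low_rating` with score
#'   `> high_score` is discordant (defaults 1.5 stars / 85%).
#' @param high_rating,low_score A product rated `>= high_rating` with
#'   score `< low_score` is discordant (defaults 4 stars / 15%).
#' @return A list: `class_summary` (tibble, one row per rating class:
#'   `n`, `min`, `q1`, `median`, `q3`, `max`), `discordant` (tibble of
#'   flagged rows with a `reason` column), and `weighted_spearman` (using
#'   [class_balance_weights()]).
#' @export
agreement_summary <- function(data, score_col = "score",
                              rating_col = "rating",
                              low_rating = 1.5, high_score = 85,
                              high_rating = 4, low_score = 15) {
  stopifnot(all(c(score_col, rating_col) %in% names(data)))
  d <- data[!is.na(data[[score_col]]) & !is.na(data[[rating_col]]), ,
            drop = FALSE]
  s <- d[[score_col]]
  r <- d[[rating_col]]
  class_summary <- tibble::tibble(rating = r, score = s) |>
    dplyr::group_by(.data$rating) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$score),
      q1 = stats::quantile(.data$score, 0.25, names = FALSE),
      median = stats::median(.data$score),
      q3 = stats::quantile(.data$score, 0.75, names = FALSE),
      max = max(.data$score),
      .groups = "drop"
    )
  reason <- dplyr::case_when(
    r <= low_rating & s > high_score ~ "low rating, high score",
    r >= high_rating & s < low_score ~ "high rating, low score",
    .default = NA_character_
  )
  discordant <- dplyr::bind_cols(d[!is.na(reason), , drop = FALSE],
                                 tibble::tibble(reason = reason[!is.na(reason)]))
  rws <- if (length(unique(r)) > 1 && length(s) >= 3) {
    weighted_spearman(s, r, class_balance_weights(r))
  } else {
    NA_real_
  }
  list(class_summary = class_summary, discordant = discordant,
       weighted_spearman = rws)
}

#' Boxplots of score by rating class
#'
#' @inheritParams agreement_summary
#' @return A ggplot mirroring the score-vs-rating agreement display.
#' @export
plot_agreement <- function(data, score_col = "score", rating_col = "rating") {
  d <- data[!is.na(data[[score_col]]) & !is.na(data[[rating_col]]), ,
            drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data[[rating_col]]), y = .data[[score_col]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "external rating", y = "score (%)") +
    ggplot2::theme_minimal()
}
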