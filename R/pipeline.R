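#' Run the full profiling pipeline on a product table
#'
#' Chains ingestion and cleaning, category-relevant nutrient
#' identification, mode-based category refinement, threshold derivation at
#' the requested target fractions, 0-100% product scoring, and (when an
#' external rating column is present) validation against it. All stages
#' are deterministic given the input and configuration. When `output_dir`
#' is given, machine-readable artifacts are written there: the cleaned
#' table (`cleaned.csv`), the relevance and partition reports
#' (`relevance.json`, `partition.json`), the thresholds per sub-category
#' and target (`thresholds.json`), the per-product scores (`scores.csv`),
#' and the validation report (`validation.json`).
#'
#' Sub-categories smaller than `min_n` products are reported but receive
#' no thresholds or scores; categories with no relevant nutrient are
#' flagged unrated.
#'
#' @param input A product tibble or a CSV path (see [read_products()]).
#' @param output_dir Optional directory for artifacts; created if needed.
#' @param targets Target top fractions (percent) for published thresholds.
#' @param rating_col Name of the external ordinal rating column, if any.
#' @param n_bins Mode-detector sensitivity, see [detect_modes()].
#' @param anchor_zero Histogram anchoring, see [detect_modes()].
#' @param min_n Minimum sub-category size for thresholds, see
#'   [derive_thresholds()].
#' @param exclude Category labels excluded from rating (non-reformulable
#'   products), see [ingest_products()].
#' @param limits Claim-limit table, see [claim_limits()].
#' @inheritParams salt_to_sodium
#' @inheritParams derive_thresholds
#' @return Invisibly, a list: `products` (cleaned table with
#'   `initial_category` and `subcategory` columns), `report` (ingestion
#'   counts), `relevance` (per category x nutrient), `partitions` (list of
#'   per-category partition summaries), `thresholds` (nested list:
#'   sub-category -> target -> `threshold_set`), `scores` (tibble), and
#'   `validation` (see [agreement_summary()], or `NULL`).
#' @export
run_pipeline <- function(input, output_dir = NULL, targets = c(50, 15),
                         rating_col = "rating", n_bins = 12,
                         anchor_zero = FALSE, min_n = 20, exclude = NULL,
                         limits = claim_limits(), m_nacl = 58.44,
                         paper_exact = FALSE,
                         qualifying_clamp = c("raise", "cap")) {
  qualifying_clamp <- match.arg(qualifying_clamp)
  ing <- ingest_products(input, exclude = exclude, m_nacl = m_nacl,
                         paper_exact = paper_exact)
  products <- ing$products
  if (nrow(products) == 0) {
    message("no products after ingestion; nothing to do")
    return(invisible(list(products = products, report = ing$report,
                          relevance = NULL, partitions = NULL,
                          thresholds = NULL, scores = NULL,
                          validation = NULL)))
  }
  relevance <- nutrient_relevance(products, limits = limits)

  cats <- split(products, products$initial_category)
  partitions <- list()
  sub_tabs <- list()
  for (cat_label in names(cats)) {
    cat_products <- cats[[cat_label]]
    rel <- relevance$nutrient[relevance$initial_category == cat_label &
                                relevance$relevant]
    rel <- intersect(nutrient_ids(), rel)
    if (length(rel) == 0) {
      cat_products$subcategory <- NA_character_
      partitions[[cat_label]] <- list(category = cat_label, unrated = TRUE)
      sub_tabs[[cat_label]] <- cat_products
      next
    }
    sub <- analyzable_subset(cat_products, rel)
    detections <- lapply(rel, function(nut) {
      detect_modes(sub[[nut]], n_bins = n_bins, anchor_zero = anchor_zero)
    })
    names(detections) <- rel
    sub <- split_category(sub, detections)
    part <- attr(sub, "partition")
    part$relevant_nutrients <- rel
    part$n_analyzable <- nrow(sub)
    part$n_dropped_missing_relevant <- attr(sub, "n_dropped")
    partitions[[cat_label]] <- part
    dropped <- cat_products[!cat_products$product_id %in% sub$product_id, ,
                            drop = FALSE]
    if (nrow(dropped) > 0) dropped$subcategory <- NA_character_
    sub_tabs[[cat_label]] <- dplyr::bind_rows(sub, dropped)
  }
  products <- dplyr::bind_rows(sub_tabs)

  thresholds <- list()
  score_tabs <- list()
  rated <- products[!is.na(products$subcategory), , drop = FALSE]
  for (sub_label in unique(rated$subcategory)) {
    sub <- rated[rated$subcategory == sub_label, , drop = FALSE]
    cat_label <- sub$initial_category[1]
    rel <- partitions[[cat_label]]$relevant_nutrients
    if (nrow(sub) < min_n) {
      thresholds[[sub_label]] <- list(n = nrow(sub), skipped = "below min_n")
      next
    }
    thresholds[[sub_label]] <- lapply(targets, function(x) {
      derive_thresholds(sub, rel, x, min_n = min_n, limits = limits,
                        qualifying_clamp = qualifying_clamp)
    })
    names(thresholds[[sub_label]]) <- as.character(targets)
    fam <- threshold_family(sub, rel, x = 1:100, min_n = min_n,
                            limits = limits,
                            qualifying_clamp = qualifying_clamp)
    score_tabs[[sub_label]] <- dplyr::bind_cols(
      tibble::tibble(subcategory = sub_label),
      score_products(sub, fam)
    )
  }
  scores <- dplyr::bind_rows(score_tabs)

  validation <- NULL
  if (nrow(scores) > 0 && rating_col %in% names(products)) {
    scored <- dplyr::left_join(
      scores, products[c("product_id", rating_col)], by = "product_id")
    if (sum(!is.na(scored[[rating_col]]) & !is.na(scored$score)) >= 3) {
      validation <- agreement_summary(scored, score_col = "score",
                                      rating_col = rating_col)
    }
  }

  out <- list(products = products, report = ing$report,
              relevance = relevance, partitions = partitions,
              thresholds = thresholds, scores = scores,
              validation = validation)
  if (!is.null(output_dir)) write_artifacts(out, output_dir)
  invisible(out)
}

json_threshold <- function(ts) {
  if (!inherits(ts, "threshold_set")) return(ts)
  list(
    x = attr(ts, "x"), p = attr(ts, "p"), coverage = attr(ts, "coverage"),
    n = attr(ts, "n"), coverage_shortfall = attr(ts, "coverage_shortfall"),
    nutrients = lapply(seq_len(nrow(ts)), function(i) {
      list(nutrient = ts$nutrient[i], threshold = ts$threshold[i],
           unit = "g per reference unit",
           direction = if (ts$direction[i] == "disqualifying") "<=" else ">=",
           clamped = ts$clamped[i])
    })
  )
}

write_artifacts <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file) {
    jsonlite::write_json(c(list(schema = "nutriprof/1"), x),
                         file.path(output_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
  }
  readr::write_csv(result$products, file.path(output_dir, "cleaned.csv"))
  wj(list(report = result$report), "cleaning_report.json")
  wj(list(relevance = result$relevance), "relevance.json")
  wj(list(partitions = result$partitions), "partition.json")
  wj(list(thresholds = lapply(result$thresholds, function(per_x) {
    lapply(per_x, json_threshold)
  })), "thresholds.json")
  if (!is.null(result$scores) && nrow(result$scores) > 0) {
    readr::write_csv(result$scores, file.path(output_dir, "scores.csv"))
  }
  if (!is.null(result$validation)) {
    wj(list(weighted_spearman = result$validation$weighted_spearman,
            class_summary = result$validation$class_summary,
            n_discordant = nrow(result$validation$discordant)),
       "validation.json")
  }
  invisible(output_dir)
}
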