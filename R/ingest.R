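#' Read a product table from CSV
#'
#' Header contract: a column `product_id` (opaque string), `category`
#' (label), `basis` (`solid`, `liquid` or `powder`), the five nutrient
#' columns `saturated_fat`, `total_sugars`, `total_sodium`, `protein`,
#' `fiber` (grams per reference unit; sodium in grams, so 120 mg is 0.120;
#' missing values stay missing), and optionally `salt` (g) and `rating`
#' (an external ordinal rating such as Health Star Rating half-stars).
#' Extra columns are passed through untouched.
#'
#' @param path Path to a CSV (or TSV, autodetected by [readr::read_delim()]
#'   conventions via `read_csv`) file.
#' @return A product tibble.
#' @export
read_products <- function(path) {
  spec <- readr::cols(
    product_id = readr::col_character(),
    category = readr::col_character(),
    basis = readr::col_character(),
    .default = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  required <- c("product_id", "category", "basis", nutrient_ids())
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_basis(out$basis)
  out
}

#' Estimate missing sodium from declared salt
#'
#' Where sodium is missing but salt is declared, sodium is estimated as
#' salt multiplied by the ratio of the molecular weight of sodium
#' (22.99 g/mol) to that of sodium chloride. A declared sodium value is
#' never overwritten. The default molar mass of NaCl is the chemically
#' correct 58.44 g/mol; `paper_exact = TRUE` uses 55.44 g/mol instead so
#' that published figures computed with that ratio can be reproduced.
#'
#' @param products A product tibble with `total_sodium` and (optionally)
#'   `salt` columns, both in g per reference unit.
#' @param m_nacl Molar mass of NaCl in g/mol.
#' @param paper_exact If `TRUE`, use 55.44 g/mol regardless of `m_nacl`.
#' @return The product tibble with `total_sodium` filled in where it was
#'   missing and salt was declared; the number of conversions is recorded in
#'   attribute `salt_conversions`.
#' @export
salt_to_sodium <- function(products, m_nacl = 58.44, paper_exact = FALSE) {
  if (paper_exact) m_nacl <- 55.44
  stopifnot(m_nacl > 0)
  if (!"salt" %in% names(products)) {
    attr(products, "salt_conversions") <- 0L
    return(products)
  }
  ratio <- 22.99 / m_nacl
  fill <- is.na(products$total_sodium) & !is.na(products$salt)
  products$total_sodium[fill] <- products$salt[fill] * ratio
  attr(products, "salt_conversions") <- sum(fill)
  products
}

#' Reconstitute powder products to a liquid basis
#'
#' Powders are assessed as the beverage they become, using a constant
#' dilution of 1 g powder per 10 mL water: 100 mL of reconstituted product
#' contains 10 g powder, so every declared nutrient value (and salt) is
#' multiplied by `dilution` (default 0.1) and the basis becomes `liquid`.
#' Missing values stay missing. Non-powder rows are untouched.
#'
#' @param products A product tibble.
#' @param dilution Grams of powder per gram (mL) of reconstituted product.
#' @return The product tibble with powder rows rescaled and relabelled;
#'   the number of reconstituted rows is in attribute `powders_reconstituted`.
#' @export
reconstitute_powders <- function(products, dilution = 0.1) {
  stopifnot(dilution > 0)
  is_powder <- products$basis == "powder"
  cols <- intersect(c(nutrient_ids(), "salt"), names(products))
  for (col in cols) {
    products[[col]][is_powder] <- products[[col]][is_powder] * dilution
  }
  products$basis[is_powder] <- "liquid"
  attr(products, "powders_reconstituted") <- sum(is_powder)
  products
}

#' Remove implausible rows by the nutrient-sum rule
#'
#' Rows whose declared nutrient contents sum to more than 100 g per
#' reference unit are physically impossible declarations and are removed.
#' The sum runs over the five model nutrients only (sodium in grams);
#' missing values are simply absent from the sum — they are never imputed
#' or zero-filled, because missingness is informative. A sum of exactly
#' 100 g is retained ("exceeds" is strict). Rows with a negative declared
#' value are rejected separately and reported, never silently dropped.
#'
#' @param products A product tibble.
#' @return A list with elements `products` (the retained rows) and `report`
#'   (a list of counts and per-nutrient declaration rates).
#' @export
clean_products <- function(products) {
  n_read <- nrow(products)
  nut <- intersect(c(nutrient_ids(), "salt"), names(products))
  vals <- as.matrix(products[nut])
  negative <- rowSums(vals < 0, na.rm = TRUE) > 0
  if (any(negative)) {
    warning(sum(negative), " row(s) with negative declared values rejected: ",
            paste(utils::head(products$product_id[negative], 5),
                  collapse = ", "),
            if (sum(negative) > 5) ", ..." else "", call. = FALSE)
  }
  sums <- rowSums(as.matrix(products[nutrient_ids()]), na.rm = TRUE)
  over <- sums > 100 & !negative
  keep <- !negative & !over
  retained <- products[keep, , drop = FALSE]
  decl <- vapply(nutrient_ids(), function(n) mean(!is.na(retained[[n]])),
                 numeric(1))
  if (nrow(retained) == 0) decl[] <- NA_real_
  report <- list(
    rows_read = n_read,
    rows_removed_sum_rule = sum(over),
    rows_rejected_negative = sum(negative),
    rows_retained = nrow(retained),
    declaration_rates = as.list(decl)
  )
  list(products = retained, report = report)
}

#' Split categories by declaration basis
#'
#' The same category label can be declared per 100 g in one region and per
#' 100 mL in another; such mixtures are not comparable, so each
#' (category, basis) pair with at least one product becomes one *initial
#' category*. Product count is conserved.
#'
#' @param products A product tibble whose `basis` is resolved (`solid` or
#'   `liquid`; run [reconstitute_powders()] first).
#' @return The tibble with an added `initial_category` column
#'   (`"<category> [<basis>]"`).
#' @export
partition_by_basis <- function(products) {
  check_basis(products$basis)
  if (any(products$basis == "powder")) {
    stop("powder rows present; run reconstitute_powders() first",
         call. = FALSE)
  }
  products$initial_category <- paste0(products$category, " [",
                                      products$basis, "]")
  products
}

#' Run the full ingestion stage
#'
#' Chains [salt_to_sodium()], [reconstitute_powders()], [clean_products()]
#' and [partition_by_basis()], optionally dropping excluded category labels
#' (products that cannot be reformulated, e.g. plain water or 100% juices,
#' are out of the model's scope and are handled as a configurable exclusion
#' list rather than hard-coded logic).
#'
#' @param products A product tibble or a path readable by [read_products()].
#' @param exclude Character vector of category labels to drop before
#'   cleaning.
#' @inheritParams salt_to_sodium
#' @inheritParams reconstitute_powders
#' @return A list: `products` (cleaned, basis-partitioned tibble) and
#'   `report` (ingestion counts, see [clean_products()]).
#' @export
ingest_products <- function(products, exclude = NULL, m_nacl = 58.44,
                            paper_exact = FALSE, dilution = 0.1) {
  if (is.character(products) && length(products) == 1) {
    products <- read_products(products)
  }
  n_excluded <- 0L
  if (!is.null(exclude)) {
    drop <- products$category %in% exclude
    n_excluded <- sum(drop)
    products <- products[!drop, , drop = FALSE]
  }
  products <- salt_to_sodium(products, m_nacl = m_nacl,
                             paper_exact = paper_exact)
  n_salt <- attr(products, "salt_conversions")
  products <- reconstitute_powders(products, dilution = dilution)
  n_powder <- attr(products, "powders_reconstituted")
  cleaned <- clean_products(products)
  out <- partition_by_basis(cleaned$products)
  report <- c(cleaned$report,
              list(rows_excluded_category = n_excluded,
                   salt_conversions = n_salt,
                   powders_reconstituted = n_powder))
  list(products = out, report = report)
}
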