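#' The five model nutrients
#'
#' The profiling model tracks three disqualifying components (to limit) and
#' two qualifying components (to encourage), chosen because population-level
#' intake goals exist for all five.
#'
#' @return Character vector of the five nutrient identifiers, in canonical
#'   order: `saturated_fat`, `total_sugars`, `total_sodium`, `protein`,
#'   `fiber`.
#' @export
#' @examples
#' nutrient_ids()
nutrient_ids <- function() {
  c("saturated_fat", "total_sugars", "total_sodium", "protein", "fiber")
}

#' @rdname nutrient_ids
#' @param nutrient Character vector of nutrient identifiers.
#' @return `nutrient_direction()`: `"disqualifying"` (lower is better) or
#'   `"qualifying"` (higher is better) for each input.
#' @export
nutrient_direction <- function(nutrient) {
  check_nutrient(nutrient)
  ifelse(nutrient %in% c("protein", "fiber"), "qualifying", "disqualifying")
}

check_nutrient <- function(nutrient) {
  bad <- setdiff(nutrient, nutrient_ids())
  if (length(bad) > 0) {
    stop("unknown nutrient(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(nutrient_ids(), collapse = ", "),
         call. = FALSE)
  }
  invisible(nutrient)
}

check_basis <- function(basis) {
  bad <- setdiff(basis, c("solid", "liquid", "powder"))
  if (length(bad) > 0) {
    stop("unknown basis value(s): ", paste(bad, collapse = ", "),
         "; expected 'solid' (per 100 g), 'liquid' (per 100 mL) or 'powder'",
         call. = FALSE)
  }
  invisible(basis)
}

# "Low in" / "source of" claim limits, g per reference unit (100 g or 100 mL).
# Sodium is carried in grams internally (0.120 g = 120 mg); the liquid fiber
# limit is half the solid one. Protein limits correspond to a 50 g nutrient
# reference value.
.default_limits <- function() {
  tibble::tibble(
    nutrient = rep(nutrient_ids(), times = 2),
    basis    = rep(c("solid", "liquid"), each = 5),
    limit    = c(1.50, 5.0, 0.120, 5.0, 3.0,
                 0.75, 2.5, 0.120, 2.5, 1.5),
    kind     = rep(c("low_in", "low_in", "low_in", "source_of", "source_of"),
                   times = 2),
    direction = rep(nutrient_direction(nutrient_ids()), times = 2)
  )
}

#' Regulatory claim limits used as relevance cut-points and clamping bounds
#'
#' Returns the per-nutrient, per-basis "low in" (disqualifying nutrients) and
#' "source of" (qualifying nutrients) claim limits, in grams per reference
#' unit (100 g for solids, 100 mL for liquids). These limits serve two roles:
#' a nutrient is category-relevant only if more than half of a category's
#' products exceed its limit, and derived thresholds are clamped so they never
#' demand more than the claimable level.
#'
#' Defaults can be overridden (e.g. for regulatory variants) either with a
#' data frame of rows `nutrient`, `basis`, `limit`, or with the path to a
#' YAML file containing a list of such records.
#'
#' @param overrides `NULL` (use defaults), a data frame with columns
#'   `nutrient`, `basis`, `limit`, or the path to a YAML file whose top level
#'   is a list of `{nutrient, basis, limit}` records.
#' @return A tibble with columns `nutrient`, `basis`, `limit` (g per
#'   reference unit), `kind` (`low_in`/`source_of`) and `direction`.
#' @export
#' @examples
#' claim_limits()
#' claim_limit("saturated_fat", "solid")
claim_limits <- function(overrides = NULL) {
  lim <- .default_limits()
  if (is.null(overrides)) {
    return(lim)
  }
  if (is.character(overrides) && length(overrides) == 1) {
    recs <- yaml::read_yaml(overrides)
    overrides <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  }
  stopifnot(is.data.frame(overrides),
            all(c("nutrient", "basis", "limit") %in% names(overrides)))
  check_nutrient(overrides$nutrient)
  check_basis(overrides$basis)
  stopifnot(all(overrides$limit >= 0))
  for (i in seq_len(nrow(overrides))) {
    sel <- lim$nutrient == overrides$nutrient[i] &
      lim$basis == overrides$basis[i]
    lim$limit[sel] <- overrides$limit[i]
  }
  lim
}

#' @rdname claim_limits
#' @param nutrient A single nutrient identifier (see [nutrient_ids()]).
#' @param basis `"solid"` or `"liquid"`.
#' @param limits A limits table, as returned by [claim_limits()].
#' @return `claim_limit()`: the scalar limit in g per reference unit.
#' @export
claim_limit <- function(nutrient, basis, limits = claim_limits()) {
  stopifnot(length(nutrient) == 1, length(basis) == 1)
  check_nutrient(nutrient)
  if (!basis %in% c("solid", "liquid")) {
    stop("claim limits are defined for 'solid' and 'liquid' bases only; ",
         "reconstitute powders first (see reconstitute_powders())",
         call. = FALSE)
  }
  limits$limit[limits$nutrient == nutrient & limits$basis == basis]
}
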