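Package: nutriprof
Title: Data-Driven Nutrient Profiling of Packaged Foods for Reformulation Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives category-specific nutrient thresholds from packaged-food
    composition databases. Given declared contents of five nutrients
    (saturated fat, total sugars, total sodium, protein, fiber), the package
    identifies category-relevant nutrients against regulatory "low in" and
    "source of" claim limits, splits nutritionally heterogeneous categories
    with a histogram-convexity mode detector, derives joint "best x%"
    thresholds by a minimal-common-percentile search with claim-limit
    clamping, scores individual products 0-100% against their category, and
    validates scores against an external ordinal rating via weighted Spearman
    correlation. Includes a synthetic product-database generator so the full
    pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
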