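# nutriprof

Data-driven nutrient profiling of packaged foods, built to answer a
manufacturer's (or regulator's) question: *what would this product's recipe
have to look like to be among the best x% of its category on the nutrients
that matter there?* Unlike consumer-facing front-of-pack schemes, the
output is a set of per-nutrient reformulation targets that are feasible by
construction, because they are read off the distribution of products
actually on the market.

The package is aimed at nutrition scientists and food-industry analysts
working with product composition databases: tables of declared contents of
five public-health nutrients — saturated fat, total sugars, total sodium
(disqualifying: lower is better), protein and fiber (qualifying: higher is
better) — in g per 100 g (solids) or 100 mL (liquids).

## The method

For each product category, four stages:

1. **Relevance.** A nutrient is *category-relevant* when more than half of
   the category's products strictly exceed its regulatory claim limit —
   the "low in" limit for disqualifying nutrients, the "source of" limit
   for qualifying ones (solid basis: 1.50 / 5.0 / 0.120 / 5.0 / 3.0 g per
   100 g). Missing declarations count against relevance, and only products
   declaring every relevant nutrient are analysed further.

2. **Refinement.** Each relevant nutrient's distribution is scanned for
   major modes with a deliberately insensitive detector: a 12-bin
   histogram in which bin *i* is a potential mode iff
   *c(i) > (c(i−1) + c(i+1)) / 2*. Runs of flagged bins merge into one
   mode at their span's midpoint, and the category is split at the
   midpoints between consecutive modes — the final sub-categories are the
   Cartesian product of the per-nutrient intervals, each a distinct
   consumer offer (e.g. low / medium / highly salted).

3. **Thresholds.** For a target top-fraction *x*, the *minimal common
   percentile* level *p* is found such that cutting every disqualifying
   nutrient at its empirical *p*-th percentile (compliance ≤) and every
   qualifying nutrient at its (100−*p*)-th percentile (compliance ≥)
   leaves at least *x*% of the sub-category's products jointly compliant.
   Thresholds that would undercut a claim limit are clamped to it and the
   search re-run on the remaining nutrients.

4. **Scoring and validation.** A product's score is 100 − *x*<sub>min</sub>,
   where *x*<sub>min</sub> is the smallest integer *x* whose thresholds it
   meets: the proportion of category peers it beats. Scores can be
   compared against an external ordinal rating (e.g. Health Star Rating
   stars) with an inverse-class-frequency **weighted Spearman
   correlation** and per-class boxplot summaries.

A synthetic product-database generator (mixture distributions, planted
modes, per-nutrient missingness, ground-truth sidecar) makes the whole
pipeline testable without any proprietary data.

## Worked example

The shipped demonstration fixture is an 850-product margarine-like solid
category with a broad unimodal saturated-fat offer and three planted
sodium offers near 135, 405 and 675 mg/100 g:

```r
library(nutriprof)

m   <- margarine_fixture()
rel <- relevant_nutrients(m)
#> [1] "saturated_fat" "total_sodium"

sub <- analyzable_subset(ingest_products(m)$products, rel)
detect_modes(sub$total_sodium)
#> <mode_detection> 850 values, 12 bins; 3 mode(s) at 0.1309, 0.3923, 0.6537;
#>   cuts at 0.2616, 0.523
```

Sodium is trimodal; the category splits at ~262 and ~523 mg/100 g into
sub-categories of 267, 293 and 290 products (saturated fat is unimodal, so
1 × 3 = 3 cells). Thresholds for the "highly salted" offer:

```r
sp   <- split_category(sub, list(saturated_fat = detect_modes(sub$saturated_fat),
                                 total_sodium  = detect_modes(sub$total_sodium)))
high <- dplyr::filter(sp, grepl("3/3", subcategory))
ts50 <- derive_thresholds(high, rel, x = 50)
glance(ts50)
#>       x     p coverage     n n_nutrients n_clamped coverage_shortfall
#> 1    50  71.0    0.503   290           2         0 FALSE
```

Reading: the top half of the 290 highly-salted products is delimited by
the 71st percentile on *each* nutrient jointly — saturated fat ≤ 16.6
g/100 g and sodium ≤ 693 mg/100 g (50.3% of products meet both). Moving
the target to the top 15% tightens them:

```r
threshold_report(ts50, derive_thresholds(high, rel, x = 15))
#>   nutrient      threshold_1 threshold_2 rel_change_pct label
#> 1 saturated_fat      16.6        12.7              -23 -23%
#> 2 total_sodium        0.693       0.666             -4 -4%
```

so a median product would need a 23% saturated-fat and 4% sodium
reduction to join the best 15% of its offer. Per-product scores follow
from the full threshold family:

```r
fam <- threshold_family(high, rel, x = 1:100)
head(score_products(high, fam), 3)
#>   product_id score x_min assessable
#> 1 P000561       53    47 TRUE
#> 2 P000562       85    15 TRUE
#> 3 P000563       37    63 TRUE
```

`run_pipeline()` chains all stages on a full product table and writes
machine-readable artifacts (cleaned CSV, relevance/partition/threshold
JSON, score CSV); `inst/scripts/nutriprof.R` is a thin command-line
wrapper with `simulate` and `run` subcommands.

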