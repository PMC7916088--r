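---
title: "Category-specific nutrient profiling: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-specific nutrient profiling: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriprof)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, the numerical conventions, the design choices
made where the method's description leaves room, and what the synthetic
data generator can and cannot tell you about behaviour on real databases.

## The model

The profiling model ranks packaged foods *within their category* on five
nutrients with established population-level intake goals: saturated fat,
total sugars and total sodium to limit (disqualifying), protein and fiber
to encourage (qualifying). All contents are grams per reference unit —
100 g for solids, 100 mL for liquids — with sodium carried internally in
grams (0.120 g = 120 mg) and rendered in mg only at reporting time, since
the claim-limit table mixes the two conventions. Powders are assessed as
the beverage they become, at a fixed dilution of 1 g powder per 10 mL
water (so all declared values scale by 0.1 and the basis becomes liquid);
no product-specific dilution is assumed because composition databases
rarely carry one.

Four assumptions do the real work:

* **Categories are competitive sets.** Thresholds and scores only ever
  compare a product with products a consumer would see as substitutes, so
  the category labels of the input database define the unit of analysis,
  refined further only where the data show distinct offers.
* **Declared values are the data.** Missingness is informative (regional
  declaration policies, categories where a nutrient is absent by nature)
  and is never imputed or zero-filled. A product missing a relevant
  nutrient is excluded from that category's analysis and is unassessable
  for scoring.
* **Claim limits anchor meaning.** The regulatory "low in" / "source of"
  limits decide which nutrients matter in a category and bound how strict
  a published target may be.
* **Feasibility comes from the market.** Every threshold is an observed
  value (an order statistic), so a published target is always a
  composition some product already achieves.

## Stage by stage

### Relevance (claim limits as evidence)

A nutrient is category-relevant when *more than half* of the category's
products strictly exceed its claim limit. Two conventions are deliberate:
the denominator is **all** products (a missing declaration counts as
non-exceeding, the conservative reading), and "exceeds" is strict — a
product exactly at the "low in" limit is claimably low in that nutrient
and is therefore not evidence that the nutrient matters. The 50% rule
itself is a trade-off baked into the method: it balances the number of
relevant nutrients against the number of products retained (those
declaring every relevant nutrient).

### Refinement (the convexity mode detector)

Categories can bundle distinct consumer offers (sugar-sweetened vs diet
drinks; low vs highly salted spreads). The detector is intentionally much
less sensitive than formal multimodality tests (dip tests and kin), which
would fragment categories: it bins each relevant nutrient into a
histogram with exactly `n_bins = 12` equal-width bins and flags bin $i$ as
a *potential mode* iff

$$c_i > \tfrac{1}{2}\,(c_{i-1} + c_{i+1}),$$

with strict inequality (a tie with the neighbour average is not
convexity). Isolated flagged bins place a mode at their midpoint; runs of
consecutive flagged bins merge into one mode at the midpoint of the run's
full span. Cut points are the means of consecutive modes, and final
sub-categories are the Cartesian product of per-nutrient intervals.

Choices the definition leaves open, and what this package does:

* **Histogram range.** `[min, max]` of the observed values (half-open
  bins, last bin closed). `anchor_zero = TRUE` anchors at 0 instead,
  which reproduces round-number bin edges when the maximum is round; the
  data-driven default generalizes better to nutrients whose support
  starts well above zero.
* **Edge bins.** The two-neighbour rule is defined for interior bins
  only; an edge bin is flagged iff it counts strictly more than its
  single neighbour.
* **Interval membership.** Left-closed: a product exactly at a cut point
  belongs to the upper interval, so "270–540" includes 270.
* **Sensitivity.** `n_bins` is the single tuning knob: fewer bins, fewer
  (never more, in practice) modes. 12 is the method's fixed default.

An honest caveat that matters for interpretation: on a *continuous*
unimodal sample of a few hundred to a thousand products, the strict
convexity test behaves like a coin flip wherever the histogram's second
difference is small relative to Poisson noise — the flanks of a smooth
peak and sparse tails. Draws of a perfectly unimodal distribution are
therefore flagged multimodal on a substantial fraction of seeds, usually
with a small spurious mode on a shoulder or in the tail. Well-separated
mixture components, by contrast, are recovered essentially always (the
test suite checks cut-point recovery on planted trimodal sodium mixtures
across 100 seeds, requiring ≥95% success within one bin width). This is a
property of the published detector, not an implementation artifact;
practitioners should read a two-mode call with a tiny secondary cell as
noise, and the shipped `margarine_fixture()` pins a default seed so that
the demonstration object actually exhibits the canonical structure
(unimodal saturated fat, trimodal sodium) it exists to illustrate.

### Thresholds (minimal common percentile)

For a target top-fraction $x$, the engine finds the smallest common
percentile level $p$ such that cutting every disqualifying nutrient at
its empirical $p$-th percentile (compliance $\le$) and every qualifying
nutrient at its $(100-p)$-th percentile (compliance $\ge$) leaves at
least $x\%$ of products *jointly* compliant. With correlated nutrients
$p$ can be far above $x$ (for two independent uniform nutrients and
$x = 50$, $p \to 100\sqrt{0.5} \approx 70.7$ — a closed form the tests
verify by simulation).

Numerical conventions:

* **Quantiles are nearest-rank** (the $\lceil pn/100 \rceil$-th order
  statistic), so thresholds are observed values and joint compliance can
  be counted exactly, with no interpolation ambiguity. The search runs
  over the grid of attainable levels $p_k = 100k/n$; coverage is a
  nondecreasing step function of $k$, so bisection over $k$ is exact.
  Ranks are indexed by integer $k$ rather than recomputed from $p$, which
  avoids a floating-point off-by-one at grid points.
* **Compliance is inclusive** ($\le$ / $\ge$) at exact equality,
  consistent with the claim-limit table's own "if ≤ limit" phrasing —
  necessary anyway, since thresholds are observed values and the defining
  product must comply with its own threshold.
* **The qualifying mirror.** The canonical worked examples only involve
  disqualifying nutrients; cutting qualifying nutrients at the
  $(100-p)$-th percentile is the symmetric construction and is what this
  package does.
* **Minimum size.** Deriving published targets from very small
  sub-categories would hang them on a handful of order statistics;
  `min_n = 20` products is the configurable floor below which derivation
  is refused.

**Clamping.** A derived threshold below the nutrient's claim limit is set
to that limit and the level re-searched with the clamped nutrient as a
fixed constraint, iterating until stable. For disqualifying nutrients the
rationale is plain: a target must not demand less than the "low in"
level. For qualifying nutrients the rule as stated ("below the source-of
limit → set to the limit") *raises* the threshold, i.e. makes it
stricter — demanding at least the claimable "source of" level; that
reading is the default (`qualifying_clamp = "raise"`). Because a raised
constraint can make the target fraction unreachable, the resulting set
then reports its achieved coverage with an explicit shortfall flag rather
than pretending. The symmetric alternative — capping a qualifying
threshold that exceeds the limit, mirroring the disqualifying direction —
is available as `qualifying_clamp = "cap"` for sensitivity analysis.

### Scoring and validation

Scores use the integer grid $x = 1..100$: a product's $x_{\min}$ is the
smallest level whose thresholds it meets, and its score is
$100 - x_{\min}$ — the proportion of category peers it beats (a product
compliant at 13% but not 12% scores 87%). Ties on all relevant nutrients
share a score; there is no randomization anywhere. Products failing even
the 100% thresholds — possible only after clamping — score 0 by
convention, and products missing a relevant nutrient are unassessable
(`NA`, never 0).

For convergent validation against an external ordinal rating, the
correlation is a weighted Spearman: both columns are converted to
midranks (both can be heavily tied) and a weighted Pearson correlation is
taken. With uniform weights this is exactly classical Spearman. The
weighting itself is not uniquely defined by "accounting for a non-uniform
rating distribution"; this package adopts inverse-class-frequency weights
normalized to mean 1 — each rating class contributes equally in aggregate
— and exposes the weight vector as an argument so any other scheme can be
plugged in. The external rating arrives as a data column and is never
computed here: its algorithm (points tables, energy, fruit/vegetable
content) is separate regulation, outside this model's five-nutrient
scope.

## The synthetic generator

`generate_products()` emulates exactly the statistical structure the
method's stages respond to: category labels with a declaration basis;
per-nutrient finite mixtures (log-normal components by default — declared
composition data are non-negative and right-skewed — or zero-truncated
normal, parameterized by natural-scale mean and sd); exact or weighted
component sizes; per-nutrient missingness probabilities; optional salt
columns for conversion testing. Ground truth (component assignment and
true means) travels in an attribute/JSON sidecar that the pipeline never
reads, so recovery tests cannot leak.

What it deliberately does **not** emulate: label rounding and digit
preference, correlated missingness across nutrients within a product,
regional declaration policies, category taxonomies of real databases, or
correlation *between* nutrients within a component. Consequently, passing
tests demonstrate that the algorithms do what they claim on data with
planted structure — they do not certify behaviour on any particular
commercial database, whose category granularity and declaration habits
dominate real-world results.

`margarine_fixture()` is the canonical demonstration: 850 solid products,
saturated fat as one broad zero-truncated normal offer (mean 14, sd 5
g/100 g), sodium as three components at 135/405/675 mg/100 g sized
267/293/290, sugars/protein/fiber set below their claim limits with 40%
fiber missingness. On it, relevance selects exactly saturated fat and
sodium, and the detector splits the category in three at cuts near 262
and 523 mg/100 g.

## Ingestion rules

Cleaning removes rows whose declared five-nutrient sum exceeds 100 g per
reference unit (strictly; a sum of exactly 100 is retained), summing only
the model's five columns with missing values absent from the sum.
Negative declarations are rejected with a diagnostic, never silently.
Where sodium is missing but salt declared, sodium = salt × 22.99 /
M(NaCl); the default molar mass is the chemically correct 58.44 g/mol,
with `paper_exact = TRUE` switching to a 55.44 g/mol variant so numbers
computed with that ratio elsewhere can be reproduced — a declared sodium
value is never overwritten either way. Categories declared on mixed bases
are split into one initial category per (label, basis) pair, and
non-reformulable product classes (plain water, 100% juices, infant
formula, supplements) are handled as a configurable exclusion list rather
than hard-coded logic.

## Problem sizes and determinism

The test suite runs on synthetic categories of 20–2000 products: exact
worked-example arithmetic on constructed histograms; brute-force oracle
equivalence of the percentile search on ≤200-product, ≤3-nutrient
fixtures; planted-mode recovery at n = 1000 over 100 seeds; full-grid
(x = 1..100) monotonicity and score–threshold duality on 100–150-product
categories — sizes at which every property is exactly checkable in
seconds while exercising the same code paths as database-scale runs.
Everything downstream of the generator is deterministic: given one input
table and configuration, reruns produce byte-identical artifacts.

## Known limitations

* Results inherit the input database's categorization; categories that
  mix offers the relevant nutrients cannot separate stay mixed.
* The detector's noise sensitivity on smooth unimodal samples (above)
  means occasional spurious small sub-categories; downstream, `min_n`
  stops them from publishing unstable thresholds, but they still shrink
  their parent.
* Thresholds are order statistics: in sub-categories near `min_n` they
  move with single products.
* Scores are within-sub-category percentiles and must not be compared
  across categories — a 90% margarine is not "healthier" than a 60%
  breakfast cereal.
* The five-nutrient scope omits energy, micronutrients and ingredient
  quality; convergent agreement with holistic ratings is expected to be
  strong but not perfect, and the discordance report exists precisely to
  surface products where the two views part ways.
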