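---
title: "Methods: share-of-search disparity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: share-of-search disparity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `searchshare`, the
assumptions it makes, the design decisions taken where the problem is
genuinely open, and what the synthetic-data tests do and do not establish.

## 1. The data and the normalization problem

The input is a county-by-period-by-symptom panel of nonnegative search
weights, in the dialect released by large search providers: aggregated,
anonymized, with two crucial quirks.

* **Inconsistent scaling.** Weights are normalized per region and time
  range with undisclosed factors, so `w(c, t, s)` is comparable to
  `w(c, t, s')` but *not* to `w(c', t, s)`. Formally we model
  `w(c, t, s) = sigma(c) * a(c, t, s)` with `sigma(c) > 0` unknown.
* **Privacy suppression.** Cells below a privacy threshold are empty, and
  sparsely populated counties are withheld entirely. An empty cell is
  *missing*, never zero; a literal 0 is an observed zero. The package
  preserves this distinction end to end.

The share of search

\[ p(c,t,s) = 100\, \frac{w(c,t,s)}{\sum_{s'} w(c,t,s')} \]

eliminates `sigma(c)` exactly. This invariance is the methodological heart
of the package and is enforced as a tested property (any positive
per-county rescaling changes no share by more than 1e-9), alongside
conservation (non-missing shares per county-period sum to 100 within
1e-9).

**Denominator decision.** Whether suppressed cells belong in the
denominator is not decidable from the data description. We exclude them:
suppression reflects a reporting threshold, not absence of searching, and
imputing 0 would inflate the observed symptoms' shares systematically in
low-volume (rural) counties — precisely the stratum under study. The
consequence is that shares in heavily suppressed county-periods are
measured over a smaller symptom basis; users comparing strata with very
different suppression rates should be aware of it.

**Biweekly aggregation.** Sub-period weights are *summed* into 14-day
half-open windows `[anchor + 14k, anchor + 14(k+1))`, labelled by window
start. Because scaling is consistent within a county, sums and means give
identical shares; summation was chosen as the more natural "total
searching" reading. A window is missing only if all contributors are
missing; trailing partially covered windows are dropped rather than
extrapolated.

## 2. Symptom-set construction

The mental-health symptom set is assembled in three audited steps:

1. **Dual-coder agreement.** Two raters label each catalogue topic as
   mental-health-relevant or not; agreement is summarized by Cohen's
   \(\kappa = (p_o - p_e)/(1 - p_e)\). The degenerate case `p_e = 1`
   (both raters constant and agreeing) is defined as `kappa = 1`.
2. **Affiliation expansion.** Somatic presentations of distress (headache,
   fatigue) co-occur in searches with explicit mental-health topics. Seeds
   are expanded through a co-search affiliation table; associations with a
   relevance score below the threshold (default 2) are removed, so a score
   *exactly at* the threshold is kept. The relevance scale is treated as an
   opaque nonnegative score — its units are provider-internal. Expansion is
   single-pass by default: transitive closure (`transitive = TRUE`) is
   available but chains quickly drift off-topic, and a one-hop
   neighbourhood matches how such lists are curated in practice.
   `threshold_sweep()` reports set size against the threshold; it is
   deliberately not an optimizer, because "coverage vs noise" is a
   judgement call, not a formal criterion.
3. **Exclusions.** Manual removals (respiratory symptoms, nonpsychiatric
   syndromes) are recorded with reasons; the invariant
   `final = (seeds U expanded) \ excluded` is tested.

## 3. Contrasts and multiple testing

Contrast families mirror the standard reporting tables: per-symptom rows
plus an `overall` composite row, each a two-group comparison of share
observations.

* **Observation unit.** Default `county_period`: each county contributes
  one observation per biweekly window. The alternative `county_mean` (one
  span mean per county) is implemented because published table captions
  rarely say which was used and the choice changes effective sample size by
  an order of magnitude. We default to county-period — it uses the panel's
  temporal replication and is the unit under which the generator's null
  calibration is verified — but neither is asserted as "the" published
  convention.
* **t test.** Welch by default: the contrasted strata have grossly unequal
  spreads (rural shortage SDs are several times metro SDs) and unequal
  sizes, so the equal-variance assumption is untenable. The pooled variant
  exists for replication attempts. Zero-variance degeneracies follow fixed
  conventions (equal means: t = 0, p = 1; unequal: p = 0 with a flag).
* **FDR.** "Q value" is Benjamini–Hochberg, the standard default when only
  "false discovery rate" is specified; the family is one results table.
  Benjamini–Yekutieli is available behind `fdr_method = "BY"` for users
  worried about dependence between symptom rows. `bh_fdr()` is
  hand-implemented (5 lines of step-up) and verified exactly against a
  brute-force implementation of the definition and against
  `stats::p.adjust`.
* **Strata.** The 6-tier urbanization code collapses as 1–4 metro, 5
  micropolitan, 6 rural; "urban" in named contrasts means micropolitan
  (tier 5) and "metro" means large central metro (tier 1, population >= 1
  million). The ambiguity of "urban" between tiers 5 and 2–4 is real; we
  chose the reading that keeps the three groups disjoint and extreme.
* **Partial designations.** Counties only partially designated as shortage
  areas are excluded from two-group contrasts (the clean comparison is
  entirely-shortage vs entirely-nonshortage) but retained in rankings and
  time series, where they are descriptive.
* **Temporal cutoff.** Default 2020-03-11 (the WHO pandemic declaration);
  configurable, since mid-March alternatives (e.g. March 15) appear in
  published footnotes. Periods are the same biweekly windows; `< cutoff`
  is pre, `>= cutoff` post, and each side must contain at least two
  windows.

## 4. The synthetic world

`generate_panel()` draws
\[ w(c,t,s) = \sigma(c)\,\lambda(s)\,e(\mathrm{stratum}(c), s)\,
   m(t,s)\,e^{\epsilon} + L, \]
with `sigma(c) ~ U(0.5, 2)` (strong scale confounding — deliberately not
removable by anything except the share normalization),
`epsilon ~ N(0, 0.2^2)` log-normal measurement noise,
`L ~ Laplace(0, b)` additive noise mimicking differential-privacy
mechanisms (`b = 0.01` by default, on the weight scale), truncation at 0,
per-cell suppression below a threshold, and whole-county suppression.
Effects `e` are **multiplicative**, so planted differences survive the
unknown scale factor exactly as real behavioural differences would; a null
configuration therefore has all true contrast differences exactly 0, which
makes ground truth analytic: true shares are
`100 * lambda e m / sum(lambda e m)` per stratum and regime, and
`true_mean_share()` / `true_contrast_diff()` expose them.

Defaults state a world, not a dial: the base propensity table
(`default_symptom_table()`) puts the mental-health composite at 15.06% of
all searching with 18 mental-health topics (17 named + a bucket) and 5
bulk non-mental-health topics standing in for a 422-topic catalogue;
stratum fractions are 45% shortage / 10% partial / 45% nonshortage and
35% rural / 30% micropolitan / 35% metro per stratum, chosen once as
plausible US county mixes. `config_disparity_demo()` plants the observed
disparity magnitudes (13.42% vs 15.06% composite; anxiety 2.03%/2.24%
elevated in shortage/rural-shortage; suicidal ideation 0.024% vs 0.088% in
rural strata) *exactly*, via the closed-form solver
`plant_share_targets()`: holding untargeted symptoms' propensity mass
fixed, the multiplier for a target share `q` is `q D / (100 lambda e)`
with `D = 100 L0 / (100 - sum(q))`. Noise and provider suppression
parameters are free parameters, not estimates — the provider's actual
mechanism is unpublished.

Determinism: one master seed; each county derives its own substream, so
enlarging a panel never perturbs existing counties (tested).

**What a green test establishes — and what it does not.** The synthetic
world has independent log-normal cell noise, exchangeable counties within
strata, and stationary regimes around a single step. Real panels have
spatial correlation, seasonality, population-size-dependent noise floors,
and suppression correlated with the outcome. Green acceptance tests
establish that the *pipeline* is correct and calibrated under its stated
model (type-I rate within binomial error of 0.05 over 200 null families;
a 0.3-percentage-point composite deficit detected in at least 95/100
seeds at 400 counties by 26 periods; planted orderings reproduced), not
that any substantive epidemiological finding is true.

## 5. Numerical choices and edge cases

* Shares and tolerances: conservation and scale invariance are asserted at
  1e-9 absolute on the 0–100 scale; all-zero county-periods yield missing
  shares rather than 0/0.
* FIPS codes are zero-padded 5-character strings everywhere; numeric
  storage silently destroys the leading zeros of New England counties.
* BH ties: tied p values share the post-`cummin` value, identical to the
  step-up definition's treatment; ranking is stable.
* Rankings break ties by ascending FIPS; `k` beyond the county count
  truncates with a warning.
* Single-county groups in time series report missing standard errors
  rather than zero-width intervals.
* Pipeline failures remove partial outputs and name the failing stage;
  manifests record a content hash (md5) and row count per written file.

## 6. Scope limitations

The package does not download provider, HRSA or NCHS files; does not render
maps (it exports the per-county composite-share CSV a mapping layer would
consume); does not model query text, sessions, or formally calibrated
differential privacy; performs no regression adjustment for confounders —
contrasts are descriptive, not causal. Run configuration is JSON and
tabular output is CSV (no YAML/Parquet dependencies in the supported
environment).
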