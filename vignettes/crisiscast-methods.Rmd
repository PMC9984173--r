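---
title: "Forecasting food crises from news streams: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting food crises from news streams: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisiscast)
```

## The problem

Famine early-warning systems publish an ordinal Integrated Phase
Classification (IPC) of food insecurity — five phases from *minimal* to
*famine* — per district, a few times a year. The risk factors behind a
deteriorating phase (conflict, price shocks, weather, pests, displacement)
are well known, but their ground measurements arrive with delays of months,
while local news reports on the same events almost immediately. `crisiscast`
implements a pipeline that turns district-tagged news streams into
district-level phase forecasts and crisis-outbreak warnings:

1. **Lexicon construction** — find text features that journalists use when
   describing *causes* of food insecurity.
2. **News factors** — convert feature mentions into monthly panel series.
3. **Granger screening** — keep only features whose district series
   anticipate the IPC phase.
4. **Forecasting** — random-forest regression of the next-period phase on
   lagged phase, traditional and news blocks, under temporal
   cross-validation.
5. **Outbreak evaluation** — dual-threshold classification of crisis
   onsets, precision-recall sweeps, and Diebold-Mariano forecast
   comparison.

Because the underlying news corpus and assessment panel are proprietary, the
package ships a synthetic-data generator that reproduces the statistical
structure every stage relies on; all tests and the acceptance script run
against it.

## Lexicon construction

**Seeds and expansion.** Three seed key phrases anchor the notion of acute
food insecurity: `"food insecurity"`, `"hunger crisis"`, `"famine"`.
Candidate n-grams are ranked by their *word mover's distance* (WMD) to the
nearest seed — the exact optimal-transport cost between the uniform
bag-of-words distributions of the two phrases under the Euclidean metric in
embedding space. `expand_seeds()` keeps the `keep_k` closest candidates,
with bigrams/trigrams required to contain "food" or "hunger".

The WMD is computed by a transportation-simplex solver written for this
package (`ot_transport()`); no exact optimal-transport solver is available
among the installed dependencies. Design choices, where the method
description is silent:

* uniform weights over token *instances* (a repeated token carries double
  mass), no stop-word removal;
* an n-gram is transported as a document of its tokens, not as an averaged
  vector;
* out-of-vocabulary tokens are dropped before transport; a fully
  out-of-vocabulary phrase has no distribution and is treated as infinitely
  far, so it can never be selected.

**Frame filter.** `select_frame_features()` consumes pre-parsed semantic
frames (role-labelled constituents plus a trigger) and applies four filters
in order: (1) the frame must contain at least one *cause* and one *effect*
role; (2) an effect constituent must contain a seed phrase
(case-insensitive contiguous-token match); (3) the trigger must be one of
the causal links (a FrameNet-derived list, `default_causal_links()`);
(4) every unigram/bigram/trigram of the surviving cause and effect
constituents is emitted. Step 4 extracts *all* contiguous token n-grams;
whether punctuation or stop words should block an n-gram is not specified
anywhere, so no extra filtering is applied. A scholarly-literature stream is
the same operation applied to a second frame file.

**Keyword expansion.** `expand_keywords()` adds corpus n-grams (all
unigrams; bigrams/trigrams occurring *strictly more than* `min_count`
times) whose WMD to an original feature is *strictly below* `dist_max`.
The reference cutoffs (`min_count = 1000`, `dist_max = 6`) presume a
multi-million-article corpus and 300-dimensional news embeddings; with
synthetic embeddings both must be rescaled to the generator's geometry.

## News factors

For feature $w$, unit $i$ and month $t$ the news factor is
$$x_{w,i,t} = \frac{\#\{\text{articles mentioning } i \text{ and } w
\text{ in } t\}}{\#\{\text{articles mentioning } i \text{ in } t\}}.$$
A province or country is "mentioned" when any of its districts is: the
aggregate terms exist to capture shocks in the surrounding region, and no
separate province-level mention tagging is defined. Months with no coverage
yield value 0 with a `coverage = 0` flag rather than a missing value, so
lag matrices stay complete; the flag permits masking downstream.
`percentile_rank()` (Hazen, $(r-0.5)/n$) is a display convenience;
screening and forecasting always consume raw proportions.

`cluster_coherence()` validates a manual partition of features into
semantic clusters by checking, on article-level binary mention indicators,
that each feature correlates more with its own cluster than with any other.
`match_traditional()` pairs each traditional risk factor with the news
factor of highest Spearman correlation over pooled district-months.

## Granger screening

Stationarity first: each feature's district series are run through an
augmented Dickey-Fuller test (constant, no trend, augmentation order by AIC
up to 12, 5% level — none of these is specified upstream and all are
conventional defaults) and differenced until stationary, at most twice
(`adf_difference()`). No unit-root test ships with the installed R
packages, so the ADF regression and the Dickey-Fuller $\tau_\mu$ p-value
table interpolation are implemented here. The panel decision is a vote: the
feature-level difference order is the smallest order sufficient for at
least half of the testable district series.

The screen fits a pooled panel ADL model at the district-period level,
$$y_{d,t} = a_0 + a_1 y_{d,t-1\,\text{per}} + \dots + a_p y_{d,t-p\,\text{per}}
 + b_1 x_{w,d,t-3} + \dots + b_q x_{w,d,t-q-2} + \varepsilon_{d,t},$$
with phase lags stepping over reporting periods and factor lags over
calendar months starting three months back. Orders $(p,q)$ are chosen by
AIC over $p \in \{1..4\}$, $q \in \{1..6\}$ (ranges are a package default;
none are given upstream), compared on a common estimation sample. A feature
is retained iff the nested F test of $b_1 = \dots = b_q = 0$ rejects at the
1% level on training observations; a later evaluation window, when
supplied, is only used for an out-of-split error report, never for the
decision. "Adds explanatory power" is read as this standard joint test;
single intercept, no district fixed effects, as the model is written.

Two calibration facts, measured by the package's own simulations and worth
knowing before trusting the screen:

* with *fixed* orders the F test holds its nominal size well
  (≈ 1.5% at the 1% level on panels with spatially correlated phases);
* AIC order search *before* testing inflates the empirical size to
  ≈ 3.5–4% — classical pretest bias — and likewise AIC pins the exact true
  orders in only ≈ half of high-signal replicates (it never *under*-selects;
  the overshoot probability is the familiar $\Pr(\chi^2_k > 2k)$ per extra
  lag and does not vanish with signal strength). The package keeps the
  AIC-then-test procedure because that is the method as described; users
  wanting a size-calibrated screen should pass single-value `p_range` /
  `q_range`. No multiple-testing correction is applied across features,
  deliberately.

## Forecasting

`build_design()` assembles, per (district, period): six period-lags of the
phase; five static district attributes; and, per time-varying factor and
per level (district, province = member mean, country = member mean), six
monthly lags ending `horizon_months` before the target period's end month
(months $t-h-0,\dots,t-h-5$; with nine factors that is $9 \times 3 \times 6
+ 5 = 167$ traditional columns, and $|w| \times 3 \times 6$ news columns).
"Previous period" is period-indexed, so the same code spans the 2016 change
from quarterly to thrice-yearly reporting. Rows lacking full lag history
are dropped and counted. `assert_no_leakage()` checks every column's lag
offset against the horizon and every fold's train < validation < test
ordering.

`make_folds()` splits the post-burn-in periods into 10 contiguous disjoint
test windows; each fold validates on the `val_periods` periods before its
test window and trains on everything earlier. `fit_predict()` grid-searches
the forest hyperparameters on the validation window, refits the winner on
training + validation, and predicts the test window; the overall RMSE is
the unweighted mean of fold test RMSEs. Forests are `ranger` forests,
single-threaded and seeded, so reruns are bit-identical. The hyperparameter
grid maps `n_estimators` to `num.trees`, `min_samples_split` to
`min.node.size` (fractions become shares of the training set), and
`max_features` to `mtry`, with `"auto"` meaning all predictors (its
historical regression meaning); an impurity-decrease threshold has no
`ranger` analogue and is omitted from the grid. RMSE is computed on the raw
1–5 ordinal scale; published headline error magnitudes evidently use an
undocumented rescaling, so only scale-invariant ratios are meaningful for
comparison. Expert forecasts, when provided, enter as one extra regressor
column. A single pooled model serves all countries.

## Outbreak evaluation

An *outbreak* starts when the phase reaches ≥ 3 for two consecutive periods
after a period at ≤ 2 (`label_outbreaks()`; an episode is *severe* if any
of its periods reaches 4). A phase forecast becomes an outbreak classifier
through two thresholds: onset is predicted at $t$ iff
$\hat y_t \ge u$, $\hat y_{t+1} \ge u$, $\hat y_{t-1} \le l$ — the "±3
months" of the source formula read as *adjacent reporting period* so the
rule survives the schedule change; the prior-period condition uses the
*predicted* value, as the formula is written (an observed-phase variant
exists). `pr_sweep()` evaluates the $(l, u)$ grid (default step 0.01; the
reference 0.001 grid is available but is ~8M threshold pairs), extracts the
non-dominated Pareto front, and integrates a trapezoidal AUC over the raw
front — smoothing a precision-recall front can create infeasible operating
points, so the AUC never uses smoothed curves. Left of the front the
precision is extended flat; beyond the largest achieved recall nothing is
added. `recall_at_precision()` reports the best front recall at a precision
floor.

`dm_test()` compares paired squared-error series with the
serial-correlation-robust variance built from truncated autocovariances up
to lag $\lfloor n^{1/3}\rfloor + 1$, against a two-sided normal reference
(reported p-values in the source are two-sided). `rmse_ci()` applies the
same correction to a single model's squared errors to give a 95% interval
on the mean squared error and its root; a negative truncated variance is
clamped to zero and flagged.

## The synthetic world

`scenario_config()` fixes everything from one seed. Defaults describe the
study conditions the package is designed around: 21 countries × 3 provinces
× 3 districts (189 districts), monthly calendar 2010–2019, quarterly IPC
reporting until 2016 then February/June/October, ~40 articles per
district-month.

* **Latent risk.** Five components (conflict, price, weather, pest,
  displacement), each a district-level AR(1) (`ar_coef = 0.85`) whose
  innovations sum district, province and country shocks
  (variance shares 0.6/0.25/0.15) — the spatial aggregation that the
  province/country regression terms exploit.
* **Phases.** The phase is 1 + the number of cutpoints below the mean of
  the lagged components; each component affects the phase `lead_tau = 4`
  months after it moves. Default cutpoints are the normal quantiles giving
  ≈ 55/30/12/2.5/0.5% of district-periods in phases 1–5, a distribution in
  the range of real assessment panels.
* **Traditional factors.** Nine monthly series (two conflict, two price,
  three weather, two vegetation), each a noisy monotone transform of one
  component observed `report_lag_months = 4` months late — encoding the
  documented pattern that ground indicators trail news by months; the
  displacement component is deliberately unmeasured. Five static
  attributes round out the traditional block.
* **Articles.** Poisson counts with a log-normal per-district coverage
  bias drawn *independently of risk* — the real joint distribution of
  coverage and food insecurity is unknown, and this neutrality is a
  modelling choice, not a finding. Planted cause-feature mentions follow
  the *current* component risk in log-odds, so mentions lead the phase by
  `lead_tau`; noise features and seeds have flat rates. A fraction of
  cause mentions emits a cause/effect frame with a seeded effect and causal
  trigger; decoy frames exercise the filters.
* **Embeddings.** Cluster centroids at scale `between_sd = 2` with words
  at `within_sd = 0.1`, so planted near-synonyms are recoverable by WMD.

What the generator does *not* emulate: natural-language article text,
gazetteer ambiguity, coverage that responds to crises, assessment error in
the phases, or any geopolitical realism. Green tests therefore demonstrate
that the pipeline's machinery is correct and that it recovers planted
structure under its own assumptions — not that the real-world effect sizes
transfer.

## Problem sizes used in tests and the acceptance script

Simulation-backed checks run at desk scale, chosen once for statistical
stability of the quantity under test: screen calibration uses 1000 null
features over five 18-district worlds; order-selection recovery uses 100
replicates of a 100-district × 30-period panel; the end-to-end
superiority check and the acceptance script use 108-district, 10-year
scenarios (20 replicate seeds for the superiority count), where the
combined-vs-traditional comparison was piloted to be stable. Exact-oracle
equivalences (WMD, nested F, threshold sweeps, DM/CI) use micro-fixtures
where brute force is feasible.

## Known limitations

* The screen's size inflation under AIC order search (above) is inherited
  from the stated procedure; treat retention counts near the nominal level
  as upper bounds.
* The WMD solver is exact but dense; it is meant for n-gram-scale
  documents, not long texts.
* Province/country aggregates are unweighted means of member districts;
  population weighting would need the static block.
* The ordinal phase is regressed as a number, as in the source method;
  no ordinal link is used.
* With very sparse coverage the zero-filled months bias proportions
  towards 0; the `coverage` flag is the escape hatch.
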