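---
title: "Sequential CART synthesis: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential CART synthesis: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartsynth)
```

## The synthesis model

`synthesize()` factorises the joint distribution of the columns as a product
of conditionals along a visit sequence,
$$ p(x_1, \dots, x_p) = p(x_1)\, p(x_2 \mid x_1) \cdots p(x_p \mid x_1, \dots, x_{p-1}), $$
and estimates each conditional nonparametrically with a classification or
regression tree. Synthetic values are not model predictions but *donor
draws*: a synthetic row is routed to a leaf and receives the target value of
one training row in that leaf, chosen uniformly with replacement. Two
consequences follow and are load-bearing:

- **Donor property.** Every synthetic cell is a value that occurs in the
  original column (missingness included). Distributional support is never
  extrapolated, and exact row matching against the original data is
  well-defined — which is what makes replicate-based disclosure control
  possible at all.
- **Within-leaf exchangeability.** The method assumes rows in a leaf are
  exchangeable for the target variable. Relationships coarser than the leaf
  resolution are preserved; structure finer than `min_leaf` rows is smoothed
  away.

The first variable has no predecessors; its conditional is the marginal, so
it is bootstrapped (equivalently, a root-only tree). With `proper = TRUE`,
each variable's tree is fitted to a fresh bootstrap resample of the original
rows, which propagates model-estimation uncertainty into the synthetic data;
the default (`FALSE`) conditions on the observed data directly. The visit
sequence defaults to schema order: no ordering is canonical, schema order is
reproducible, and the argument is user-overridable.

## Tree fitting

Regression targets minimise within-node sum of squared deviations;
categorical targets minimise count-weighted Gini impurity. Candidate
numeric thresholds are the midpoints between consecutive distinct sorted
values; candidate categorical splits are all proper level subsets
(exhaustive up to 10 levels, above that the classic ordered-levels reduction:
sort levels by mean response, or first-class share, and cut contiguously).

Growth controls (all in `cart_params()`):

| parameter | default | meaning |
|---|---|---|
| `min_leaf` | 5 rows | smallest admissible leaf; also the smallest donor pool |
| `min_split` | 10 rows | a node smaller than this is never split |
| `max_depth` | 30 | recursion cap (root = depth 0) |
| `min_impurity_decrease` | 1e-8 of root impurity | minimum useful gain |

The defaults follow the conventions of the sequential-synthesis ecosystem.
`min_leaf` is the privacy/utility dial that matters: donor pools of 5 mean a
synthetic value identifies its donor row with probability at most 1/5 given
its leaf, while larger values blur conditional structure.

**Determinism.** Ties among equally good splits are broken by predictor
order, then smallest threshold, then subset enumeration order; equality is
judged with a relative tolerance of $10^{-12}$ of the root impurity so that
floating-point noise cannot reorder candidates. A value exactly at a
threshold routes left.

**Missing values.** A missing categorical predictor value is its own
category, eligible for either side of a subset split. A missing numeric
predictor value follows the branch that gave lower impurity at fit time
(ties left), and the choice is stored in the split. An unseen categorical
level at routing time follows the branch that held the majority of that
node's training rows. There are no surrogate splits: every rule is explicit,
stored, and deterministic. A missing categorical *target* is an extra class;
a numeric column with missing cells is synthesised in two parts (indicator
tree, then value tree on complete rows) — the scheme keeps the donor
property and makes the synthetic missing rate testable against the observed
rate.

**Degenerate inputs.** A constant target, an all-identical predictor set,
or any node below `min_split` yields a leaf (for the first variable this
collapses to a bootstrap). Zero-row data and all-missing numeric targets
are errors; an all-missing column inside a larger synthesis passes through
as all-missing with a warning rather than killing a pipeline run.

## Randomness protocol

One root seed governs a run. Each (dataset, variable) pair re-seeds from a
fixed affine substream of the root seed, so earlier columns are bit-for-bit
invariant when later variables are added to the visit sequence, and every
seeded pipeline is byte-identical on rerun. Seeds derived internally stay
below $2^{31}$.

## Utility metrics

*General utility* aligns frequency tables — categorical levels come from the
schema (so zero-count levels stay aligned), numeric values are binned on
equal-width breaks over the pooled min–max (default `n_bins = 20`),
missingness is an explicit extra bar — and reports total-variation distance
$\tfrac12\sum_b |\hat p_b - \hat q_b|$ with proportions taken over all rows.
TV is a metric, 0 iff the relative tables agree and 1 for disjoint support;
the binning makes an otherwise visual comparison quantitative and testable.

*Specific utility* refits one user-specified linear model on both datasets.
The standardized coefficient difference divides by the **observed** fit's
standard error — not pooled, not the synthetic one — because the question is
whether synthesis displaced the estimate relative to the original data's
uncertainty; its reference distribution is taken as standard normal. The
lack-of-fit statistic uses the full observed coefficient covariance
(Mahalanobis form) with df = number of coefficients, intercept included;
this reduces exactly to $z^2$ for one coefficient and is invariant to
predictor rescaling, which a diagonal approximation is not. The interval
overlap is the average of the two intervals' shares of their intersection;
it is symmetric, equals 1 only for identical intervals, and goes negative
for disjoint ones, so "high overlap" statements have a fixed scale. No
multiple-testing adjustment is applied across coefficients; the report
presents per-coefficient values as a screening display, not a family of
confirmatory tests.

## Disclosure control

A synthetic row is a *replicate* iff it equals an original row on every
column, missing matching missing, numerics compared exactly (donor sampling
copies doubles verbatim, so exact comparison is well-posed; CSV output uses
17 significant digits to keep it well-posed across round-trips). Each
synthetic row is counted once however many original rows it matches —
the count answers "how many synthetic rows are risky", not "how many
pairings exist". Near-match or attribute-disclosure risk is out of scope by
design. The `FAKE_DATA` label column is provenance metadata: it is always
first, constant, and automatically excluded from synthesis, utility and
replicate computations.

## The physiological simulator

`simulate_hrv_dataset()` emulates a resting-physiology study: heart rate
~ N(70, 10) bpm, weight ~ N(75, 15) kg, fitness ~ N(40, 8), HRV ~ mean 42 sd
15 ms, with corr(HRV, fitness) = 0.3 (a medium effect) and all other
correlations zero. Skewed HRV margins — typical of RMSSD-type measures —
are produced by a rank-preserving map of the normal margin onto a
moment-matched log-normal whose shape parameter is solved to hit sample
skewness ≈ 1 ("low") or ≈ 3 ("high"); rank preservation keeps the
association with fitness intact on the rank scale. Outliers replace
`max(1, round(0.01 n))` HRV values with draws 4–6 sd above the mean
(equipment artefacts, not distribution tails). Missingness is completely at
random at the cell's rate, applied to all four variables — the mechanism a
malfunctioning sensor induces. All of these are explicit `sim_params()`
arguments, not hidden constants; where the emulated study design does not
pin a value, the default above is the package's declared choice and is not
tuned against any outcome.

What the generator does *not* emulate: real RMSSD heteroskedasticity,
informative (MAR/MNAR) missingness, measurement rounding, or within-person
repeated measures. A green grid therefore establishes robustness of the
synthesis-and-assessment loop across sample size, skew and MCAR missingness
— not performance on any particular real dataset.

## Known limitations

- Sequential trees capture interactions only as deep as the trees grow; weak
  high-order structure in small samples is smoothed into leaves.
- Specific utility is model-relative: a model nobody fits can still be
  distorted. Assess the models you intend to publish.
- Replicate removal truncates the synthetic sample and can slightly bias
  marginals when the replicate rate is high (small discrete tables).
- Inference uses classical OLS machinery; robust/sandwich errors, GLMs and
  pooled multi-dataset (m > 1) inference are intentionally not provided.
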