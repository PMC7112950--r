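# cartsynth

Sequential CART synthesis of tabular data, with utility assessment and
statistical disclosure control.

## The problem

Many human-subjects datasets — clinical, psychological, physiological —
cannot be shared openly: even after removing direct identifiers, individual
records remain re-identifiable. A *synthetic* dataset replaces every value
by a draw from a model of the original data, so that no row corresponds to a
real person while the distributions and inter-variable relationships that
analyses depend on are preserved. `cartsynth` is for researchers and data
custodians who want to release such a synthetic version of a rectangular
dataset and to *demonstrate*, quantitatively, that it is both useful and
safe.

## The method

**Synthesis.** Variables are synthesised one at a time in a visit sequence
x₁, x₂, …, x_p. The first variable is bootstrapped from its observed
marginal. Each later variable x_j is modelled by a classification and
regression tree (CART) of x_j on the already-visited variables x₁…x_{j−1},
fitted to the original data; each synthetic row is routed down the tree and
receives the value of one *donor* row drawn uniformly from the leaf it
reaches. Regression trees split to minimise within-node Σ(y−ȳ)²,
classification trees to minimise count-weighted Gini impurity; growth stops
at `min_leaf` = 5, `min_split` = 10, `max_depth` = 30. Because every
synthetic cell is a copied original value, exact-replicate detection is
well-defined. Missing values are first-class: a missing categorical value is
its own level end-to-end, and a numeric column with missing cells is
synthesised as a missingness indicator (classification tree) plus a value
tree fitted to the complete rows.

**Utility.** *General utility* compares aligned marginal and bivariate
frequency tables (missingness as its own bar) by total-variation distance.
*Specific utility* compares a user-chosen linear model fitted to both
datasets:

- standardized coefficient difference `z_j = (β_syn,j − β_obs,j) / se_obs,j`
  with a two-sided normal p-value,
- confidence interval overlap
  `½·[I/(hi_o−lo_o) + I/(hi_s−lo_s)]`, `I = min(hi)−max(lo)`
  (1 iff identical, negative when disjoint),
- a global lack-of-fit test
  `χ² = (β_syn−β_obs)ᵀ V_obs⁻¹ (β_syn−β_obs)` on df = number of
  coefficients.

**Disclosure control.** Exact replicates of original rows are detected
(all columns, missing-matches-missing) and optionally removed; an exported
file gets a constant `FAKE_DATA` column in front so it can never be mistaken
for real data; `collapse_levels()` and `top_code()` (e.g. ages ≥ 70 →
`"70+"`) coarsen risky categories.

**Robustness study.** A built-in simulator generates four physiological
variables (heart rate, weight, fitness, HRV) with corr(HRV, fitness) = 0.3,
configurable HRV skew (rank-preserving log-normal transform), injected
outliers and MCAR missingness, and `run_grid()` crosses sample size × skew ×
missingness, scoring specific utility of `fitness ~ hrv` in every cell.

## Worked example

```r
library(cartsynth)
set.seed(2025)
n <- 200
obs <- data.frame(
  age   = round(rnorm(n, 45, 12), 1),
  group = factor(sample(c("placebo", "treatment"), n, TRUE),
                 levels = c("placebo", "treatment")))
obs$score <- round(2 + 0.05 * obs$age + 0.8 * (obs$group == "treatment") + rnorm(n), 2)

syn <- synthesize(obs, seed = 42)$datasets[[1]]
rep <- find_replicates(obs, syn)
print(rep)
#> 19 of 200 synthetic row(s) replicate an original row (9.5%)
syn <- apply_sdc(syn, rep, remove_replicates = TRUE, add_label = TRUE)

compare_marginals(obs, syn)
#> marginal comparison: 200 observed vs 181 synthetic rows
#> total-variation distance per variable:
#>    age  group  score
#> 0.1380 0.0057 0.0725
assess_specific(obs, syn, "score", c("group", "age"))
#> specific utility report
#>            coef beta_obs beta_syn       z      p ci_overlap
#>     (Intercept)   2.1900   2.4118  0.7828 0.4338     0.7988
#>  grouptreatment   0.6382   0.8381  1.4143 0.1573     0.6482
#>             age   0.0471   0.0414 -0.9673 0.3334     0.7505
#> lack-of-fit: X2(3) = 3.524, p = 0.3177
```

Reading the numbers: synthesis reproduced the marginals closely (TV ≤ 0.14),
19 chance replicates were removed, no coefficient moved detectably relative
to the original fit's uncertainty (all standardized-difference p > 0.15, CI
overlaps 0.65–0.80), and the joint lack-of-fit test finds no displacement of
the model (χ²(3) = 3.52, p = 0.32) — the synthetic file supports the same
inference as the original.

A command-line wrapper is installed at `inst/cli/cartsynth.R`
(`synth` / `assess` / `simulate` subcommands); see its header for usage.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch: it simulates
a physiological dataset, synthesises it, applies disclosure control, scores
general and specific utility, and executes the scaled 3 skew × 3 missingness
simulation grid at n = 100, printing every report it computes and writing
the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
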