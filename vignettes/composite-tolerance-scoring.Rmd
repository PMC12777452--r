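---
title: "Composite tolerance scoring and multi-omics integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite tolerance scoring and multi-omics integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salttol)
```

## The scoring model

`evaluate_tolerance()` turns a treatments × indicators panel into one
composite score per treatment in five steps.

**Standardization.** Every indicator is expressed relative to the control
treatment. For a *positive* indicator the score is
$100 \cdot x_{ti}/x_{ci}$; for a *negative* indicator (one whose increase
reflects damage, e.g. malondialdehyde or the Na⁺/K⁺ ratio) the reciprocal
$100 \cdot x_{ci}/x_{ti}$ is used, so that "more" is always "better" after
this step. Ratio standardization assumes all measurements are strictly
positive — reciprocals and ratios are meaningless otherwise — and the
package enforces that with named errors rather than producing NaNs. An
immediate consequence, tested as an invariant, is *scale invariance*:
multiplying any one indicator (including its control value) by any
positive constant leaves every downstream number unchanged.

**PCA.** The standardized columns are z-scored (sample standard deviation,
`ddof = 1`; configurable, and immaterial past the correlation matrix) and
the correlation matrix eigendecomposed. Indicators enter on heterogeneous
scales even after ratio standardization — a proline ratio can reach 380
while a water-content ratio moves by a few percent — so the correlation
(not covariance) matrix is the right object: each indicator gets equal a
priori footing. The variance contribution of component $j$ is
$PC_j = \lambda_j / \sum_k \lambda_k$, and the smallest $k$ whose
cumulative contribution reaches the threshold (default $\ge 0.85$) is
retained. Component scores are $F = Z V$ with $V$ the retained
eigenvectors.

**Weights.** $W_j = PC_j / \sum_{i=1}^{k} PC_i$ over the $k$ retained
components. The denominator is the sum over *all* retained components;
this is the only reading under which the weights form a convex
combination, which the composite-score step requires for $CS \in [0, 1]$.

**Membership function.** Each component-score column is min–max rescaled
across treatments, $U = (F - F_{\min})/(F_{\max} - F_{\min})$. Every
membership column therefore attains exactly 0 and exactly 1; a column with
no spread (possible only in contrived inputs) is an explicit error, since
its membership would be undefined.

**Composite score and rank.** $CS = \sum_j W_j U_j$, a convex combination
of values in $[0,1]$. Rank 1 is the largest $CS$; exact ties keep input
order (`rank(..., ties.method = "first")`), which makes ranking
deterministic and permutation-equivariant in the tested sense.

## Numerical choices

- **Eigenvector signs.** An eigenvector is defined only up to sign, and the
  membership step is *not* sign-invariant, so a fixed convention is
  applied: each component is flipped so that its largest-magnitude
  coefficient is positive, ties broken by the lowest indicator index. The
  test suite compares component scores against a brute-force
  eigendecomposition only up to column sign for exactly this reason.
- **Component selection** uses a `1e-12` slack on the cumulative sum so a
  threshold of exactly 0.85 is not missed to floating-point rounding.
- **Percent changes** (`percent_change()`) are rounded half-up (away from
  zero) to two decimals — the rounding that reproduces published two-decimal
  comparisons — rather than R's banker's rounding.
- **Small panels.** Two treatments are allowed: the correlation matrix
  degenerates to ±1 entries, one component is retained, and the composite
  scores are exactly {0, 1}. One treatment, constant indicators, and
  thresholds outside (0, 1] are errors.

## Screening rules

`screen_degs()` and `screen_dams()` implement the two printed rules
exactly, including their asymmetry, which is deliberate and preserved:

| | fold change | significance |
|---|---|---|
| DEG | strictly `> 1.42` or `< 1/1.42` | BH-adjusted `q ≤ 0.05` (inclusive) |
| DAM | `≥ 1.2` or `≤ 0.83` (inclusive) | raw `p < 0.05` (strict) |

"Absolute fold change above 1.42" is interpreted on the ratio scale as
FC > 1.42 or FC < 1/1.42 (equivalently $|\log_2 FC| > \log_2 1.42$); the
absolute value of a ratio has no other sensible meaning. Boundary
behaviour is locked down by exhaustive grid tests straddling every
threshold. Features with missing statistics are excluded with a logged
count, never silently.

`compute_feature_stats()` is intentionally plain plumbing for synthetic
sample matrices: group-mean fold change with a pseudocount (default 1),
Welch's t-test on `log2(x + pseudocount)`, BH adjustment across all
features in the table. It is not, and does not try to be, a
negative-binomial differential-expression engine; real count data should
be screened from externally computed statistics tables, which the screens
accept directly.

## Nine-quadrant integration

Pairs pass a Spearman gate and are then classified by the sign class of
each member's log2 fold change at `lfc_min = 0.5`, all comparisons strict.
The grid is numbered with the gene axis horizontal (down, unchanged, up)
and the metabolite axis vertical with "up" on top: Q3/Q7 concordant,
Q1/Q9 discordant, Q5 doubly unchanged. The numbering convention is the
package's own (such plots are rarely numbered explicitly in print) and is
emitted in every JSON output header. The gate defaults to $|\rho| > 0.8$;
whether a published gate of "Spearman > 0.8" meant signed or absolute
correlation is generally ambiguous, so `gate = "signed"` is available.
Pairs with missing $\rho$ or fold changes are tallied as `missing` —
partition completeness (gated + filtered + missing = total) is a tested
invariant, as is the antisymmetry Q1↔Q9, Q2↔Q8, Q3↔Q7, Q4↔Q6 under
joint sign flips.

## The synthetic-data generators

`generate_indicator_table()` emulates a two-series dose-response
experiment: each value is the mean of `n_reps = 3` replicates of
`control_mean × multiplier × (1 + noise)` with multiplicative Gaussian
noise (`cv = 0.05` by default, truncated at −0.9 to keep values positive).
The built-in `default_indicator_design()` encodes ten treatments (water
vs H₂S-donor irrigation × 0/50/100/200/300 mM NaCl) and twelve indicators
whose control means and response shapes follow the magnitudes typical of
published root physiology panels: enzyme activities peaking at moderate
salt, monotone proline and MDA accumulation, starch decline, K⁺ loss, and
attenuated damage in the donor series. Which indicators are "negative" is
a judgement call the method leaves to the analyst; the built-in design
marks MDA and the Na⁺/K⁺ ratio negative and everything else positive, and
the polarity map is always user-configurable.

`generate_paired_omics()` draws background features as independent
log-normals (log2 noise sd 0.5) with true fold change 1. A planted pair
shares a latent factor: the stated noise sd is *split* into a latent
component (`sd·√latent_cor`) and an independent residual, so planted
features keep the background noise level while the within-pair log-scale
correlation hits the target (0.95 by default). At `noise_sd = 0` a planted
pair is purely latent and its Spearman correlation is exactly ±1. Group
mean shifts implement the designed log2 fold changes (|log2FC| = 2 in the
built-in design, 12 samples per group), and the truth table records each
planted pair's designed quadrant.

What these generators do *not* emulate matters for interpreting green
tests: indicator noise is independent across indicators (real physiology
panels are correlated through shared biology), omics abundances have no
mean–variance relationship, no batch structure, and no missingness, and
fold changes are planted directly rather than arising from counts. Passing
recovery tests therefore demonstrate the *pipeline's* correctness and
calibration, not robustness to every pathology of real data.

## Problem sizes and determinism

All stochastic checks run under fixed or `--seed`-derived seeds with no
global RNG state (`withr::with_seed`). The test suite uses 200 replicates
for quadrant recovery and null-screen calibration, 100 seeds for rank
recovery of a six-treatment dominance ladder at CV 0.05, and brute-force
oracles (hand-coded BH step-up, definition-based rank Pearson, explicit
correlation-matrix eigendecomposition) on small cases; the acceptance
script reports the same quantities at 100 replicates each. These sizes
give stable estimates (binomial se < 2% at the tested rates) while keeping
a full run in tens of seconds on one core.

## Known limitations

- The composite score is relative to the treatment set at hand: adding or
  removing a treatment changes the min–max normalization and can reorder
  close scores. Scores should not be compared across differently composed
  panels.
- With more indicators than treatments the trailing eigenvalues are
  numerically zero; contributions are clipped at zero and renormalized,
  which is why a 10-treatment, 12-indicator panel is fine but its trailing
  components are meaningless.
- The DEG/DAM screens inherit whatever bias is in the supplied fold
  changes and p-values; the built-in Welch feeder is for synthetic data
  and small validation panels.
- All-pairs association is O(genes × metabolites); pass a candidate pair
  list for large panels.
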