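# salttol

Composite salt-tolerance evaluation and transcript–metabolite integration
for treatment-structured plant stress experiments.

When a stress experiment measures a panel of physiological indicators
(antioxidant enzyme activities, osmolytes, membrane damage, ion balance,
root architecture, ...) across a set of treatments, no single indicator
tells you which treatment left the plant best off. The agronomic
comprehensive-evaluation method answers that with one number per treatment.
`salttol` implements that method as a tested, reusable pipeline, together
with the companion multi-omics steps used in the same kind of study:
threshold screens for differentially expressed genes (DEGs) and
differentially accumulated metabolites (DAMs), and the nine-quadrant
classification of gene–metabolite pairs gated on Spearman correlation. A
synthetic-data module generates treatment panels and paired omics matrices
with known ground truth, so every stage is testable without any download.

## The method

Given a treatments × indicators matrix with a designated control treatment
and a per-indicator polarity:

1. **Standardization.** Positive indicators: `100 × value / control`;
   negative indicators (higher = worse): `100 × control / value`. The
   control row becomes 100 everywhere and larger is always better.
2. **PCA.** Columns are z-scored and the correlation matrix
   eigendecomposed. Components are retained until the cumulative variance
   contribution reaches a threshold (default ≥ 0.85). Component scores are
   `F = Z · X`, with `X` the score coefficients (sign-fixed eigenvectors).
3. **Weights.** `W_j = PC_j / Σ_i PC_i` over the retained components, with
   `PC_j` the variance contribution rate, so `Σ W_j = 1`.
4. **Membership function.** Each component score column is min–max rescaled
   across treatments: `U = (F − F_min) / (F_max − F_min)` ∈ [0, 1].
5. **Composite score and rank.** `CS = Σ_j W_j U_j` ∈ [0, 1]; rank 1 goes to
   the highest CS (ties keep input order).

The omics side applies the field's printed screening rules: DEGs pass with
fold change strictly above 1.42 (or below 1/1.42) and BH-adjusted
q ≤ 0.05; DAMs with fold change ≥ 1.2 or ≤ 0.83 and raw p < 0.05. Pairs of
screened features are placed on a 3×3 grid by the sign class of each
member's log2 fold change (|log2FC| > 0.5), restricted to pairs with
Spearman |rho| > 0.8.

## Worked example

```r
library(salttol)

des <- default_indicator_design(cv = 0.05)   # ten treatments, 12 indicators
tbl <- generate_indicator_table(des, seed = 42)
fit <- evaluate_tolerance(tbl, des$polarity, control = "W")
fit
#> Composite tolerance evaluation
#>   control: W  retained components: 2  weights: 0.851 0.149
#>
#> # A tibble: 10 × 3
#>    treatment composite  rank
#>    <chr>         <dbl> <int>
#>  1 W             0.883     1
#>  2 H             0.851     2
#>  3 WS50          0.771     3
#>  4 HS50          0.758     4
#>  5 HS100         0.579     5
#>  6 WS100         0.519     6
#>  7 HS200         0.385     7
#>  8 WS200         0.293     8
#>  9 HS300         0.132     9
#> 10 WS300         0        10
```

Two principal components carry 85% of the panel's variance, weighted
0.851/0.149. The unstressed treatments (`W`, `H`) score highest, composite
scores fall with NaCl dose, and at every matched dose the donor-treated
series (`HS*`) outranks the water series (`WS*`) — e.g. at 200 mM:

```r
percent_change(fit$scores$composite[fit$scores$treatment == "WS200"],
               fit$scores$composite[fit$scores$treatment == "HS200"])
#> [1] 31.41
```

`tidy(fit)` returns the per-treatment table with component scores and
membership values, `glance(fit)` the one-row model summary, and
`autoplot(fit)` a ranked bar chart. The omics stages chain the same way:

```r
om <- generate_paired_omics(default_omics_design(), seed = 1)
gs <- compute_feature_stats(om$genes, om$groups, "control")
ms <- compute_feature_stats(om$metabolites, om$groups, "control")
screen_degs(gs)                        # up/down DEG calls
pa <- pair_associations(om$genes, om$metabolites, gs, ms)
classify_nine_quadrant(pa)             # quadrant per pair + counts
```

A command-line wrapper with `score`, `screen-deg`, `screen-dam`,
`quadrant`, and `simulate` subcommands is installed at
`system.file("scripts", "salttol", package = "salttol")`; file formats are
documented in `inst/FORMATS.md`.

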