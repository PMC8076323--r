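# tdfe — unsupervised feature extraction by matrix and tensor decomposition

`tdfe` selects features (genes, genomic regions) from small-sample,
high-dimensional omics experiments — the regime of an unreplicated
time course, e.g. expression and MeRIP-seq m6A coverage measured once
each at 0/6/12/24 h — where per-feature tests have no power after
multiple-testing correction.

Instead of fitting a model per feature, the package decomposes the
whole data set once and works backwards from the sample-side
structure:

1. **Decompose.** A features × samples matrix goes through gram-matrix
   PCA (`pca_gram()`: scores `u_ℓ` are eigenvectors of `X Xᵀ`, computed
   via thin SVD; loadings `v_ℓ = Xᵀ u_ℓ`). A features × time ×
   condition tensor goes through one-pass higher-order SVD (`hosvd()`):
   `x_ktj = Σ G(ℓ₁ℓ₂ℓ₃) u_{ℓ₁k} u_{ℓ₂t} u_{ℓ₃j}` with orthonormal
   factor matrices and an all-orthogonal core `G`.
2. **Choose components post hoc.** The time axis is the sample factor
   most correlated (|Pearson r|) with the time covariate; the condition
   axis on a two-level mode is the lowest component with opposite-sign
   (contrast) or same-sign (concordant) entries; the feature axis is
   the `ℓ₁` maximizing `|G(ℓ₁, ℓ₂, ℓ₃)|` given the chosen sample axes.
3. **Attribute P-values.** Each feature's score is standardized by the
   score vector's standard deviation σ and referred to the upper tail
   of χ²(1): `P_i = P_{χ²}[> (u_i/σ)²]`; BH adjustment; strict
   `adjusted < 0.01` selection.
4. **Integrate two layers (KTD).** Two data sets over the same time
   points are combined into a small sample-space kernel tensor built
   from feature-space inner products (`build_pair_kernel()`,
   `build_dual_kernel()`); HOSVD of the kernel plus back-projection
   (`project_*_features()`) yields per-feature scores for each data
   set, selected with the same χ²/BH machinery, and the overlap of the
   two selections is quantified by Fisher's exact test with the
   conditional-MLE odds ratio (`overlap_fisher()`).

Supporting modules: BED-like interval reading and fixed 25-kb genome
binning for MeRIP-seq coverage (`read_intervals()`, `bin_coverage()`,
`assemble_tensor()`), planted-signal benchmark generators
(`simulate_planted_tensor()`, `simulate_paired_tensors()`), a native
per-feature linear-regression baseline
(`linear_regression_select()`), confusion-matrix evaluation against
planted truth, tidyverse-style `tidy()`/`glance()`/`autoplot()`
methods, and a thin CLI at `exec/tdfe`
(`simulate | pca | td | ktd | benchmark`).

## Worked example

```r
library(tdfe)

set1 <- simulate_planted_tensor(seed = 3)
#> <synthetic_set1> 1000 features (10 concordant + 10 discordant planted), noise sd 0.5

sel <- run_td_workflow(set1$tensor, condition = "discordant")
glance(sel)
#> # A tibble: 1 × 5
#>   n_features n_selected alpha  sigma component
#>        <int>      <int> <dbl>  <dbl> <chr>
#> 1       1000         10  0.01 0.0315 1

attr(sel, "axes")
#>   feature      time condition
#>         1         1         1

confusion_matrix(sel$selected, set1$truth_discordant)
#>      selected
#> truth  no yes
#>   out 990   0
#>   in    0  10
```

The workflow decomposed the 1000 × 4 × 2 tensor, picked the
time-correlated axis and the sign-contrasting condition axis, scanned
the core for the coupled feature component, and selected exactly the
ten planted condition-discordant features: 990 true negatives, no
errors. σ = 0.0315 is the standard deviation of the feature scores
(≈ 1/√1000, as expected for a unit-norm factor); the `axes` attribute
records which components were chosen automatically.

Overlap statistics reproduce published selection-overlap tables from
their printed cells:

```r
overlap_fisher(table = matrix(c(19773, 189, 45, 7), 2))
#>       [,1] [,2]
#> [1,] 19773   45
#> [2,]   189    7
#> odds ratio (conditional MLE) 16.26, sample 16.27, P = 7.15e-07
```

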