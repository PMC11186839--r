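# ctvmm — cell type-specific variance mixed models for single-cell pseudobulk

Most single-cell RNA-seq analyses ask whether a gene's **mean** expression
differs between cell types. `ctvmm` asks a different question: does a
gene's **variation across individuals** differ between cell types? A gene
can be equally expressed on average everywhere yet vary across donors in
only one cell type — a signature of cell type-specific regulation that
neither bulk RNA-seq nor standard differential expression can resolve.
The package is aimed at analysts of population-scale scRNA-seq cohorts
(tens to hundreds of donors) who want calibrated tests and unbiased
variance decompositions at those sample sizes.

## The model

For a gene, the cell type-specific pseudobulk of individual *i* in cell
type *c* is the mean over its n<sub>ic</sub> cells, modeled as

    y_ic = beta_c + alpha_i + Gamma_ic + delta_ic

* `beta_c` — cell-type mean (fixed effect);
* `alpha_i ~ N(0, sigma_alpha^2)` — individual effect shared across cell
  types;
* `Gamma_i. ~ N(0, V)` — cell type-specific individual effect, with V a
  C×C covariance across cell types;
* `delta_ic ~ N(0, nu_ic)` — measurement noise, with
  `nu_ic = sigma_ic^2 / n_ic` estimated from the within-pair
  cell-to-cell variance (not a free parameter).

Nested structures of V: **Hom** (V = 0), **IID** (V = vI), **Free**
(V diagonal), **Full** (V any symmetric matrix; sigma_alpha^2 fixed at 0
for identifiability). The headline test — is interindividual variation
cell type-specific? — compares Free against Hom. Estimators: ML, REML
(block-structured likelihood, O(NC^3), analytic gradients), and
closed-form Haseman–Elston regression. Tests: likelihood-ratio
(chi-square, C df), and Wald F-tests with Fisher-information or
delete-one-jackknife precision matrices, including a mean-differentiation
test. The package also ships structured-missingness imputation (low-rank
SVD completion and EM multivariate-normal), a copy-mask imputation
benchmark, a simulation engine for calibration/power studies, and
transcriptome-level variance-share summaries.

## Worked example

Simulate a cohort of 60 donors with genuinely cell type-specific variance
and test it:

```r
library(ctvmm)

cfg <- sim_config(n_individuals = 60, n_cell_types = 4,
                  structure = "free", sigma_alpha2 = 0.1,
                  V = diag(0.1, 4), seed = 7)
sim <- simulate_ctp(cfg, replicate = 1)

free <- fit_reml(sim$pb, ctmm_spec("free", "CTP"))
hom  <- fit_reml(sim$pb, ctmm_spec("hom",  "CTP"))
free
#> <ctmm_fit> REML / free / CTP: converged (objective -175.8269)
#> <variance_components>
#>   sigma_alpha2: 0.08808
#>   diag(V):      0.17039 0.13401 0.09051 0.03001

lrt_free_vs_hom(free, hom)
#> <ctmm_test> lrt: stat = 67.81, df = 4, p = 6.581e-14

jk <- jackknife_fit(sim$pb, free)
wald_variance_test(free, sim$pb, "jackknife", jack = jk)
#> <ctmm_test> wald_jackknife: stat = 5.977, df = 4/51, p = 0.0005054
```

The fitted shared variance (0.088) and per-cell-type specific variances
(0.03–0.17) scatter around their true values (0.1 each, at N = 60); the
likelihood-ratio test rejects the hypothesis that all interindividual
variance is shared (p ≈ 7e-14), and the more conservative jackknife Wald
test agrees (p ≈ 5e-4). With cell-level input, `aggregate_cells()`,
`apply_missingness()`, `standardize_pseudobulk()` and the imputers take
raw data to the same place — or `run_pipeline()` / the `inst/scripts/ctvmm`
command line does it end to end for every gene, with Bonferroni-corrected
output tables.

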