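---
title: "Partitioning cell type-shared and cell type-specific expression variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning cell type-shared and cell type-specific expression variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Single-cell RNA-seq studies with many donors make it possible to ask not
only whether a gene's *mean* expression differs between cell types, but
whether its *variation across individuals* does. A gene can be equally
expressed on average in every cell type and still vary across donors in
only one of them — a signature of cell type-specific regulation that bulk
RNA-seq cannot resolve, because bulk mixes cell types in donor-specific
proportions.

ctvmm works on pseudobulk summaries of the cell-level data. For a gene,
individual $i$ and cell type $c$, the cell type-specific pseudobulk (CTP)
is the mean over that pair's $n_{ic}$ cells,
$y_{ic} = \frac{1}{n_{ic}}\sum_s y_{ics}$, and the overall pseudobulk (OP)
averages over all of an individual's cells. CTP is modeled as

$$y_{ic} = \beta_c + \alpha_i + \Gamma_{ic} + \delta_{ic},$$

with cell-type means $\beta_c$ (fixed), a shared individual effect
$\alpha_i \sim N(0, \sigma^2_\alpha)$, a cell type-specific individual
effect $\Gamma_{i\cdot} \sim N(0, V)$ with $V$ a $C \times C$ covariance
across cell types, and measurement noise
$\delta_{ic} \sim N(0, \nu_{ic})$. The noise variance is not a free
parameter: it is estimated from the cells as
$\nu_{ic} = \hat\sigma^2_{ic} / n_{ic}$ with $\hat\sigma^2_{ic}$ the
unbiased within-pair sample variance. Averaging many cells makes
$\delta_{ic}$ approximately Gaussian even though single-cell expression is
not, and it lets the model separate true interindividual variation from
sampling noise — something impossible in bulk data. The OP model is the
proportion-weighted mixture of the same components, with
$\mathrm{var}(y_i) = \sigma^2_\alpha + P_i^\top V P_i + \nu_i$.

Four covariance structures are nested: **Hom** ($V = 0$: all
interindividual variance shared), **IID** ($V = vI$: equal specific
variance in every cell type), **Free** ($V$ diagonal), and **Full** ($V$
an arbitrary symmetric matrix). In the Full model $\sigma^2_\alpha$ is
fixed at zero because adding $\lambda J$ to $V$ while subtracting
$\lambda$ from $\sigma^2_\alpha$ leaves the likelihood unchanged; the
identity is unit-tested over a $\lambda$ grid. The central scientific
question — is interindividual variance cell type-specific? — is the Free
vs Hom comparison.

## Estimation

Three estimators are provided.

* **ML / REML** maximize the (restricted) Gaussian likelihood by
  limited-memory quasi-Newton iterations with analytic gradients, with the
  fixed effects profiled out by GLS at every step. The restricted
  likelihood includes $\log|X^\top X|$ so that its value is invariant to
  reparameterizing the fixed design. If the initial attempt fails (an
  optimizer error, a non-finite objective, or an invalid covariance), up
  to 10 random restarts are run, each drawing variance components from
  $|N(0, s^2_y/2)|$ where $s^2_y$ is the sample variance of the
  pseudobulk. An optional Nelder–Mead refinement pass is available but off
  by default. Negative variance components are deliberately permitted —
  constraining them at zero would bias small estimates upward and
  invalidate the chi-square reference of the likelihood-ratio test.
* **HE** (Haseman–Elston) regresses the outer product of OLS-residualized
  pseudobulk, with the known noise $\mathrm{diag}(\nu)$ subtracted, onto
  the covariance pattern of each component by least squares. The normal
  equations are assembled from trace identities, so the $NC \times NC$
  design is never materialized; the fit is closed-form and deterministic.
  It is validated against a naive dense construction in the unit tests.

The CTP covariance is block-diagonal over individuals with blocks
$\sigma^2_\alpha J + V + \mathrm{diag}(\nu_{i\cdot})$, so the likelihood
costs $O(NC^3)$ rather than $O(N^3C^3)$. For the Hom/IID/Free structures
each block is a rank-one update of a diagonal matrix, and the whole
likelihood (and its gradient) vectorizes over individuals in $O(NC)$;
positive definiteness of every block is decided exactly by Sylvester's
criterion on closed-form leading minors, which remains valid when
individual components are negative. The Full model and any configuration
the rank-one form cannot express fall back to per-block Cholesky
factorizations, where a failed factorization rejects the parameter
vector. A blocked extra random effect (e.g., experimental batch) adds
$\tau^2 ZZ^\top$ and is folded in by a Woodbury correction on the
batch-count scale. All fast paths are tested against a dense
multivariate-normal oracle to $10^{-8}$.

## Testing

* **LRT** (Free vs Hom): $2\Delta\ell$ against $\chi^2_C$. Because
  negative components keep the null in the parameter interior, the plain
  $\chi^2_C$ reference is used rather than a boundary mixture; this choice
  may be mildly conservative or liberal in small samples and is the
  reference the calibration suite checks.
* **Wald** test of $\mathrm{diag}(V) = 0$: quadratic form divided by $C$
  against $F(C,\,N - R)$ with $R = 2C + 1$ Free-model parameters. The
  precision of $\hat V_{\mathrm{diag}}$ comes either from the inverse
  observed Fisher information (central-difference Hessian at the optimum)
  or from a **delete-one jackknife**: the model is refitted $N$ times,
  dropping one individual (all its cell types) at a time, warm-started at
  the full-sample optimum, and
  $\widehat{\mathrm{cov}} = \frac{N-1}{N}\sum_i (\hat\theta_{(-i)} -
  \bar\theta)(\hat\theta_{(-i)} - \bar\theta)^\top$. The statistic inverts
  the V-diagonal sub-block of that covariance; a selection-matrix variant
  on the full-parameter precision is available behind a flag.
* **Mean differentiation**: GLS cell-type means under the Free-model
  covariance, tested with the successive-difference contrast against
  $F(C-1,\,N-R)$ with jackknife precision (any full-rank contrast yields
  the same statistic). HE pipelines use OLS for the means.
* **Bonferroni** correction across genes.

## Simulation engine and what it does (not) show

`simulate_ctp()` / `simulate_op()` draw data at the pseudobulk level under
any of the structures. The package-wide default conditions are $C = 4$
equal-proportion cell types, $\beta = 0$, $\sigma^2_\alpha = 0.1$,
Free-model $V = 0.1I$, and true $\nu_{ic} \sim U(0.05, 0.15)$; OP
proportions vary across individuals as Dirichlet draws with concentration
20 (about a 0.09 SD per proportion — realistic between-donor variability).
Estimation error in $\nu$ is emulated by `perturb_nu()`:
$\nu' = \nu(1 \pm x)$ with $x \sim \mathrm{Beta}(2, b)$, independent fair
signs, over the grid $b \in \{20, 10, 5, 3, 2\}$.

Under these conditions the REML LRT on CTP is calibrated at large $N$
(false positive rate within the binomial band around 5% at $N = 1000$),
rejects essentially always under the Free model at $N = 50$, above 80% at
$N = 20$, and CTP is far more powerful than OP — the acceptance suite
recomputes all of these. The generator emulates Gaussian pseudobulk with
known noise variances; it does not emulate count-level sampling,
mean–variance coupling, doublets, or cell-type misassignment, so passing
tests demonstrate correctness of the estimators and tests under the
model's own assumptions, not robustness to every artifact of real data.

One documented limitation surfaced by the noise study: under strong
multiplicative noise in $\nu$ ($b = 3$, a coefficient of variation near
0.45), the REML estimate of each $V_{cc}$ acquires an upward bias of
order $0.2\,\bar\nu$ — entries whose noise variance is understated receive
inflated likelihood weight $1/(V_{cc} + \nu')$. The jackknife covariance
still tracks the sampling variance correctly (verified against the
empirical spread across replicates), but no precision estimate can remove
a bias, so at $N = 100$ the jackknife Wald inflates well above nominal,
while the moment-based HE estimator — linear in the stated $\nu$, hence
mean-unbiased — stays only slightly inflated. The likelihood-ratio test
inflates most of all. Practically: when $\nu$ is itself noisy, HE is the
conservative choice for calibration and REML retains the most power; at
milder noise ($b \ge 10$) all three behave as in the noiseless design.

## Imputation

The cell-count filter ("more than ten cells per pair", configurable to 5
or 20; individuals need at least 100 cells) produces *structured*
missingness: an under-sampled cell type is missing for every gene at
once. Three imputers are provided for the resulting $N \times C$ (or
stacked $N \times CG$) matrices: iterative soft-thresholded SVD completion
(per gene or transcriptome-wide; threshold chosen by 5-fold entry-held-out
cross-validation over a small grid when not given, with a maximum-rank
guard of $\min(\mathrm{dim}) - 1$ so a vanishing threshold still enforces
low rank), and an EM-fitted $C$-variate Gaussian that fills conditional
means per individual. Observed entries are never altered. Imputed noise
variances can come out negative; they are repaired to 0 in OP mode and to
the per-gene, per-cell-type maximum of the observed raw $\nu$ in CTP mode
(so the entry is downweighted rather than trusted). $\nu$ is imputed on
its raw scale, matching those repair semantics. Imputation accuracy is
benchmarked by copy-masking: a fully observed individual receives the
complete missing pattern of a randomly drawn donor until 10% of pairs are
masked, and median correlation/MSE over ten mask replicates are reported
per gene and cell type.

## Numerical choices

* Standardization scales each gene so OP has mean 0 and variance 1
  (sample, $n-1$ convention); CTP values shift and scale with OP, and
  $\nu$ divides by the OP variance (variances transform with the square of
  the data scale). The transform is recorded and invertible.
* Pairs with a single cell are treated as missing (their sample variance
  is undefined) rather than assigned $\nu = 0$.
* Positive definiteness is decided at a $10^{-12}$ minor tolerance on the
  fast path and by Cholesky success elsewhere.
* Optimizer: `optim(method = "L-BFGS-B")`, `factr = 1e5`, at most 500
  iterations, analytic gradients on the block-diagonal paths and central
  differences elsewhere.
* Jackknife refits warm-start at the full-sample optimum, which cuts cost
  and the risk of hopping between local optima; a refit that still fails
  after restarts aborts the test with a named error rather than silently
  dropping the replicate.
* Variance shares on the standardized OP scale are an ANOVA-style
  decomposition: the sample variance of the fitted fixed predictor
  (proportion-weighted cell-type means plus covariates), the batch
  variance, $\sigma^2_\alpha$, the proportion-weighted
  $\sum_c \bar P_c V_{cc}$, and the mean $\nu$, normalized to sum to one.
* Replicate $r$ of any simulation seeds the RNG with `seed + r`, so every
  table in the package is reproducible bit-for-bit from its configuration.

The simulation sizes used by the test suite (up to 1000 replicates at
$N = 1000$ for calibration; 150–200 replicates for noise-robustness and
recovery studies) were chosen to keep Monte-Carlo error well inside the
assertion margins while remaining comfortable to run routinely on a
single core.

## Known limitations

Discrete, pre-assigned cell types are assumed; inferred labels deflate
cell type-specific variance by construction, and continuous trajectories
must be discretized. The Gaussian approximation needs enough cells per
pair (hence the ten-cell rule), and lowly expressed genes may need more.
The Full model's parameter count grows quadratically in $C$ and its
estimates are only useful at large $N$ or aggregated across genes. HE
does not support the blocked batch random effect. The jackknife Wald test
inherits any bias of the underlying estimator, as the noise study above
makes explicit.
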