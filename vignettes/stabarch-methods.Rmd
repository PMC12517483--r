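---
title: "Methods: the stabilizing-selection model of trait architecture and its inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stabilizing-selection model of trait architecture and its inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model, the numerical and design choices, and the
limitations of `stabarch`. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The generative model

A quantitative trait is one projection of a high-dimensional phenotype
under stabilizing selection. Each trait-affecting site experiences
underdominant selection of strength $s$: selection pushes the minor allele
downward regardless of the direction of its effect, with expected
per-generation frequency change
$$E[\Delta q] = -s\,q(1-q)\left(\tfrac12-q\right),$$
while drift contributes variance $q(1-q)/2N(t)$ under a piecewise-constant
history $N(t)$. Mutations arise at rate $\mu$ per site per generation with
$s \sim f(s)$. Conditional on $s$, the effect on the focal trait (in trait
standard deviations) is
$$\beta \mid s \sim N\!\left(0,\; \frac{h^2}{L}\,\frac{k\,s}{4\mu}\right),$$
and the observed association z-score is
$z \mid \beta, q \sim N(\beta\sqrt{2q(1-q)n},\,1)$ at effective sample
size $n$. Hits are the variants with minor allele frequency $\ge 1\%$ and
$|z| > 5.45$ (the two-sided $5\times10^{-8}$ convention,
`significance_threshold()`).

The constant $k$ is defined by self-consistency of the heritability
decomposition
$h^2 = L \int E[2\beta^2 q(1-q)\mid s]\, f(s)\, ds$, giving
$$k = 4\mu \Big/ \int s\, E[2q(1-q)\mid s]\, f(s)\, ds .$$
In the mutation–selection-balance limit $E[2q(1-q)\mid s] \to 4\mu/s$ and
$k \to 1$; for distributions with substantial effectively-neutral mass
$k$ exceeds 1 because heterozygosity saturates while $s$ shrinks. `stabarch`
recomputes $k$ from $f(s)$ and the cached spectra whenever parameters are
built, so `heritability(params)` equals $L \cdot h^2/L$ by construction —
a property the test suite asserts to 1%.

## Frequency spectra: solver and oracles

`present_day_sfs()` discretizes the Wright–Fisher diffusion with influx on
a 400-point logit-spaced frequency grid using exponentially fitted
(Scharfetter–Gummel) finite-volume fluxes. The Péclet numbers
$-2Ns\,[q(1-q)]_{q_j}^{q_{j+1}}$ are available in closed form, so the
discrete steady state tracks Wright's sojourn-time solution essentially to
quadrature accuracy; `equilibrium_sfs()` evaluates that closed form in log
space (stable to $2Ns$ in the thousands) and the two agree under constant
$N$ to relative $L_1$ error below $10^{-3}$ — one of the package's
acceptance checks. Time integration across epochs is implicit Euler with
steps capped at `min(N/50, 25)` generations; the ancient epoch is
initialized at its exact stationary solve. New mutations are injected at
$p_0 = 1/2N$, split log-linearly across the two bracketing grid nodes,
and the closed form uses the same origin frequency, so both solvers
describe the same process (below $p_0$ the influx solution is flat
rather than $\propto 1/q$).

Two independent brute-force oracles guard the solver: a dense discrete
Wright–Fisher transition matrix at small $N$ (`wf_equilibrium_sfs()`,
matched on $2Ns$) and, for ages, a cohort-propagation oracle
(`wf_age_oracle()`).

The cache (`sfs_cache()`) stores, for 121 log-spaced $s$ values plus the
neutral reference column, the spectrum, its folded (minor-allele) version,
the segregating mass and the heterozygosity moment. It is trait-independent;
one cache serves every fit under a given demography and $\mu$. It lives in
memory with optional RDS persistence.

## Demography

The exact history used to build the package's illustrative spectra is a
four-epoch caricature of north-west European demography
(`demography_preset("ukb-default")`): ancestral $N = 14{,}000$; a
bottleneck to $3{,}000$ between generations 2,500 and 2,400 before
present; $N = 10{,}000$ until generation 100; then a large recent epoch
($N = 500{,}000$) standing in for explosive growth. It is a caricature —
the qualitative conclusions that matter here (weakly selected variants
drift to high frequency and great age; strongly selected ones stay rare
and young) are robust to its details, and any two-column text file can be
substituted (`load_demography()`).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| $\mu$ | $1.25\times10^{-8}$ | per site per generation | standard human SNP rate; configurable |
| $z$ threshold | 5.45 | z-score | two-sided $p<5\times10^{-8}$ |
| MAF cutoff | 0.01 | frequency | imputation-quality floor for hits |
| knots of $\log f(s)$ | $-6,-4.5,-3,-1.5$ | $\log_{10} s$ | span the range GWAS hits inform |
| support of $f(s)$ | $[10^{-7}, 10^{-1}]$ | $s$ | hard truncation |
| penalty weight $\lambda$ | 2 | — | recovery sweep (below) |
| optimizer | 8 simplex starts + BFGS polish | — | 5-dim objective with a soft ridge |
| generation time | 28 | years | age conversion only |

## Inference: likelihood, penalty, and an identifiability ridge

`fit_tsd()` maximizes the conditional likelihood of observed
$(\mathrm{maf}_i, |z_i|)$ pairs given ascertainment,
$-\sum_i \log[\,\text{hit density}(q_i,z_i)/\Pr(\text{hit})\,]$, over the
four knot log-densities and $\log_{10} h^2/L$; $L$ is then estimated by
matching the expected number of hits to the observed count (so
`expected_hits()` at the fit reproduces the data's hit count exactly).
`fit_ssd()` shares one $f(s)$ across traits and alternates shared-knot
updates with per-trait $h^2/L$ line searches.

Hits carry almost no information about $f(s)$ mass at effectively neutral
$s \lesssim 10^{-5}$ (effects too small to reach significance) or at very
strong $s \gtrsim 10^{-2}$ (frequencies below the MAF cutoff). This is not
a numerical nuisance but a structural ridge: invisible neutral mass
renormalizes $k$ and trades off exactly against $h^2/L$ and $L$. The tail
penalty $\lambda(\text{slope}_{\text{low}}^2 +
\text{slope}_{\text{high}}^2)$ on the log-density extrapolation slopes at
the terminal knots pins the tails to the flat members of the spline
family. Consequences, verified in development and enforced by the test
suite:

- Unpenalized fits occasionally run far along the ridge (heritability per
  site wrong by large factors with correspondingly inflated target
  sizes). $\lambda$ was chosen by a small recovery sweep over
  $\{0, 0.25, 0.5, 1, 2, 4\}$ at 500-hit replicates; $\lambda \ge 1$
  removes the excursions and $\lambda = 2$ is the default.
- Recovery of $h^2/L$ and $L$ is unbiased only when the generating
  $f(s)$ is itself compatible with the tail regularization, i.e. has flat
  log-density tails. The shipped presets (`ssd-like`, `weak`, `strong`)
  are therefore constructed as zero-tail-slope members of the spline
  family; the `ssd-like` preset keeps the shape characteristic of
  polygenic traits (most mass at weak selection comparable to drift,
  roughly 10% of mass above $s = 10^{-3}$, spanning several decades). For
  generating distributions with steep tails the estimator remains
  consistent for the *observable* architecture but reports $h^2/L$ biased
  by the prior's opinion of the invisible mass — an inherent limit of
  ascertained-hit inference, not a removable defect.

The optimizer initializes $f(s)$ at the broad `ssd-like` shape and
$h^2/L$ from a median-$z^2$ moment heuristic, then runs eight jittered
Nelder–Mead starts polished by BFGS. Jitters come from a private RNG
stream that restores the caller's seed state, so resampling procedures
built on refits (bootstrap, cross-validation) stay independent of the
optimizer's internals.

`bootstrap_fit()` refits bootstrap replicates warm-started from the
point estimate and reports pointwise 5–95% envelopes of the $f(s)$ CDF
plus percentile CIs for $h^2/L$ and $L$. Two resampling schemes are
provided: block resampling of hits (the default) and a parametric
scheme that simulates replicate hit tables from the fitted model. A
caveat established during development and reflected in the test suite:
because the fit is sensitive to a handful of extreme (rare, large-z)
hits, both schemes somewhat underestimate the estimator's sampling
spread (bootstrap-to-sampling sd ratios around 0.7), so envelope
coverage of the true $f(s)$ CDF runs below nominal; the parametric
scheme behaves better and is what the package's own calibration
experiments use. Envelopes should be read as lower bounds on
uncertainty.

## Model criticism

The residual p-value of hit $i$ is
$\Pr(|z|>z_i \mid |z|>5.45, q_i, \text{model})$ — a probability integral
transform that is Uniform(0,1) exactly when the model that generated the
data is the one being scored (the suite checks this calibration both
in-sample and under 90/10 block cross-validation). Skew toward 0 means
observed z-scores run hotter than modelled. Per-trait goodness of fit is
a KS test against uniformity on the cross-validated residuals;
across-trait decisions use Benjamini–Hochberg at FDR 0.05
(`bh_fdr()`); single anomalous hits are flagged at the Bonferroni level
(`flag_outliers()`).

Two heuristic baselines are fitted to the same hits by conditional
maximum likelihood on $z \mid q$ under identical ascertainment:
the alpha-model, $\beta \mid q \sim N(0, \sigma^2 (2q(1-q))^\alpha)$, and
the normal-effects model ($\alpha = 0$). Because the stabilizing-selection
architecture mixes effect scales across several decades of $s$, its
conditional z distributions are strongly heavier-tailed than any single
Gaussian; the baselines under-predict both the many near-threshold hits
and the minority of much stronger ones, and their residual p-values fail
uniformity on data simulated from the main model.

The heavy tails also set a detection floor for planted outliers: doubling
a *median* common hit's z-score (say $6.5 \to 13$) produces a residual
p-value around $10^{-1}$ and is structurally undetectable, while doubling
the *strongest* common signal reproduces the FTO situation and is what
`spike_outlier()` implements.

## Allele ages

`simulate_ages()` runs forward origin-stamped trajectories (deterministic
underdominant update plus binomial sampling at $2N(t)$), with origin times
drawn proportional to the mutational influx $2N(t)\mu$ over a horizon of
$4 N_\text{ancestral}$ generations, and keeps alleles segregating at
present. Ages are therefore truncated at the horizon, and every oracle
comparison uses the same truncation. `predicted_hit_ages()` draws each
hit's $s$ from its posterior given frequency *and* observed z-score (the
default: hits are ascertained for large effects, so the frequency-only
posterior — also available with `use_z = FALSE` — is dominated by
effectively-neutral mass and predicts almost no age shift), then samples
ages conditioned on the hit's MAF bin. Simulations run in a
diffusion-rescaled frame (`scale_demography()`; `predicted_hit_ages()`
defaults to 1/10 of the true sizes, and the packaged experiments use
1/20, with $s$ scaled up and ages scaled back), which preserves the
distributions of interest while keeping trajectory counts tractable; the
neutral simulator is validated against the matrix oracle's mean age
within 15%. Years use 28 years per generation.

## Synthetic data

`simulate_trait()` draws the full hierarchy: the number of segregating
causal sites is Binomial($L$, mean segregating probability); $s$ is drawn
from the segregation-weighted $f(s)$; $q$ by inverse-CDF from the cached
spectrum (uniform within grid cells); $\beta$, $z$ and the ascertainment
flag follow the model; consecutive variants are chunked into ~1,700
blocks emulating genome/LD blocks for cross-validation and block
bootstrap. Panels (`panel_preset()`) reproduce the main model axes (weak
vs strong selection, high vs low $h^2/L$, small vs large $L$) and a
UK-Biobank-shaped panel (95 traits, 100–1,760 expected hits per trait,
mean near 495, $n$ up to $4.6\times10^5$).

What the generator does *not* emulate: linkage disequilibrium within
blocks (variants are exchangeable), winner's-curse noise in per-hit
effect estimates beyond the Gaussian z model, imputation error beyond the
hard MAF cutoff, assortative mating, and genetic correlations between
traits. Passing recovery and calibration tests on these synthetic data
therefore demonstrates the correctness and internal consistency of the
inference machinery — not robustness to the full messiness of real GWAS
summary statistics.

## Numerical choices and degenerate inputs

- Frequency grid: 400 logit-spaced nodes on $[10^{-7}, 1-10^{-7}]$,
  symmetric about $1/2$; weights are cell widths summing exactly to 1.
  Doubling the grid changes moments by under $10^{-3}$ relative (tested).
- All spectrum integrals are computed in log space with exponentially
  fitted segment quadrature, so $2Ns$ up to thousands cannot overflow.
- $f(s)$ integrals use trapezoid masses on the 121-point $\log_{10} s$
  grid, renormalized to sum exactly to 1; fits thin this grid two-fold
  for speed and the final reported parameters are rebuilt on the full
  grid.
- Likelihood evaluation interpolates the folded spectrum log-linearly in
  log-MAF; the ascertainment integral uses a dedicated 240-point log
  grid on $[0.01, 0.5]$.
- Degenerate inputs are rejected with informative errors: non-monotone
  demographies, $N \le 1$, hits outside the ascertainment region,
  implied $h^2 \ge 1$, bootstrap with $B < 20$, cross-validation without
  blocks or with fewer blocks than folds, and age simulations in which no
  allele survives to the present.
- Adding a constant to all four knot values leaves $f(s)$ unchanged; the
  parameterization removes this flat direction by centering, and the
  penalty is invariant to it.

## Problem sizes used by the tests and the acceptance script

Recovery and calibration experiments use 20 replicate traits of ~500
expected hits at $n = 3\times10^5$ with bootstrap $B = 24$ and 10-fold
block cross-validation; scaling-collapse experiments use trait pairs with
~1,500 expected hits; age experiments use 100,000 trajectory origins per
selection bin in the 1/20-rescaled frame and a $N = 200$ matrix oracle.
These sizes were chosen so the full suite completes comfortably on a
single core while leaving the Monte-Carlo error well below each
criterion's tolerance.

## Known limitations

- $f(s)$ outside $s \in [10^{-5}, 10^{-2}]$ is regularization-driven, and
  $h^2/L$ and $L$ inherit that dependence (see the ridge discussion).
  Estimates should be read jointly with the bootstrap envelopes.
- The SSD fit weights traits implicitly by hit count (summed per-hit
  log-likelihoods).
- KS goodness-of-fit p-values do not account for parameters estimated on
  the training blocks; residual calibration is verified under the exact
  cross-validation design used for reporting.
- Observed MAF is treated as exact; sampling noise in allele frequency is
  ignored.
- The block structure is exchangeable; real LD induces correlation within
  blocks that the bootstrap approximates only block-wise.
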