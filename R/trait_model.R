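#' Genome-wide significance threshold on the z scale
#'
#' The absolute z-score whose two-sided normal tail probability equals
#' `p`; the conventional p < 5e-8 corresponds to |z| > 5.45.
#'
#' @param p two-sided p-value threshold.
#' @return Positive z threshold.
#' @examples
#' round(significance_threshold(), 2)  # 5.45
#' @export
significance_threshold <- function(p = 5e-8) {
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Parameters of a trait's generative architecture
#'
#' Bundles everything needed to evaluate the generative model for one
#' trait: the distribution of selection coefficients f(s), the
#' heritability per site h2/L (the fundamental effect-size scaling
#' factor), the mutational target size L, the GWAS effective sample size
#' n, the mutation rate, and the ascertainment region (minor allele
#' frequency at least `maf_min` and absolute z-score above `z_thresh`).
#' The scaling constant k is recomputed from f(s) and the cached spectra
#' whenever parameters are constructed, so the heritability decomposition
#' h2 = L * (h2/L) holds by construction.
#'
#' @param fs a [selection_density()].
#' @param h2_over_L heritability per site (> 0).
#' @param L mutational target size in sites (>= 1).
#' @param n GWAS effective sample size.
#' @param cache an [sfs_cache()] for the demography and mutation rate.
#' @param z_thresh absolute z-score threshold of genome-wide significance
#'   (5.45 corresponds to the two-sided p < 5e-8 convention).
#' @param maf_min minor-allele-frequency cutoff of the ascertainment
#'   region.
#' @return An object of class `trait_params`.
#' @export
trait_params <- function(fs, h2_over_L, L, n, cache,
                         z_thresh = 5.45, maf_min = 0.01) {
  stopifnot(inherits(fs, "selection_density"), inherits(cache, "sfs_cache"),
            h2_over_L > 0, L >= 1, n > 0, z_thresh > 0,
            maf_min > 0, maf_min < 0.5)
  h2 <- h2_over_L * L
  if (h2 >= 1)
    stop(sprintf("implied h2 = %.3g >= 1: inconsistent (h2/L, L)", h2))
  k <- compute_k(fs, cache)
  s <- cache$s_values[-1L]
  mass <- fs_mass(fs, s)
  # fine ascertainment grid on [maf_min, 1/2] for significance integrals
  ma <- exp(seq(log(maf_min), log(0.5), length.out = 240L))
  we <- c(maf_min, (ma[-length(ma)] + ma[-1L]) / 2, 0.5)
  wa <- diff(we)
  lam_asc <- .interp_lambda_fold(cache, ma)[, -1L, drop = FALSE]
  structure(
    list(fs = fs, h2_over_L = h2_over_L, L = L, n = n, mu = cache$mu,
         k = k, z_thresh = z_thresh, maf_min = maf_min,
         s = s, mass = mass, cache = cache,
         asc_maf = ma, asc_w = wa, asc_lambda = lam_asc),
    class = "trait_params")
}

#' Variance of the trait effect given the selection coefficient
#'
#' In trait-standard-deviation units, beta | s ~ N(0, (h2/L) k s / (4 mu));
#' effectively neutral sites (s = 0) have vanishing effects.
#'
#' @param s selection coefficient(s).
#' @param params a [trait_params()].
#' @return Variance of beta given s.
#' @export
beta_variance_given_s <- function(s, params) {
  stopifnot(inherits(params, "trait_params"))
  params$h2_over_L * params$k * s / (4 * params$mu)
}

#' Heritability implied by trait parameters
#'
#' Numerically integrates the decomposition
#' h2 = L * Int E[2 beta^2 q(1-q) | s] f(s) ds over the cached spectra.
#' By the definition of k this equals L * (h2/L) up to quadrature error.
#'
#' @param params a [trait_params()].
#' @return Scalar h2 in (0, 1).
#' @export
heritability <- function(params) {
  stopifnot(inherits(params, "trait_params"))
  h2 <- params$L * sum(params$mass *
                         beta_variance_given_s(params$s, params) *
                         params$cache$e2pq[-1L])
  if (h2 >= 1) stop("implied heritability >= 1: inconsistent parameters")
  h2
}

# per-s marginal z sd at given maf and sample size: z | s,q is centered
# normal with variance 1 + 2q(1-q) n Var(beta|s)
.z_sd_matrix <- function(m, params, n = params$n) {
  a <- 2 * m * (1 - m) * n                       # length(m)
  sig2 <- beta_variance_given_s(params$s, params)  # length(s)
  sqrt(1 + outer(a, sig2))
}

#' Joint density of (minor allele frequency, |z|) for GWAS hits
#'
#' The un-normalized joint density of observing a segregating variant at
#' minor allele frequency `q` with absolute z-score `z`, marginalized over
#' the selection coefficient and the effect size: the folded frequency
#' spectrum weighs each s, beta | s is centered normal, and
#' z | beta, q ~ N(beta sqrt(2q(1-q) n), 1), folded to |z|. Units are
#' per site, so integrating over the ascertainment region gives
#' [prob_significant()].
#'
#' @param q minor allele frequencies in (0, 0.5] (vectorized).
#' @param z absolute z-scores (vectorized, recycled against `q`).
#' @param params a [trait_params()].
#' @param n effective sample size(s); defaults to the trait-level n.
#' @return Numeric vector of densities.
#' @export
hit_density <- function(q, z, params, n = params$n) {
  stopifnot(inherits(params, "trait_params"))
  kk <- max(length(q), length(z))
  q <- rep_len(q, kk); z <- rep_len(z, kk); n <- rep_len(n, kk)
  lamf <- .interp_lambda_fold(params$cache, q)[, -1L, drop = FALSE]
  a <- 2 * q * (1 - q) * n
  sig2 <- beta_variance_given_s(params$s, params)
  v <- sqrt(1 + outer(a, sig2))
  dens <- (2 * stats::dnorm(z / v) / v) * lamf
  as.numeric(dens %*% params$mass)
}

#' Per-site probability that a variant is a genome-wide significant hit
#'
#' Integrates [hit_density()] over the ascertainment region
#' (maf >= maf_min, |z| > z_thresh). Includes the probability of
#' segregating at an ascertainable frequency, so multiplying by L gives
#' the expected hit count.
#'
#' @param params a [trait_params()].
#' @param n effective sample size; defaults to the trait-level n.
#' @return Scalar per-site probability.
#' @export
prob_significant <- function(params, n = params$n) {
  stopifnot(inherits(params, "trait_params"))
  v <- .z_sd_matrix(params$asc_maf, params, n)
  tail2 <- 2 * stats::pnorm(params$z_thresh / v, lower.tail = FALSE)
  per_s <- colSums(params$asc_w * params$asc_lambda * tail2)
  sum(per_s * params$mass)
}

#' Expected number of genome-wide significant hits
#'
#' @param params a [trait_params()].
#' @return L times the per-site significance probability.
#' @export
expected_hits <- function(params) {
  params$L * prob_significant(params)
}

#' Conditional tail probability of |z| given frequency and ascertainment
#'
#' Pr(|z| > z0 | |z| > z_thresh, maf = q) under the model: the residual
#' p-value of an observed hit. Uniform on (0, 1] over hits when the model
#' that generated them is the one being evaluated.
#'
#' @param z0 absolute z-scores (>= z_thresh).
#' @param q minor allele frequencies (vectorized with z0).
#' @param params a [trait_params()].
#' @param n effective sample size(s).
#' @return Tail probabilities in (0, 1].
#' @export
conditional_z_tail_given_q <- function(z0, q, params, n = params$n) {
  stopifnot(inherits(params, "trait_params"))
  if (any(z0 < params$z_thresh - 1e-9))
    stop("z0 below the significance threshold ", params$z_thresh)
  kk <- max(length(z0), length(q))
  z0 <- rep_len(z0, kk); q <- rep_len(q, kk); n <- rep_len(n, kk)
  lamf <- .interp_lambda_fold(params$cache, q)[, -1L, drop = FALSE]
  a <- 2 * q * (1 - q) * n
  sig2 <- beta_variance_given_s(params$s, params)
  v <- sqrt(1 + outer(a, sig2))
  wgt <- lamf * matrix(params$mass, kk, length(params$s), byrow = TRUE)
  num <- rowSums(wgt * stats::pnorm(z0 / v, lower.tail = FALSE))
  den <- rowSums(wgt * stats::pnorm(params$z_thresh / v, lower.tail = FALSE))
  pmin(num / den, 1)
}

#' Posterior distribution of the selection coefficient given frequency
#'
#' Among segregating causal variants observed at minor allele frequency q,
#' the selection coefficient has posterior mass proportional to
#' lambda_fold(q | s) f(s): higher frequencies favour weaker selection.
#'
#' @param q a single minor allele frequency in (0, 0.5].
#' @param fs a [selection_density()].
#' @param cache an [sfs_cache()].
#' @return data.frame with columns `s` and `mass` (summing to 1).
#' @export
conditional_s_given_q <- function(q, fs, cache) {
  stopifnot(length(q) == 1L, q > 0, q <= 0.5)
  s <- cache$s_values[-1L]
  mass <- fs_mass(fs, s)
  lamf <- as.numeric(.interp_lambda_fold(cache, q)[, -1L])
  post <- mass * lamf
  data.frame(s = s, mass = post / sum(post))
}

#' Conditional distribution of the squared effect size given frequency
#'
#' beta^2 at a causal variant of frequency q is a mixture of scaled
#' chi-squared(1) distributions over the posterior of s given q. In units
#' of h2/L the mixture scales are k s / (4 mu), independent of h2/L: the
#' scaled distribution is shared by all traits with the same f(s).
#'
#' @param q a single minor allele frequency.
#' @param params a [trait_params()].
#' @param scaled if `TRUE`, beta^2 is measured in units of h2/L.
#' @return A list with `density(b2)` and `cdf(b2)` functions and the
#'   mixture components (`s`, `mass`, `scale`).
#' @export
conditional_beta2_given_q <- function(q, params, scaled = FALSE) {
  stopifnot(inherits(params, "trait_params"))
  post <- conditional_s_given_q(q, params$fs, params$cache)
  scl <- beta_variance_given_s(post$s, params)
  if (scaled) scl <- scl / params$h2_over_L
  dens <- function(b2) {
    vapply(b2, function(v)
      sum(post$mass * stats::dchisq(v / scl, df = 1) / scl), numeric(1L))
  }
  cdf <- function(b2) {
    vapply(b2, function(v)
      sum(post$mass * stats::pchisq(v / scl, df = 1)), numeric(1L))
  }
  list(density = dens, cdf = cdf, s = post$s, mass = post$mass, scale = scl)
}

#' Proportion of heritability explained by genome-wide significant hits
#'
#' Expected contribution E[2 beta^2 q(1-q)] accumulated over the
#' ascertainment region, divided by total heritability. Uses the joint
#' normality of (beta, z) given (s, q) in closed form. Increases with
#' h2/L (better-powered traits capture more of their heritability) and is
#' invariant to L.
#'
#' @param params a [trait_params()].
#' @param n effective sample size.
#' @return Fraction in (0, 1).
#' @export
prop_h2_explained_by_hits <- function(params, n = params$n) {
  stopifnot(inherits(params, "trait_params"))
  m <- params$asc_maf
  a <- 2 * m * (1 - m) * n
  sig2 <- beta_variance_given_s(params$s, params)
  v2 <- 1 + outer(a, sig2)
  tau <- params$z_thresh / sqrt(v2)
  tail_mass <- 2 * stats::pnorm(tau, lower.tail = FALSE)
  tail_z2 <- 2 * (stats::pnorm(tau, lower.tail = FALSE) +
                    tau * stats::dnorm(tau))
  sig2m <- matrix(sig2, length(m), length(sig2), byrow = TRUE)
  am <- matrix(a, length(m), length(sig2))
  # E[beta^2 1{|z|>t}] = (sig2/v2) P(|z|>t) + (sig2^2 a / v2) E[Z^2 1{|Z|>tau}]
  eb2 <- (sig2m / v2) * tail_mass + (sig2m^2 * am / v2) * tail_z2
  contrib <- colSums(params$asc_w * params$asc_lambda * (am / n) * eb2)
  num <- sum(contrib * params$mass)   # per-site E[2 beta^2 q(1-q); sig]
  num / params$h2_over_L
}

#' @export
print.trait_params <- function(x, ...) {
  cat("Trait architecture parameters\n")
  cat(sprintf("  h2/L = %.3g, L = %.3g (h2 = %.3g), n = %.3g\n",
              x$h2_over_L, x$L, x$h2_over_L * x$L, x$n))
  cat(sprintf("  f(s): %s; k = %.3f; mu = %g\n", x$fs$label, x$k, x$mu))
  cat(sprintf("  ascertainment: maf >= %g, |z| > %g\n",
              x$maf_min, x$z_thresh))
  invisible(x)
}
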