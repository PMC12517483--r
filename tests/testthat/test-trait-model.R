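test_that("significance threshold matches the 5e-8 convention", {
  expect_equal(round(significance_threshold(5e-8), 2), 5.45)
})

test_that("effect-size variance scales as (h2/L) k s / (4 mu)", {
  cache <- fixture_cache("ukb")
  p <- trait_params(selection_density_preset("ssd-like"), 3e-8, 1e6, 3e5,
                    cache)
  expect_equal(beta_variance_given_s(1e-3, p),
               3e-8 * p$k * 1e-3 / (4 * p$mu))
  # with k = 1 the benchmark value is 6e-4 at these parameters
  expect_equal(beta_variance_given_s(1e-3, p) / p$k, 6e-4)
  p2 <- trait_params(selection_density_preset("ssd-like"), 6e-8, 1e6, 3e5,
                     cache)
  expect_equal(beta_variance_given_s(1e-3, p2),
               2 * beta_variance_given_s(1e-3, p))
  expect_equal(beta_variance_given_s(0, p), 0)
})

test_that("heritability decomposition is conserved", {
  cache <- fixture_cache("ukb")
  p <- trait_params(selection_density_preset("ssd-like"), 3e-8, 1e7, 3e5,
                    cache)
  expect_equal(heritability(p), 0.30, tolerance = 0.01)
  p2 <- trait_params(selection_density_preset("ssd-like"), 3e-8, 2e7, 3e5,
                     cache)
  expect_equal(heritability(p2), 2 * heritability(p), tolerance = 1e-9)
  # k renormalizes: same h2 for very different f(s)
  p3 <- trait_params(selection_density_point(1e-3), 3e-8, 1e7, 3e5, cache)
  expect_equal(heritability(p3), heritability(p), tolerance = 0.01)
  expect_error(trait_params(selection_density_preset("ssd-like"),
                            3e-8, 1e9, 3e5, cache), "h2")
})

test_that("hit density is a proper mixture with heavier-than-normal tails", {
  cache <- fixture_cache("ukb")
  p <- trait_params(selection_density_preset("ssd-like"), 3e-8, 1e6, 3e5,
                    cache)
  q <- c(0.02, 0.1, 0.3, 0.5)
  z <- c(5.5, 7, 10, 20)
  d <- hit_density(q, z, p)
  expect_true(all(d >= 0) && all(is.finite(d)))
  # at fixed q, compare the mixture tail with the single Gaussian of
  # matched conditional variance: the s-mixture must be heavier far out
  q0 <- 0.2
  sig2 <- beta_variance_given_s(p$s, p)
  v2 <- 1 + 2 * q0 * (1 - q0) * p$n * sig2
  lamf <- stabarch:::.interp_lambda_fold(cache, q0)[, -1L]
  w <- lamf * p$mass / sum(lamf * p$mass)
  v2_match <- sum(w * v2)            # same E[z^2 | q]
  for (z0 in c(15, 25)) {
    mix_tail <- sum(w * pnorm(z0 / sqrt(v2), lower.tail = FALSE))
    expect_gt(mix_tail, pnorm(z0 / sqrt(v2_match), lower.tail = FALSE))
  }
})

test_that("significance probability behaves as an ascertainment integral", {
  cache <- fixture_cache("ukb")
  fs <- selection_density_preset("ssd-like")
  ps <- vapply(c(1e-8, 3e-8, 6e-8), function(h2L)
    prob_significant(trait_params(fs, h2L, 1e6, 3e5, cache)), numeric(1L))
  expect_true(all(diff(ps) > 0))   # more heritability per site, more hits
  pL <- trait_params(fs, 3e-8, 1e6, 3e5, cache)
  pL2 <- trait_params(fs, 3e-8, 2e6, 3e5, cache)
  expect_equal(prob_significant(pL), prob_significant(pL2))  # per site
  expect_equal(expected_hits(pL2), 2 * expected_hits(pL))
  # null limit: pure noise z, ascertainable frequency mass
  p0 <- trait_params(fs, 1e-13, 1e6, 3e5, cache)
  seg_asc <- sum(p0$asc_w * (p0$asc_lambda %*% p0$mass))
  expect_equal(prob_significant(p0),
               2 * pnorm(5.45, lower.tail = FALSE) * seg_asc,
               tolerance = 1e-3)
})

test_that("conditional z tail is a valid survival function", {
  cache <- fixture_cache("ukb")
  p <- trait_params(selection_density_preset("ssd-like"), 3e-8, 1e6, 3e5,
                    cache)
  expect_equal(conditional_z_tail_given_q(5.45, 0.1, p), 1)
  zs <- c(5.45, 6, 8, 12, 40, 200)
  tails <- conditional_z_tail_given_q(zs, rep(0.1, length(zs)), p)
  expect_true(all(diff(tails) < 0))
  expect_lt(tails[length(tails)], 1e-6)
  expect_error(conditional_z_tail_given_q(5, 0.1, p), "threshold")
})

test_that("posterior of s given frequency shifts down as frequency rises", {
  cache <- fixture_cache("ukb")
  fs <- selection_density_preset("ssd-like")
  post_rare <- conditional_s_given_q(0.01, fs, cache)
  post_common <- conditional_s_given_q(0.5, fs, cache)
  expect_equal(sum(post_rare$mass), 1)
  # stochastic ordering of the CDFs
  expect_true(all(cumsum(post_common$mass) >=
                    cumsum(post_rare$mass) - 1e-12))
  expect_gt(sum(cumsum(post_common$mass) - cumsum(post_rare$mass)), 0.5)
  pm <- conditional_s_given_q(0.1, selection_density_point(1e-3), cache)
  expect_equal(pm$mass[which.min(abs(pm$s - 1e-3))], 1, tolerance = 1e-12)
})

test_that("squared effects given frequency are scale-invariant in h2/L", {
  cache <- fixture_cache("ukb")
  fs <- selection_density_preset("ssd-like")
  pa <- trait_params(fs, 1e-8, 1e6, 3e5, cache)
  pb <- trait_params(fs, 6e-8, 1e6, 3e5, cache)
  ca <- conditional_beta2_given_q(0.1, pa, scaled = TRUE)
  cb <- conditional_beta2_given_q(0.1, pb, scaled = TRUE)
  grid <- 10^seq(-2, 6, length.out = 80L)
  expect_lt(max(abs(ca$cdf(grid) - cb$cdf(grid))), 1e-6)
  # point-mass f(s): exactly a scaled chi-squared(1)
  pp <- trait_params(selection_density_point(1e-3), 3e-8, 1e6, 3e5, cache)
  cp <- conditional_beta2_given_q(0.1, pp)
  scl <- beta_variance_given_s(cp$s[cp$mass > 0], pp)
  b2 <- c(0.1, 0.5, 1, 2) * scl
  expect_equal(cp$cdf(b2), pchisq(b2 / scl, 1), tolerance = 1e-12)
})

test_that("heritability explained by hits rises with h2/L, not with L", {
  cache <- fixture_cache("ukb")
  fs <- selection_density_preset("ssd-like")
  props <- vapply(c(1e-8, 3e-8, 6e-8), function(h2L)
    prop_h2_explained_by_hits(trait_params(fs, h2L, 1e6, 3e5, cache)),
    numeric(1L))
  expect_true(all(diff(props) > 0))
  expect_true(all(props > 0 & props < 1))
  expect_equal(
    prop_h2_explained_by_hits(trait_params(fs, 3e-8, 2e6, 3e5, cache)),
    props[2L])
  expect_lt(prop_h2_explained_by_hits(
    trait_params(fs, 3e-8, 1e6, 1e3, cache)), 0.01)
})

test_that("simulated hits agree with the analytic hit density", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 7L)
  hits <- sim$hits
  p <- sim$params
  # expected cell probabilities by quadrature: maf bins x z bins
  maf_breaks <- c(0.01, 0.03, 0.08, 0.2, 0.35, 0.5)
  z_breaks <- c(5.45, 6, 6.8, 8.5, Inf)
  ma <- p$asc_maf
  wa <- p$asc_w
  sig2 <- beta_variance_given_s(p$s, p)
  v <- sqrt(1 + outer(2 * ma * (1 - ma) * p$n, sig2))
  probs <- matrix(0, length(maf_breaks) - 1L, length(z_breaks) - 1L)
  for (i in seq_len(nrow(probs))) {
    in_bin <- ma > maf_breaks[i] & ma <= maf_breaks[i + 1L]
    for (j in seq_len(ncol(probs))) {
      taildiff <- pnorm(z_breaks[j] / v, lower.tail = FALSE) -
        pnorm(z_breaks[j + 1L] / v, lower.tail = FALSE)
      probs[i, j] <- sum((colSums((wa * in_bin) * p$asc_lambda *
                                    taildiff)) * p$mass)
    }
  }
  probs <- probs / sum(probs)
  obs <- table(cut(hits$maf, maf_breaks), cut(hits$abs_z, z_breaks))
  chs <- suppressWarnings(chisq.test(as.vector(obs), p = as.vector(probs)))
  expect_gt(chs$p.value, 0.01)
})
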