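test_that("residual p-values are boundary-correct and calibrated", {
  sim <- fixture_sim(seed = 71L)
  p <- sim$params
  expect_equal(residual_pvalue(5.45, 0.2, p), 1)
  rp <- residual_pvalue(c(5.45, 6, 7, 9), rep(0.2, 4), p)
  expect_true(all(diff(rp) < 0))
  expect_error(residual_pvalue(5.2, 0.2, p), "threshold")
  # probability integral transform: uniform under the generating model
  res <- residual_pvalue(sim$hits$abs_z, sim$hits$maf, p,
                         n = sim$hits$n_eff)
  expect_gt(ks_uniform(res)$p, 0.01)
})

test_that("ks_uniform matches the closed form and a manual computation", {
  n <- 50L
  grid_p <- (seq_len(n) - 0.5) / n
  expect_equal(ks_uniform(grid_p)$D, 0.5 / n, tolerance = 1e-12)
  low <- rep(0.001, 20L)
  expect_gt(ks_uniform(low)$D, 0.99)
  expect_lt(ks_uniform(low)$p, 1e-10)
  set.seed(8)
  for (r in 1:3) {
    x <- sort(runif(97L))
    manual <- max(pmax(seq_along(x) / length(x) - x,
                       x - (seq_along(x) - 1L) / length(x)))
    expect_equal(ks_uniform(x)$D, manual, tolerance = 1e-12)
  }
})

test_that("BH selection controls the FDR", {
  expect_length(bh_fdr(rep(1, 95L)), 0L)
  ps <- c(t1 = 1e-6, stats::setNames(runif(94L, 0.2, 1),
                                     paste0("t", 2:95)))
  expect_true("t1" %in% bh_fdr(ps))
  set.seed(13)
  fdr <- replicate(200L, {
    rej <- bh_fdr(runif(95L))
    length(rej) > 0L   # all-null: any rejection is a false discovery
  })
  expect_lt(mean(fdr), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("outlier flagging finds a planted FTO-like signal", {
  sim <- fixture_sim(seed = 81L)
  rep0 <- insample_residuals(sim$hits, sim$params)
  expect_identical(nrow(flag_outliers(rep0[integer(0L), ])), 0L)
  # no outliers expected on clean self-simulated data
  expect_lte(nrow(flag_outliers(rep0)), 1L)
  spiked <- spike_outlier(sim$hits, factor = 3, seed = 3L)
  target <- attr(spiked, "spiked_snp")
  rep1 <- insample_residuals(spiked, sim$params)
  flagged <- flag_outliers(rep1)
  expect_true(target %in% flagged$snp)
  expect_identical(spike_outlier(sim$hits, 1)$abs_z, sim$hits$abs_z)
})

test_that("cross-validated residuals score every hit exactly once", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 91L)
  ctrl <- fit_control(n_starts = 1L, maxit = 150L, polish_maxit = 0L)
  rep1 <- crossval_residuals(sim$hits, cache, n_folds = 5L, seed = 2L,
                             control = ctrl)
  expect_equal(nrow(rep1), nrow(sim$hits))
  expect_true(all(rep1$residual_p > 0 & rep1$residual_p <= 1))
  expect_setequal(unique(rep1$fold), 1:5)
  rep2 <- crossval_residuals(sim$hits, cache, n_folds = 5L, seed = 2L,
                             control = ctrl)
  expect_identical(rep1$residual_p, rep2$residual_p)
  few_blocks <- hit_table(sim$hits$snp, sim$hits$maf, sim$hits$abs_z,
                          sim$hits$n_eff,
                          block = rep(1:3, length.out = nrow(sim$hits)))
  expect_error(crossval_residuals(few_blocks, cache, n_folds = 10L),
               "fewer blocks")
  no_blocks <- hit_table(sim$hits$snp, sim$hits$maf, sim$hits$abs_z,
                         sim$hits$n_eff)
  expect_error(crossval_residuals(no_blocks, cache), "block")
})

test_that("alpha-model recovery and reduction to the normal model", {
  # simulate from the alpha-model itself: maf from a convenient spread,
  # beta | q ~ N(0, sigma2 (2q(1-q))^alpha), z | beta ~ N(beta sqrt(a), 1)
  sim_alpha <- function(alpha, sigma2, n_target, seed) {
    set.seed(seed)
    out <- NULL
    while (is.null(out) || nrow(out) < n_target) {
      maf <- 10^runif(4e4, -2, log10(0.5))
      a <- 2 * maf * (1 - maf)
      beta <- rnorm(length(maf), 0, sqrt(sigma2 * a^alpha))
      z <- rnorm(length(maf), beta * sqrt(a * 3e5), 1)
      keep <- abs(z) > 5.45
      out <- rbind(out, data.frame(maf = maf[keep], z = abs(z)[keep]))
    }
    out <- out[seq_len(n_target), ]
    hit_table(paste0("v", seq_len(n_target)), out$maf, out$z, 3e5)
  }
  hits <- sim_alpha(alpha = -0.4, sigma2 = 2e-4, 500L, seed = 5L)
  fit <- fit_alpha_model(hits)
  expect_lt(abs(fit$alpha - (-0.4)), 0.2)
  res <- residuals(fit, hits)
  expect_gt(ks_uniform(res$residual_p)$p, 0.01)
  # alpha fixed at zero is exactly the normal-effects model
  fit0 <- fit_alpha_model(hits, fix_alpha = 0)
  fitn <- fit_normal_model(hits)
  expect_equal(fit0$sigma2, fitn$sigma2, tolerance = 1e-8)
  expect_equal(fit0$alpha, 0)
})

test_that("baselines are inferior to the generating model on model data", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 101L)
  main_nll <- hit_nll(sim$hits, sim$params)
  # compare on the shared conditional z | q scale
  cond_main <- main_nll  # hit_nll conditions on ascertainment already
  alpha_fit <- fit_alpha_model(sim$hits)
  normal_fit <- fit_normal_model(sim$hits)
  expect_lt(alpha_fit$nll, normal_fit$nll + 1e-6)
  # conditional-on-q nll of the generating model for the same hits
  num <- hit_density(sim$hits$maf, sim$hits$abs_z, sim$params,
                     n = sim$hits$n_eff)
  sig2 <- beta_variance_given_s(sim$params$s, sim$params)
  lamf <- stabarch:::.interp_lambda_fold(cache, sim$hits$maf)[, -1L]
  a <- 2 * sim$hits$maf * (1 - sim$hits$maf) * sim$hits$n_eff
  v <- sqrt(1 + outer(a, sig2))
  wgt <- lamf * matrix(sim$params$mass, nrow(lamf), ncol(lamf),
                       byrow = TRUE)
  den <- rowSums(wgt * 2 * pnorm(5.45 / v, lower.tail = FALSE))
  marg <- rowSums(wgt)
  cond_nll_main <- -sum(log(num / marg) - log(den / marg))
  expect_lt(cond_nll_main, alpha_fit$nll)
})
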