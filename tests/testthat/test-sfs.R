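test_that("expected frequency change follows the underdominant form", {
  expect_equal(expected_delta_q(0.01, 0.1), -3.6e-4)
  expect_equal(expected_delta_q(0.05, 0.5), 0)      # unstable fixed point
  expect_equal(expected_delta_q(0.01, 0.9), 3.6e-4) # minor-allele symmetry
  expect_error(expected_delta_q(-0.1, 0.5), "non-negative")
  expect_error(expected_delta_q(0.01, 1.5), "0, 1")
})

test_that("frequency grid is symmetric with unit total weight", {
  g <- frequency_grid()
  expect_equal(sum(g$w), 1, tolerance = 1e-12)
  expect_lt(max(abs(g$q - rev(1 - g$q))), 1e-12)
  expect_true(all(diff(g$q) > 0))
})

test_that("neutral equilibrium has the 4Nmu/q influx shape", {
  g <- frequency_grid()
  N <- 10000; mu <- 1.25e-8
  lam <- equilibrium_sfs(0, N, mu, g)
  sel <- g$q > 2e-4 & g$q < 0.9   # above the injection frequency
  shape <- lam[sel] * g$q[sel] / (4 * N * mu)
  expect_true(all(abs(shape - 1) < 0.02))
})

test_that("transient solver reproduces the constant-N closed form", {
  g <- frequency_grid()
  dem <- demography_preset("constant")
  for (s in c(0, 1e-3)) {
    lam_t <- present_day_sfs(s, dem, 1.25e-8, g)
    lam_e <- equilibrium_sfs(s, 10000, 1.25e-8, g)
    rel_l1 <- sum(abs(lam_t - lam_e) * g$w) / sum(lam_e * g$w)
    expect_lt(rel_l1, 1e-3)
  }
})

test_that("strong selection approaches mutation-selection balance", {
  g <- frequency_grid()
  mu <- 1.25e-8
  lam <- equilibrium_sfs(1e-2, 10000, mu, g)
  e2pq <- sum(2 * g$q * (1 - g$q) * lam * g$w)
  expect_lt(abs(e2pq / (4 * mu / 1e-2) - 1), 0.2)
  # mass concentrated at low q under strong selection
  expect_lt(sum(lam[g$q > 0.99] * g$w[g$q > 0.99]),
            1e-3 * sum(lam[g$q < 0.01] * g$w[g$q < 0.01]))
})

test_that("density is linear in the mutation rate", {
  g <- frequency_grid(128L)
  lam1 <- present_day_sfs(1e-4, demography_preset("ukb-default"), 1e-8, g)
  lam2 <- present_day_sfs(1e-4, demography_preset("ukb-default"), 2e-8, g)
  expect_equal(lam2, 2 * lam1, tolerance = 1e-9)
})

test_that("discrete Wright-Fisher oracle matches the diffusion at matched 2Ns", {
  # N = 200 with s chosen so 2Ns matches the diffusion run at N = 10,000
  Nsmall <- 400; mu <- 1.25e-8
  for (twoNs in c(0, 10)) {
    wf <- wf_equilibrium_sfs(Nsmall, twoNs / (2 * Nsmall), mu)
    g <- frequency_grid()
    lam <- equilibrium_sfs(twoNs / (2 * 10000), 10000, mu, g)
    # compare CDF shapes over matched interior quantiles
    sel_wf <- wf$q >= 0.02 & wf$q <= 0.98
    cdf_wf <- cumsum(wf$count[sel_wf]) / sum(wf$count[sel_wf])
    sel_d <- g$q >= 0.02 & g$q <= 0.98
    cdf_d <- cumsum(lam[sel_d] * g$w[sel_d]) /
      sum(lam[sel_d] * g$w[sel_d])
    cdf_d_at_wf <- approx(g$q[sel_d], cdf_d, xout = wf$q[sel_wf],
                          rule = 2)$y
    expect_lt(max(abs(cdf_wf - cdf_d_at_wf)), 0.02)
  }
})

test_that("segregating mass decreases with selection strength", {
  cache <- fixture_cache("ukb")
  expect_true(all(diff(cache$seg_prob[-1L]) <= 1e-12))
  # stochastic ordering: weaker selection -> commoner variants
  mean_maf <- function(j) {
    m <- pmin(cache$grid$q, 1 - cache$grid$q)
    sum(m * cache$lambda[, j] * cache$grid$w) /
      sum(cache$lambda[, j] * cache$grid$w)
  }
  j_weak <- which.min(abs(cache$s_values - 10^-4.5))
  j_strong <- which.min(abs(cache$s_values - 1e-2))
  expect_gt(mean_maf(j_weak), mean_maf(j_strong))
})

test_that("seg_moment computes definitional moments", {
  g <- frequency_grid(128L)
  dem <- demography_preset("constant")
  lam <- present_day_sfs(1e-3, dem, 1.25e-8, g)
  expect_equal(seg_moment(1e-3, dem, 1.25e-8, function(q) rep(1, length(q)),
                          g, lambda = lam),
               sum(lam * g$w))
  expect_equal(seg_moment(1e-3, dem, 1.25e-8,
                          function(q) rep(0, length(q)), g, lambda = lam), 0)
})

test_that("moments converge under grid refinement", {
  dem <- demography_preset("constant")
  m1 <- seg_moment(1e-3, dem, 1.25e-8, function(q) 2 * q * (1 - q),
                   frequency_grid(400L))
  m2 <- seg_moment(1e-3, dem, 1.25e-8, function(q) 2 * q * (1 - q),
                   frequency_grid(800L))
  expect_lt(abs(m2 - m1) / m1, 1e-3)
})

test_that("k is near 1 for strong point-mass selection and large when neutral", {
  cache <- fixture_cache("const")
  k <- compute_k(selection_density_point(1e-2), cache)
  expect_gt(k, 0.8)
  expect_lt(k, 1.25)
  expect_warning(k_neutral <- compute_k(selection_density_point(10^-6.5),
                                        cache), "neutral")
  expect_gt(k_neutral, 10)
  # k invariant to mu in the strong-selection limit
  cache2 <- sfs_cache(demography_preset("constant"), mu = 2.5e-8,
                      s_grid = default_s_grid(31L))
  k2 <- compute_k(selection_density_point(1e-2), cache2)
  expect_equal(k2, compute_k(selection_density_point(1e-2),
                             sfs_cache(demography_preset("constant"),
                                       s_grid = default_s_grid(31L))),
               tolerance = 0.02)
})
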