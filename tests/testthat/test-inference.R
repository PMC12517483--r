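test_that("negative log-likelihood is additive and order-invariant", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 11L)
  hits <- sim$hits
  nll1 <- hit_nll(hits, sim$params)
  perm <- sample(nrow(hits))
  hits_perm <- hit_table(hits$snp[perm], hits$maf[perm], hits$abs_z[perm],
                         hits$n_eff[perm], block = hits$block[perm])
  expect_equal(hit_nll(hits_perm, sim$params), nll1)
  dup <- hit_table(c(hits$snp, hits$snp), c(hits$maf, hits$maf),
                   c(hits$abs_z, hits$abs_z), c(hits$n_eff, hits$n_eff))
  expect_equal(hit_nll(dup, sim$params), 2 * nll1)
})

test_that("generating parameters beat a decade-shifted f(s) on average", {
  cache <- fixture_cache("ukb")
  fs_true <- selection_density_preset("ssd-like")
  fs_shift <- selection_density(fs_true$knot_logdens,
                                knot_x = fs_true$knot_x + 1,
                                support = c(-6, 0), label = "shifted")
  wins <- 0L
  for (r in 1:6) {
    sim <- fixture_sim(seed = 200L + r)
    p_true <- sim$params
    p_shift <- trait_params(fs_shift, p_true$h2_over_L, p_true$L,
                            p_true$n, cache)
    if (hit_nll(sim$hits, p_true) < hit_nll(sim$hits, p_shift))
      wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("TSD fit matches hit counts and is reproducible at its optimum", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 21L)
  fit <- fit_tsd(sim$hits, cache, fast_control(n_starts = 3L))
  expect_s3_class(fit, "tsd_fit")
  expect_true(fit$converged)
  # L matching: expected hits reproduce the observed count
  expect_equal(expected_hits(fit$params), nrow(sim$hits), tolerance = 1e-3)
  # factor-2 sanity on this single replicate (tight recovery is assessed
  # over many replicates elsewhere)
  expect_lt(abs(log(fit$h2_over_L / 3e-8)), log(2.5))
  # refitting from the optimum does not move the objective
  refit <- fit_tsd(sim$hits, cache,
                   fit_control(n_starts = 1L, maxit = 400L,
                               lambda = fit$penalty_weight),
                   warm_start = fit$theta)
  expect_lt(abs(refit$objective - fit$objective), 0.05)
  expect_warning(
    fit_tsd(hit_table(sim$hits$snp[1:50], sim$hits$maf[1:50],
                      sim$hits$abs_z[1:50], sim$hits$n_eff[1:50]),
            cache, fast_control(n_starts = 1L, maxit = 60L)),
    "100 hits")
})

test_that("self-simulation from a fitted model reproduces its likelihood", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 31L)
  fit <- fit_tsd(sim$hits, cache, fast_control(n_starts = 2L))
  resim <- simulate(fit, nsim = 1L, seed = 99L)[[1L]]
  nll_per_hit_orig <- fit$nll / nrow(sim$hits)
  nll_per_hit_resim <- hit_nll(resim, fit$params) / nrow(resim)
  expect_lt(abs(nll_per_hit_resim / nll_per_hit_orig - 1), 0.05)
})

test_that("SSD on a single trait agrees with its TSD fit", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 41L)
  ctrl <- fast_control(n_starts = 2L)
  tsd <- fit_tsd(sim$hits, cache, ctrl)
  ssd <- fit_ssd(list(sim$hits), cache, ctrl)
  expect_equal(ssd$joint_nll, tsd$nll, tolerance = 0.01 * abs(tsd$nll))
  expect_equal(unname(log10(ssd$per_trait[[1L]]$h2_over_L)),
               log10(tsd$h2_over_L),
               tolerance = 0.12)
})

test_that("TSD nests SSD when traits have genuinely different f(s)", {
  cache <- fixture_cache("ukb")
  ctrl <- fast_control(n_starts = 2L)
  p_weak <- trait_params(selection_density_preset("weak"), 3e-8, 1e6,
                         3e5, cache)
  p_strong <- trait_params(selection_density_preset("strong"), 3e-8, 1e6,
                           3e5, cache)
  h1 <- simulate_trait(trait_scenario(
    "weakT", "weak", 3e-8, 350 / prob_significant(p_weak), 3e5,
    seed = 51L), cache)$hits
  h2 <- simulate_trait(trait_scenario(
    "strongT", "strong", 3e-8, 350 / prob_significant(p_strong), 3e5,
    seed = 52L), cache)$hits
  tsd_sum <- fit_tsd(h1, cache, ctrl)$nll + fit_tsd(h2, cache, ctrl)$nll
  ssd <- fit_ssd(list(h1, h2), cache, ctrl)
  expect_lt(tsd_sum, ssd$joint_nll)
})

test_that("bootstrap envelopes are deterministic and well-formed", {
  cache <- fixture_cache("ukb")
  sim <- fixture_sim(seed = 61L)
  fit <- fit_tsd(sim$hits, cache, fast_control(n_starts = 2L))
  expect_error(bootstrap_fit(fit, cache, B = 10L), "B >= 20")
  ctrl_b <- fit_control(n_starts = 1L, maxit = 120L, polish_maxit = 0L)
  env1 <- bootstrap_fit(fit, cache, B = 20L, seed = 5L, control = ctrl_b)
  env2 <- bootstrap_fit(fit, cache, B = 20L, seed = 5L, control = ctrl_b)
  expect_identical(env1$cdf_lo, env2$cdf_lo)
  expect_identical(env1$h2_over_L_ci, env2$h2_over_L_ci)
  expect_true(all(env1$cdf_lo <= env1$cdf_hi + 1e-12))
  # envelope brackets the point estimate at most grid points
  inside <- mean(env1$cdf_point >= env1$cdf_lo - 1e-9 &
                   env1$cdf_point <= env1$cdf_hi + 1e-9)
  expect_gt(inside, 0.9)
})
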