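test_that("simulation is seed-deterministic and respects ascertainment", {
  s1 <- fixture_sim(seed = 111L, keep_architecture = TRUE)
  s2 <- fixture_sim(seed = 111L, keep_architecture = TRUE)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$architecture, s2$architecture)
  arch <- s1$architecture
  expect_true(all(s1$hits$maf >= 0.01 & s1$hits$maf <= 0.5))
  expect_true(all(s1$hits$abs_z > 5.45))
  expect_equal(sum(arch$significant), nrow(s1$hits))
  expect_identical(arch$significant,
                   arch$maf >= 0.01 & abs(arch$z) > 5.45)
})

test_that("hit counts and realized heritability match their expectations", {
  cache <- fixture_cache("ukb")
  counts <- vapply(1:10, function(r)
    nrow(fixture_sim(seed = 300L + r)$hits), numeric(1L))
  expect_lt(abs(mean(counts) - 500) / (sd(counts) / sqrt(10)), 3)
  arch <- fixture_sim(seed = 311L, L = 1e7, h2_over_L = 3e-8,
                      keep_architecture = TRUE)$architecture
  realized <- sum(2 * arch$beta^2 * arch$q * (1 - arch$q))
  expect_lt(abs(realized / (1e7 * 3e-8) - 1), 0.05)
})

test_that("panel axes reproduce the expected architecture contrasts", {
  cache <- fixture_cache("ukb")
  sc <- panel_preset("fig-grid", cache, seed = 7L)
  hits <- simulate_panel(sc, cache)
  man <- attr(hits, "manifest")
  expect_setequal(names(hits), c("sel-weak", "sel-strong", "h2L-high",
                                 "h2L-low", "L-small", "L-large"))
  # strong selection: larger fraction of rare hits
  rare <- function(h) mean(h$maf < 0.05)
  pt <- prop.test(c(sum(hits$`sel-strong`$maf < 0.05),
                    sum(hits$`sel-weak`$maf < 0.05)),
                  c(nrow(hits$`sel-strong`), nrow(hits$`sel-weak`)),
                  alternative = "greater")
  expect_lt(pt$p.value, 0.01)
  # high h2/L: larger z-scores and more hits
  expect_gt(median(hits$`h2L-high`$abs_z), median(hits$`h2L-low`$abs_z))
  expect_gt(nrow(hits$`h2L-high`), nrow(hits$`h2L-low`))
  # doubling L doubles counts without changing the maf distribution
  expect_lt(abs(nrow(hits$`L-large`) / nrow(hits$`L-small`) - 2), 0.35)
  expect_gt(suppressWarnings(
    ks.test(hits$`L-large`$maf, hits$`L-small`$maf))$p.value, 0.05)
  expect_equal(man$`L-large`$L, 2 * man$`L-small`$L)
})

test_that("panel writing round-trips through the dataset directory", {
  cache <- fixture_cache("ukb")
  dir <- withr::local_tempdir()
  sc <- list(trait_scenario("tA", "ssd-like", 3e-8, fixture_L500() / 2,
                            3e5, seed = 1L))
  hits <- simulate_panel(sc, cache, dir = dir)
  expect_true(file.exists(file.path(dir, "tA.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_hits(file.path(dir, "tA.tsv"))
  expect_equal(back$maf, hits$tA$maf, tolerance = 1e-10)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$tA$h2_over_L, 3e-8)
})

test_that("spiked outliers record their ground truth", {
  sim <- fixture_sim(seed = 121L)
  sp <- spike_outlier(sim$hits, factor = 2, seed = 9L)
  snp <- attr(sp, "spiked_snp")
  expect_false(is.na(snp))
  i <- match(snp, sp$snp)
  expect_gt(sp$maf[i], 0.3)
  expect_equal(sp$abs_z[i], sim$hits$abs_z[i] * 2)
  expect_identical(sp$abs_z[-i], sim$hits$abs_z[-i])
  expect_true(is.na(attr(spike_outlier(sim$hits, 1), "spiked_snp")))
})

test_that("a ukb-like panel spans the documented hit-count range", {
  cache <- fixture_cache("ukb")
  sc <- panel_preset("ukb-like", cache, n_traits = 12L, seed = 3L)
  expected <- vapply(sc, function(s) {
    p <- trait_params(s$fs, s$h2_over_L, s$L, s$n, cache)
    expected_hits(p)
  }, numeric(1L))
  expect_true(all(expected >= 80 & expected <= 2000))
  expect_true(all(vapply(sc, function(s) s$n, numeric(1L)) <= 4.6e5))
})
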