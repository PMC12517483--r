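# Shared fixtures, built once per test run. Caches are moderately
# expensive (~2 s each) so they are memoized in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture_cache <- function(which = c("ukb", "const")) {
  which <- match.arg(which)
  key <- paste0("cache_", which)
  if (is.null(.fixtures[[key]])) {
    dem <- demography_preset(if (which == "ukb") "ukb-default" else
                               "constant")
    .fixtures[[key]] <- sfs_cache(dem)
  }
  .fixtures[[key]]
}

# a standard synthetic trait: ssd-like f(s), h2/L = 3e-8, n = 3e5, target
# size calibrated once for ~500 expected hits under ukb-default
fixture_L500 <- function() {
  if (is.null(.fixtures$L500)) {
    p <- trait_params(selection_density_preset("ssd-like"), 3e-8, 1e6,
                      3e5, fixture_cache("ukb"))
    .fixtures$L500 <- 500 / prob_significant(p)
  }
  .fixtures$L500
}

fixture_sim <- function(seed = 42L, L = fixture_L500(),
                        h2_over_L = 3e-8, n = 3e5, fs = "ssd-like",
                        keep_architecture = FALSE) {
  simulate_trait(
    trait_scenario(paste0("fix", seed), fs, h2_over_L, L, n, seed = seed),
    fixture_cache("ukb"), keep_architecture = keep_architecture)
}

# quick optimizer settings for tests that need many refits
fast_control <- function(n_starts = 2L, maxit = 250L, ...) {
  fit_control(n_starts = n_starts, maxit = maxit, polish_maxit = 0L, ...)
}
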