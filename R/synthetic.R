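#' Scenario describing one synthetic trait
#'
#' @param label trait label.
#' @param fs a [selection_density()] or a preset name
#'   (`"ssd-like"`, `"weak"`, `"strong"`).
#' @param h2_over_L heritability per site.
#' @param L mutational target size.
#' @param n GWAS effective sample size.
#' @param seed integer seed for this trait's draws.
#' @param n_blocks number of contiguous genome blocks assigned to causal
#'   variants (emulates LD-block structure for cross-validation and block
#'   bootstrap).
#' @return An object of class `trait_scenario`.
#' @export
trait_scenario <- function(label, fs = "ssd-like", h2_over_L = 3e-8,
                           L = 1e7, n = 3e5, seed = 1L, n_blocks = 1700L) {
  if (is.character(fs)) fs <- selection_density_preset(fs)
  stopifnot(inherits(fs, "selection_density"), h2_over_L > 0, L >= 1, n > 0)
  if (h2_over_L * L >= 1)
    stop("implied h2 >= 1; reduce h2_over_L or L")
  structure(list(label = label, fs = fs, h2_over_L = h2_over_L, L = L,
                 n = n, seed = as.integer(seed),
                 n_blocks = as.integer(n_blocks)),
            class = "trait_scenario")
}

#' Simulate a causal architecture and its GWAS hits
#'
#' Draws the full generative hierarchy for one trait: each of the L sites
#' receives a selection coefficient s ~ f(s); sites segregate at the
#' present with probability seg_prob(s), in which case a derived frequency
#' is drawn from the conditional spectrum lambda(q | s); the trait effect
#' is beta | s ~ N(0, (h2/L) k s / (4 mu)); and the observed z-score is
#' z ~ N(beta sqrt(2 q (1-q) n), 1). Hits are the variants in the
#' ascertainment region (maf >= 1%, |z| > 5.45). Only segregating sites
#' are instantiated (their count is Binomial(L, mean seg prob)), which
#' makes target sizes up to 1e8 tractable.
#'
#' @param scenario a [trait_scenario()].
#' @param cache an [sfs_cache()].
#' @param keep_architecture if `TRUE`, also return the full causal table.
#' @return A list with `hits` (a [hit_table()]), `params` (the true
#'   [trait_params()]), and optionally `architecture` (data.frame with
#'   per-variant s, q, maf, beta, z, significance flag and block id).
#' @export
simulate_trait <- function(scenario, cache, keep_architecture = FALSE) {
  stopifnot(inherits(scenario, "trait_scenario"), inherits(cache, "sfs_cache"))
  params <- trait_params(scenario$fs, scenario$h2_over_L, scenario$L,
                         scenario$n, cache)
  set.seed(scenario$seed)
  s_vals <- cache$s_values[-1L]
  mass <- params$mass
  segp <- cache$seg_prob[-1L]
  p_seg <- sum(mass * segp)
  n_seg <- stats::rbinom(1L, size = round(scenario$L), prob = p_seg)
  if (n_seg == 0L) stop("no segregating causal variants; increase L")
  # s | segregating
  js <- sample.int(length(s_vals), n_seg, replace = TRUE,
                   prob = mass * segp)
  # q | s via inverse CDF on the cached spectra, uniform within cells
  q <- numeric(n_seg)
  grid <- cache$grid
  for (j in unique(js)) {
    idx <- which(js == j)
    cellp <- cache$lambda[, j + 1L] * grid$w
    cells <- sample.int(grid$n, length(idx), replace = TRUE, prob = cellp)
    lo <- grid$edges[cells]
    hi <- grid$edges[cells + 1L]
    q[idx] <- lo + stats::runif(length(idx)) * (hi - lo)
  }
  s <- s_vals[js]
  beta <- stats::rnorm(n_seg, 0, sqrt(beta_variance_given_s(s, params)))
  z <- stats::rnorm(n_seg, beta * sqrt(2 * q * (1 - q) * scenario$n), 1)
  maf <- pmin(q, 1 - q)
  sig <- maf >= params$maf_min & abs(z) > params$z_thresh
  block <- ceiling(seq_len(n_seg) / max(1, ceiling(n_seg / scenario$n_blocks)))
  out <- list(params = params)
  if (keep_architecture)
    out$architecture <- data.frame(s = s, q = q, maf = maf, beta = beta,
                                   z = z, significant = sig, block = block)
  if (!any(sig)) {
    out$hits <- hit_table(character(0), numeric(0), numeric(0), numeric(0),
                          trait = scenario$label)
  } else {
    out$hits <- hit_table(
      snp = sprintf("%s_v%d", scenario$label, which(sig)),
      maf = maf[sig], abs_z = abs(z)[sig], n_eff = scenario$n,
      block = block[sig], trait = scenario$label,
      z_thresh = params$z_thresh, maf_min = params$maf_min)
  }
  out
}

#' Simulate a panel of traits
#'
#' @param scenarios list of [trait_scenario()] objects.
#' @param cache an [sfs_cache()].
#' @param dir optional output directory: hit tables are written as TSV and
#'   the true parameters as `manifest.json`.
#' @return Named list of [hit_table()] objects with a `manifest` attribute
#'   recording the true parameters and seeds.
#' @export
simulate_panel <- function(scenarios, cache, dir = NULL) {
  stopifnot(length(scenarios) >= 1L)
  hits <- list()
  manifest <- list()
  for (sc in scenarios) {
    sim <- simulate_trait(sc, cache)
    hits[[sc$label]] <- sim$hits
    manifest[[sc$label]] <- list(
      label = sc$label, fs = sc$fs$label,
      knot_x = sc$fs$knot_x, knot_logdens = sc$fs$knot_logdens,
      h2_over_L = sc$h2_over_L, L = sc$L, n = sc$n, seed = sc$seed,
      n_hits = nrow(sim$hits))
  }
  attr(hits, "manifest") <- manifest
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (lbl in names(hits))
      write_hits(hits[[lbl]], file.path(dir, paste0(lbl, ".tsv")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  hits
}

#' Scenario panels mirroring the main model axes
#'
#' `"fig-grid"` builds three scenario pairs varying one model axis each:
#' weak vs strong selection, high vs low h2/L, and small vs large L.
#' `"ukb-like"` builds a panel shaped like a UK-Biobank-scale dataset:
#' `n_traits` traits sharing an ssd-like f(s), with target sizes chosen so
#' expected hit counts span roughly 100 to 1,760 (mean about 495) at
#' effective sample sizes up to 4.6e5.
#'
#' @param name panel name.
#' @param cache an [sfs_cache()] (used to calibrate L against expected hit
#'   counts).
#' @param n_traits number of traits for the `"ukb-like"` panel.
#' @param seed base seed; trait i uses seed + i.
#' @return List of [trait_scenario()] objects.
#' @export
panel_preset <- function(name = c("fig-grid", "ukb-like"), cache,
                         n_traits = 95L, seed = 1L) {
  name <- match.arg(name)
  L_for_hits <- function(fs, h2L, n, target_hits) {
    p <- prob_significant(trait_params(fs, h2L, 1e6, n, cache))
    target_hits / p
  }
  if (name == "fig-grid") {
    base_h2L <- 3e-8; base_n <- 3e5
    sc <- list()
    for (fsn in c("weak", "strong")) {
      fs <- selection_density_preset(fsn)
      sc[[paste0("sel-", fsn)]] <- trait_scenario(
        paste0("sel-", fsn), fs, base_h2L,
        L_for_hits(fs, base_h2L, base_n, 500), base_n,
        seed = seed + length(sc))
    }
    fs <- selection_density_preset("ssd-like")
    h2L_levels <- c(high = 6e-8, low = 1e-8)
    for (nm in names(h2L_levels)) {
      lbl <- paste0("h2L-", nm)
      sc[[lbl]] <- trait_scenario(lbl, fs, h2L_levels[[nm]],
                                  L_for_hits(fs, 3e-8, base_n, 500), base_n,
                                  seed = seed + length(sc))
    }
    L0 <- L_for_hits(fs, base_h2L, base_n, 250)
    sc[["L-small"]] <- trait_scenario("L-small", fs, base_h2L, L0, base_n,
                                      seed = seed + length(sc))
    sc[["L-large"]] <- trait_scenario("L-large", fs, base_h2L, 2 * L0,
                                      base_n, seed = seed + length(sc))
    return(sc)
  }
  # ukb-like
  fs <- selection_density_preset("ssd-like")
  set.seed(seed)
  target_hits <- round(exp(stats::runif(n_traits, log(100), log(1760))))
  # calibrated so the mean lands near 495, the shape of the real dataset
  target_hits <- pmin(1760, pmax(100, round(
    target_hits * 495 / mean(target_hits))))
  h2L <- 10^stats::runif(n_traits, log10(1.5e-8), log10(6e-8))
  n_eff <- round(stats::runif(n_traits, 2.5e5, 4.6e5))
  lapply(seq_len(n_traits), function(i) {
    trait_scenario(sprintf("trait%02d", i), fs, h2L[i],
                   L_for_hits(fs, h2L[i], n_eff[i], target_hits[i]),
                   n_eff[i], seed = seed + i)
  })
}

#' Inflate the strongest common hit's z-score (planted FTO-like outlier)
#'
#' Multiplies the z-score of the most significant common hit by `factor`,
#' emulating a single variant whose signal stands far above the rest of
#' the architecture (the FTO situation in body-mass GWAS). Because the
#' model's conditional z-distributions are intrinsically heavy-tailed, a
#' doubled mid-range z-score is *not* anomalous; doubling the strongest
#' common signal is, which is exactly the FTO phenomenon this fixture
#' reproduces.
#'
#' @param hits a [hit_table()].
#' @param factor multiplicative z inflation (1 leaves the table unchanged).
#' @param seed kept for call-compatibility; the pick is deterministic
#'   (largest |z| among common hits).
#' @param maf_min_common only hits with maf above this are eligible.
#' @return The modified [hit_table()] with attribute `spiked_snp` naming
#'   the altered variant (`NA` if `factor == 1`).
#' @export
spike_outlier <- function(hits, factor, seed = 1L, maf_min_common = 0.3) {
  stopifnot(inherits(hits, "hit_table"), factor >= 1)
  if (factor == 1) {
    attr(hits, "spiked_snp") <- NA_character_
    return(hits)
  }
  eligible <- which(hits$maf > maf_min_common)
  if (!length(eligible)) stop("no common hits to spike")
  pick <- eligible[which.max(hits$abs_z[eligible])]
  hits$abs_z[pick] <- hits$abs_z[pick] * factor
  attr(hits, "spiked_snp") <- hits$snp[pick]
  hits
}
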