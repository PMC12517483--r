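#' Forward-simulated allele ages conditional on segregating at present
#'
#' Simulates origin-time-stamped allele trajectories under the
#' underdominant deterministic dynamics plus binomial drift at the
#' epoch-specific population size. Origin times are drawn over the past
#' `horizon` generations with probability proportional to the mutational
#' influx 2 N(t) mu; each mutation starts at frequency 1/(2 N(t)).
#' Trajectories absorbed at loss or fixation are discarded; alleles still
#' segregating at the present are returned with their age (generations
#' since origin).
#'
#' @param s selection coefficient (0 for neutral).
#' @param demography a `demographic_model` (use [scale_demography()] for
#'   diffusion-rescaled runs at tractable sizes).
#' @param mu mutation rate (affects only the influx weighting across
#'   epochs, which is proportional to N(t)).
#' @param reps number of mutation origins to simulate (>= 1000).
#' @param seed integer seed.
#' @param horizon oldest origin considered, generations before present;
#'   defaults to 4 times the oldest-epoch size. Ages are necessarily
#'   truncated at the horizon; compare only against oracles with the same
#'   truncation.
#' @return An object of class `age_sample`: data.frame with columns `s`,
#'   `q`, `maf`, `age` (generations), `weight`; attributes record seed,
#'   reps and horizon.
#' @export
simulate_ages <- function(s, demography, mu = 1.25e-8, reps = 10000L,
                          seed = 1L, horizon = NULL) {
  stopifnot(inherits(demography, "demographic_model"), s >= 0)
  if (reps < 1000L) stop("reps must be at least 1000")
  if (is.null(horizon))
    horizon <- 4 * demography$N[length(demography$N)]
  horizon <- as.integer(horizon)
  set.seed(seed)
  # epoch influx weights over [0, horizon)
  starts <- demography$start_gen
  ends <- c(starts[-1L], Inf)
  lo <- pmin(starts, horizon)
  hi <- pmin(ends, horizon)
  dur <- pmax(hi - lo, 0)
  wts <- dur * demography$N
  ep <- sample.int(length(wts), reps, replace = TRUE, prob = wts)
  t0 <- floor(lo[ep] + stats::runif(reps) * dur[ep])  # origin gens b.p.
  births <- table(factor(t0, levels = as.character(seq_len(horizon) - 1L)))
  births <- as.integer(births)  # index g+1 = origins at generation g b.p.
  q <- numeric(0)
  age0 <- integer(0)
  for (g in seq(horizon - 1L, 0L)) {
    N <- size_at(demography, g)
    nb <- births[g + 1L]
    if (nb > 0L) {
      q <- c(q, rep(1 / (2 * N), nb))
      age0 <- c(age0, rep(g, nb))
    }
    if (!length(q)) next
    qd <- q + expected_delta_q(s, q)
    q <- stats::rbinom(length(q), 2 * N, pmin(pmax(qd, 0), 1)) / (2 * N)
    alive <- q > 0 & q < 1
    q <- q[alive]
    age0 <- age0[alive]
  }
  if (!length(q))
    stop("no alleles segregating at present; increase reps")
  structure(
    data.frame(s = s, q = q, maf = pmin(q, 1 - q), age = age0 + 1L,
               weight = 1),
    class = c("age_sample", "data.frame"),
    seed = seed, reps = reps, horizon = horizon,
    demography = demography$label)
}

#' Model-predicted allele ages for GWAS hits
#'
#' For each hit, a selection coefficient is drawn from the posterior given
#' its frequency (optionally sharpened by its z-score), discretized to a
#' coarse s grid; ages are then sampled from forward simulations at each
#' s, conditioned on the hit's minor-allele-frequency bin. Setting
#' `neutral = TRUE` ignores the fit and draws frequency-matched neutral
#' ages, the comparison distribution.
#'
#' @param fit a `tsd_fit` or `ssd_fit` (any object with `$fs` and, for
#'   `use_z`, `$params`); ignored when `neutral = TRUE`.
#' @param hits a [hit_table()].
#' @param cache an [sfs_cache()] (posterior of s given q).
#' @param demography simulation-frame demography for the trajectories
#'   (default: the cache's demography scaled by `scale_factor`).
#' @param scale_factor diffusion rescaling: trajectories run under
#'   `scale_demography(demography, scale_factor)` with s divided by
#'   `scale_factor`, and ages are returned multiplied back by
#'   1/`scale_factor`.
#' @param reps_per_s forward-simulated origins per s bin.
#' @param n_s_bins number of coarse s bins for the posterior draws.
#' @param use_z also condition the s posterior on the observed z-score
#'   (default): hits are ascertained for large effects, so frequency alone
#'   understates their selection coefficients.
#' @param neutral predict ages for frequency-matched neutral variants.
#' @param seed integer seed.
#' @return An `age_sample` with one or more age draws per hit.
#' @export
predicted_hit_ages <- function(fit, hits, cache,
                               demography = cache$demography,
                               scale_factor = 0.1, reps_per_s = 20000L,
                               n_s_bins = 8L, use_z = TRUE,
                               neutral = FALSE, seed = 1L) {
  stopifnot(inherits(hits, "hit_table"), nrow(hits) > 0L)
  set.seed(seed)
  maf_breaks <- c(0.01, 0.025, 0.05, 0.1, 0.2, 0.35, 0.5)
  hit_bin <- cut(hits$maf, maf_breaks, include.lowest = TRUE,
                 labels = FALSE)
  if (neutral) {
    s_draw <- rep(0, nrow(hits))
  } else {
    s_grid <- cache$s_values[-1L]
    s_draw <- vapply(seq_len(nrow(hits)), function(i) {
      post <- conditional_s_given_q(hits$maf[i], fit$fs, cache)
      w <- post$mass
      if (use_z) {
        sig2 <- beta_variance_given_s(post$s, fit$params)
        a <- 2 * hits$maf[i] * (1 - hits$maf[i]) * hits$n_eff[i]
        v <- sqrt(1 + a * sig2)
        w <- w * stats::dnorm(hits$abs_z[i] / v) / v
      }
      sample(post$s, 1L, prob = w)
    }, numeric(1L))
  }
  # coarse s bins in the simulation frame
  pos <- s_draw > 0
  s_bin <- rep(0, length(s_draw))
  if (any(pos)) {
    lx <- log10(s_draw[pos])
    centers <- seq(min(lx), max(lx), length.out = n_s_bins)
    s_bin[pos] <- 10^centers[pmax(1L,
      findInterval(lx, (centers[-1L] + centers[-n_s_bins]) / 2) + 1L)]
  }
  dem_sim <- scale_demography(demography, scale_factor)
  samples <- list()
  for (sb in unique(s_bin)) {
    # one shared trajectory seed: common random numbers couple the pools
    # across s bins (and the neutral reference), so between-pool
    # comparisons are paired and far less noisy
    sim <- simulate_ages(sb / scale_factor, dem_sim, mu = cache$mu,
                         reps = reps_per_s, seed = seed)
    sim$age <- sim$age / scale_factor
    samples[[as.character(sb)]] <- sim
  }
  # each hit demands one unit of mass from the (s bin, maf bin) pool; the
  # whole pool is returned with weights, which is far more stable than
  # resampling single trajectories from small pools
  pool_bin <- lapply(samples, function(sim)
    cut(sim$maf, maf_breaks, include.lowest = TRUE, labels = FALSE))
  demand <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    key_s <- as.character(s_bin[i])
    bin <- hit_bin[i]
    repeat {
      n_pool <- sum(pool_bin[[key_s]] == bin, na.rm = TRUE)
      if (n_pool >= 3L || bin >= length(maf_breaks) - 1L) break
      bin <- bin + 1L  # widen toward common bins where sojourn is longer
    }
    key <- paste(key_s, bin)
    demand[[key]] <- (if (is.null(demand[[key]])) 0 else demand[[key]]) + 1
  }
  out <- list()
  for (key in ls(demand)) {
    parts <- strsplit(key, " ")[[1L]]
    sim <- samples[[parts[1L]]]
    rows <- which(pool_bin[[parts[1L]]] == as.integer(parts[2L]))
    if (!length(rows)) rows <- seq_len(nrow(sim))
    out[[key]] <- data.frame(
      s = as.numeric(parts[1L]), q = sim$maf[rows], maf = sim$maf[rows],
      age = sim$age[rows], weight = demand[[key]] / length(rows))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            class = c("age_sample", "data.frame"),
            seed = seed, reps = reps_per_s, horizon = NA_integer_,
            demography = dem_sim$label)
}

#' Weighted quantiles of an allele-age sample
#'
#' @param sample an `age_sample`.
#' @param probs quantile levels.
#' @return Named numeric vector of age quantiles (generations), computed
#'   from the weighted empirical CDF.
#' @export
age_quantiles <- function(sample, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(sample, "age_sample"))
  ord <- order(sample$age)
  a <- sample$age[ord]
  cw <- cumsum(sample$weight[ord]) / sum(sample$weight)
  stats::setNames(vapply(probs, function(p) a[which(cw >= p)[1L]],
                         numeric(1L)),
                  paste0(100 * probs, "%"))
}

#' Convert generations to years
#'
#' @param generations numeric vector.
#' @param years_per_generation generation time in years (28 by default).
#' @return Years.
#' @export
to_years <- function(generations, years_per_generation = 28) {
  generations * years_per_generation
}

#' @export
print.age_sample <- function(x, ...) {
  med <- age_quantiles(x, 0.5)
  cat(sprintf(
    "Allele-age sample: %d alleles; median age %.0f generations (%.0f years)\n",
    nrow(x), med, to_years(med)))
  invisible(x)
}
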