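#' Negative log-likelihood of a hit table under trait parameters
#'
#' The ascertainment-corrected conditional likelihood of the observed
#' (maf, |z|) pairs given that each variant is a genome-wide significant
#' hit: -sum_i log[ hit_density(q_i, z_i) / prob_significant ]. The target
#' size L cancels and does not enter.
#'
#' @param hits a [hit_table()].
#' @param params a [trait_params()].
#' @return Scalar negative log-likelihood.
#' @export
hit_nll <- function(hits, params) {
  stopifnot(inherits(hits, "hit_table"), nrow(hits) > 0L)
  dens <- hit_density(hits$maf, hits$abs_z, params, n = hits$n_eff)
  if (any(dens <= 0)) {
    bad <- which(dens <= 0)
    stop("zero model density at hit row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ngrp <- unique(hits$n_eff)
  logp <- numeric(nrow(hits))
  for (nv in ngrp) {
    logp[hits$n_eff == nv] <- log(prob_significant(params, n = nv))
  }
  -sum(log(dens) - logp)
}

#' Control settings for maximum-likelihood fitting
#'
#' @param n_starts number of jittered optimizer starts.
#' @param lambda tail-penalty weight passed to [fs_penalty()].
#' @param s_thin keep every `s_thin`-th selection coefficient of the cache
#'   grid during optimization (the final reported fit always uses the full
#'   grid).
#' @param maxit simplex iteration cap per start.
#' @param polish_maxit BFGS polish iteration cap (0 disables).
#' @param n_asc number of minor-allele-frequency quadrature points for the
#'   significance integral during optimization.
#' @param seed seed for the start jitter.
#' @return List of class `fit_control`.
#' @export
fit_control <- function(n_starts = 8L, lambda = 2, s_thin = 2L,
                        maxit = 300L, polish_maxit = 25L, n_asc = 120L,
                        seed = 1L) {
  structure(list(n_starts = as.integer(n_starts), lambda = lambda,
                 s_thin = as.integer(s_thin), maxit = as.integer(maxit),
                 polish_maxit = as.integer(polish_maxit),
                 n_asc = as.integer(n_asc), seed = as.integer(seed)),
            class = "fit_control")
}

# Precomputed quantities for fast objective evaluation. Everything that
# depends only on (hits, cache) is built once.
.fit_context <- function(hits, cache, control) {
  s_idx <- seq(1L, length(cache$s_values) - 1L, by = control$s_thin)
  s <- cache$s_values[-1L][s_idx]
  e2pq <- cache$e2pq[-1L][s_idx]
  lamf_hits <- .interp_lambda_fold(cache, hits$maf)[, -1L,
                                                    drop = FALSE][, s_idx,
                                                                  drop = FALSE]
  ma <- exp(seq(log(attr(hits, "maf_min")), log(0.5),
                length.out = control$n_asc))
  we <- c(attr(hits, "maf_min"), (ma[-length(ma)] + ma[-1L]) / 2, 0.5)
  lam_asc <- .interp_lambda_fold(cache, ma)[, -1L, drop = FALSE][, s_idx,
                                                                 drop = FALSE]
  n_groups <- lapply(unique(hits$n_eff), function(nv)
    list(n = nv, rows = which(hits$n_eff == nv)))
  list(s = s, x = log10(s), e2pq = e2pq, mu = cache$mu,
       z = hits$abs_z, a_hits = 2 * hits$maf * (1 - hits$maf) * hits$n_eff,
       lamf_hits = lamf_hits,
       asc_maf = ma, asc_w = diff(we), lam_asc = lam_asc,
       a_asc_base = 2 * ma * (1 - ma), n_groups = n_groups,
       z_thresh = attr(hits, "z_thresh"), n_hits = nrow(hits))
}

# theta = (4 knot log densities, log10 h2/L); returns penalized nll
.fit_objective <- function(theta, ctx, lambda,
                           knot_x = c(-6, -4.5, -3, -1.5)) {
  if (any(!is.finite(theta)) || any(abs(theta[1:4]) > 30) ||
      theta[5L] < -12 || theta[5L] > -4)
    return(1e10)
  fs <- selection_density(theta[1:4], knot_x = knot_x)
  mass <- fs_mass(fs, ctx$s)
  h2L <- 10^theta[5L]
  denom <- sum(mass * ctx$s * ctx$e2pq)
  sig2 <- h2L * ctx$s / denom          # = (h2/L) k s / (4 mu)
  # per-hit mixture density of (maf, z)
  v_h <- sqrt(1 + outer(ctx$a_hits, sig2))
  dens <- as.numeric(((2 * stats::dnorm(ctx$z / v_h) / v_h) *
                        ctx$lamf_hits) %*% mass)
  if (any(dens <= 0) || any(!is.finite(dens))) return(1e10)
  # significance probability per n_eff group
  ll <- sum(log(dens))
  for (grp in ctx$n_groups) {
    v_a <- sqrt(1 + outer(ctx$a_asc_base * grp$n, sig2))
    tail2 <- 2 * stats::pnorm(ctx$z_thresh / v_a, lower.tail = FALSE)
    psig <- sum((colSums(ctx$asc_w * ctx$lam_asc * tail2)) * mass)
    if (psig <= 0) return(1e10)
    ll <- ll - length(grp$rows) * log(psig)
  }
  -ll + fs_penalty(fs, lambda)
}

# moment-matched initialization: broad default f(s); h2/L from the
# median z^2 via the single-s heuristic z^2 ~ 1 + 2q(1-q) n Var(beta)
.fit_init <- function(hits, s_typ = 1e-3, denom_typ = 4 * 1.25e-8) {
  a <- 2 * hits$maf * (1 - hits$maf) * hits$n_eff
  sig2 <- stats::median(pmax(hits$abs_z^2 - 1, 1)) / stats::median(a)
  h2L <- sig2 * denom_typ / s_typ
  c(0.313, 0, -1.25, -1.563, min(-4.5, max(-11, log10(h2L))))
}

.run_starts <- function(obj_fn, init, control, warm = NULL) {
  # jitters come from a private stream so optimization never disturbs the
  # caller's RNG state (bootstrap/CV resampling depends on this)
  rng_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
  })
  set.seed(control$seed)
  starts <- if (is.null(warm)) list(init) else list(warm)
  base <- starts[[1L]]
  while (length(starts) < control$n_starts) {
    starts[[length(starts) + 1L]] <-
      base + c(stats::rnorm(4L, 0, 0.8), stats::rnorm(1L, 0, 0.4))
  }
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, obj_fn, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (control$polish_maxit > 0L) {
    pol <- tryCatch(
      stats::optim(best$par, obj_fn, method = "BFGS",
                   control = list(maxit = control$polish_maxit)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < best$value) best <- pol
  }
  best
}

#' Fit the trait-specific model by ascertainment-corrected ML
#'
#' Maximizes the conditional likelihood of the observed (maf, |z|) pairs
#' over the four f(s) knot log-densities and log10 h2/L, with the tail
#' penalty of [fs_penalty()]; the target size L is then estimated by
#' matching the expected number of hits to the observed count. Uses
#' multiple jittered simplex starts around a moment-matched
#' initialization, polished by BFGS.
#'
#' @param hits a [hit_table()].
#' @param cache an [sfs_cache()].
#' @param control a [fit_control()].
#' @param warm_start optional length-5 parameter vector (4 knot
#'   log-densities, log10 h2/L) used as the first start; when given, the
#'   jittered starts are skipped unless `control$n_starts > 1`.
#' @return An object of class `tsd_fit` with the fitted [trait_params()],
#'   the penalized and unpenalized negative log-likelihood, and optimizer
#'   diagnostics.
#' @export
fit_tsd <- function(hits, cache, control = fit_control(),
                    warm_start = NULL) {
  stopifnot(inherits(hits, "hit_table"), inherits(cache, "sfs_cache"))
  if (nrow(hits) == 0L) stop("empty hit table")
  low_hits <- nrow(hits) < 100L
  if (low_hits)
    warning("fewer than 100 hits (", nrow(hits),
            "); estimates may be unstable", call. = FALSE)
  ctx <- .fit_context(hits, cache, control)
  obj <- function(theta) .fit_objective(theta, ctx, control$lambda)
  init <- .fit_init(hits)
  best <- .run_starts(obj, init, control, warm = warm_start)
  theta <- best$par
  fs <- selection_density(theta[1:4], label = "fitted")
  n_trait <- stats::median(hits$n_eff)
  params <- trait_params(fs, 10^theta[5L], 1, n_trait, cache,
                         z_thresh = attr(hits, "z_thresh"),
                         maf_min = attr(hits, "maf_min"))
  psig <- prob_significant(params)
  params$L <- nrow(hits) / psig
  if (params$h2_over_L * params$L >= 1)
    warning("fitted parameters imply h2 >= 1", call. = FALSE)
  structure(
    list(params = params, fs = fs, h2_over_L = 10^theta[5L],
         L = params$L, theta = theta,
         nll = hit_nll(hits, params), objective = best$value,
         penalty_weight = control$lambda,
         converged = is.finite(best$value) && best$value < 1e9,
         n_hits_used = nrow(hits), low_hits = low_hits,
         hits = hits, cache_label = cache$demography$label,
         control = control, call = match.call()),
    class = c("tsd_fit", "trait_fit"))
}

#' Fit the single-shared-distribution (SSD) model across traits
#'
#' One f(s) is shared by all traits; each trait keeps its own h2/L (the
#' only trait-specific parameter affecting the fit shape) and its own L
#' (count matching). Optimization is block-coordinate: the shared knots
#' are updated against the summed conditional likelihood, then each
#' trait's log10 h2/L is updated by line search, until the joint objective
#' stabilizes.
#'
#' @param hit_tables list of [hit_table()] objects (>= 1 traits).
#' @param cache an [sfs_cache()].
#' @param control a [fit_control()].
#' @param tol convergence tolerance on the joint penalized objective.
#' @param max_rounds cap on block-coordinate rounds.
#' @return An object of class `ssd_fit` with the shared
#'   [selection_density()], per-trait `h2_over_L`, `L` and nll, and the
#'   joint objective.
#' @export
fit_ssd <- function(hit_tables, cache, control = fit_control(),
                    tol = 1e-4, max_rounds = 30L) {
  stopifnot(length(hit_tables) >= 1L,
            all(vapply(hit_tables, inherits, TRUE, "hit_table")))
  if (is.null(names(hit_tables)))
    names(hit_tables) <- vapply(hit_tables, attr, "", "trait")
  ctxs <- lapply(hit_tables, .fit_context, cache = cache, control = control)
  inits <- lapply(hit_tables, .fit_init)
  knots <- Reduce(`+`, lapply(inits, `[`, 1:4)) / length(inits)
  h2Ls <- vapply(inits, `[`, numeric(1L), 5L)
  joint_obj <- function(kn, hv) {
    tot <- 0
    for (i in seq_along(ctxs))
      tot <- tot + .fit_objective(c(kn, hv[i]), ctxs[[i]], 0)
    tot + fs_penalty(selection_density(kn), control$lambda)
  }
  prev <- joint_obj(knots, h2Ls)
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(knots, function(kn) joint_obj(kn, h2Ls),
                        method = "Nelder-Mead",
                        control = list(maxit = control$maxit))
    knots <- opt$par
    for (i in seq_along(ctxs)) {
      oo <- stats::optimize(function(h)
        .fit_objective(c(knots, h), ctxs[[i]], 0), interval = c(-11, -4.5))
      h2Ls[i] <- oo$minimum
    }
    cur <- joint_obj(knots, h2Ls)
    if (prev - cur < tol) break
    prev <- cur
  }
  fs <- selection_density(knots, label = "fitted SSD")
  per_trait <- lapply(seq_along(hit_tables), function(i) {
    hits <- hit_tables[[i]]
    params <- trait_params(fs, 10^h2Ls[i], 1, stats::median(hits$n_eff),
                           cache, z_thresh = attr(hits, "z_thresh"),
                           maf_min = attr(hits, "maf_min"))
    params$L <- nrow(hits) / prob_significant(params)
    list(trait = names(hit_tables)[i], params = params,
         h2_over_L = 10^h2Ls[i], L = params$L,
         nll = hit_nll(hits, params), n_hits = nrow(hits))
  })
  names(per_trait) <- names(hit_tables)
  structure(
    list(fs = fs, knots = knots, per_trait = per_trait,
         joint_objective = joint_obj(knots, h2Ls),
         joint_nll = sum(vapply(per_trait, `[[`, numeric(1L), "nll")),
         penalty_weight = control$lambda, hit_tables = hit_tables,
         control = control, call = match.call()),
    class = c("ssd_fit", "trait_fit"))
}

#' Bootstrap uncertainty envelope for a trait fit
#'
#' Refits bootstrap replicates of the hit table, warm-started from the
#' point estimate, and returns pointwise 5/95-percentile envelopes of the
#' f(s) CDF and percentile CIs for h2/L and L. `type = "block"` resamples
#' hits with replacement (whole genome blocks when a `block` column is
#' present); `type = "parametric"` simulates replicate hit tables from
#' the fitted generative model, which propagates the sampling variability
#' of the rare, extreme hits the estimator is most sensitive to and which
#' plain resampling reproduces poorly.
#'
#' @param fit a [fit_tsd()] result.
#' @param B number of bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param cache an [sfs_cache()] (defaults to a rebuild keyed by the fit).
#' @param control optional [fit_control()] for the refits; defaults to a
#'   single warm start.
#' @param type resampling scheme (see above).
#' @param s_grid grid on which the f(s) CDF envelope is evaluated.
#' @return An object of class `bootstrap_envelope`.
#' @export
bootstrap_fit <- function(fit, cache, B = 50L, seed = 1L, control = NULL,
                          type = c("block", "parametric"),
                          s_grid = default_s_grid()) {
  stopifnot(inherits(fit, "tsd_fit"))
  type <- match.arg(type)
  if (B < 20L) stop("B < 20 gives a meaningless envelope; use B >= 20")
  hits <- fit$hits
  if (is.null(control))
    control <- fit_control(n_starts = 1L, lambda = fit$penalty_weight,
                           s_thin = fit$control$s_thin,
                           maxit = 200L, polish_maxit = 0L,
                           n_asc = fit$control$n_asc)
  set.seed(seed)
  cdf_mat <- matrix(NA_real_, B, length(s_grid))
  h2L_b <- numeric(B)
  L_b <- numeric(B)
  for (b in seq_len(B)) {
    if (type == "parametric") {
      hb <- simulate(fit, nsim = 1L, seed = seed * 1000L + b,
                     cache = cache)[[1L]]
      if (nrow(hb) < 10L) next
    } else if (!is.null(hits$block)) {
      blocks <- unique(hits$block)
      pick <- sample(blocks, length(blocks), replace = TRUE)
      rows <- unlist(lapply(pick, function(bl) which(hits$block == bl)))
      hb <- hit_table(hits$snp[rows], hits$maf[rows], hits$abs_z[rows],
                      hits$n_eff[rows], block = hits$block[rows],
                      trait = attr(hits, "trait"),
                      z_thresh = attr(hits, "z_thresh"),
                      maf_min = attr(hits, "maf_min"))
    } else {
      rows <- sample.int(nrow(hits), nrow(hits), replace = TRUE)
      hb <- hit_table(hits$snp[rows], hits$maf[rows], hits$abs_z[rows],
                      hits$n_eff[rows],
                      trait = attr(hits, "trait"),
                      z_thresh = attr(hits, "z_thresh"),
                      maf_min = attr(hits, "maf_min"))
    }
    fb <- suppressWarnings(fit_tsd(hb, cache, control,
                                   warm_start = fit$theta))
    cdf_mat[b, ] <- fs_cdf(fb$fs, s_grid)
    h2L_b[b] <- fb$h2_over_L
    L_b[b] <- fb$L
  }
  keep <- !is.na(cdf_mat[, 1L])
  cdf_mat <- cdf_mat[keep, , drop = FALSE]
  h2L_b <- h2L_b[keep]
  L_b <- L_b[keep]
  structure(
    list(s_grid = s_grid,
         cdf_lo = apply(cdf_mat, 2L, stats::quantile, 0.05),
         cdf_hi = apply(cdf_mat, 2L, stats::quantile, 0.95),
         cdf_point = fs_cdf(fit$fs, s_grid),
         h2_over_L_ci = stats::quantile(h2L_b, c(0.05, 0.95)),
         L_ci = stats::quantile(L_b, c(0.05, 0.95)),
         h2_over_L_b = h2L_b, L_b = L_b, B = B, seed = seed),
    class = "bootstrap_envelope")
}

#' @export
print.bootstrap_envelope <- function(x, ...) {
  cat(sprintf("Bootstrap envelope (B = %d)\n", x$B))
  cat(sprintf("  h2/L 90%% CI: [%.3g, %.3g]\n",
              x$h2_over_L_ci[1L], x$h2_over_L_ci[2L]))
  cat(sprintf("  L    90%% CI: [%.3g, %.3g]\n", x$L_ci[1L], x$L_ci[2L]))
  invisible(x)
}
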