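#' Residual p-value of an observed hit
#'
#' Pr(|z| > z_i | |z| > z_thresh, q_i, model): the conditional tail
#' probability of the observed z-score given the hit's frequency and the
#' ascertainment. When the model is correct these are Uniform(0, 1) over
#' hits; skew toward 0 means observed z-scores run hotter than the model
#' predicts, skew toward 1 cooler.
#'
#' @param z absolute z-score(s), at least the significance threshold.
#' @param q minor allele frequency (vectorized with z).
#' @param params a [trait_params()].
#' @param n effective sample size(s).
#' @return p-values in (0, 1].
#' @export
residual_pvalue <- function(z, q, params, n = params$n) {
  conditional_z_tail_given_q(z, q, params, n)
}

#' Cross-validated residual p-values
#'
#' Splits the genome blocks of a hit table into folds, refits the model on
#' the complement of each fold, and scores the held-out hits with
#' [residual_pvalue()], so goodness of fit is assessed out of sample.
#'
#' @param hits a [hit_table()] carrying a `block` column.
#' @param cache an [sfs_cache()].
#' @param n_folds number of folds (blocks are partitioned among them).
#' @param seed seed for the fold assignment.
#' @param fitter function `(hits) -> object with $params` used for each
#'   training set; defaults to [fit_tsd()] with a single warm-started
#'   simplex run for speed.
#' @param control a [fit_control()] for the default fitter.
#' @return An object of class `residual_report`: data.frame columns
#'   `snp`, `maf`, `abs_z`, `fold`, `residual_p`, with the trait-level KS
#'   test against uniformity in attributes `ks_D`, `ks_p`.
#' @export
crossval_residuals <- function(hits, cache, n_folds = 10L, seed = 1L,
                               fitter = NULL, control = NULL) {
  stopifnot(inherits(hits, "hit_table"))
  if (is.null(hits$block))
    stop("cross-validation requires a block column")
  blocks <- unique(hits$block)
  if (length(blocks) < n_folds)
    stop("fewer blocks (", length(blocks), ") than folds (", n_folds, ")")
  if (is.null(control))
    control <- fit_control(n_starts = 2L, maxit = 250L, polish_maxit = 0L)
  if (is.null(fitter))
    fitter <- function(h) suppressWarnings(fit_tsd(h, cache, control))
  set.seed(seed)
  fold_of_block <- sample(rep_len(seq_len(n_folds), length(blocks)))
  names(fold_of_block) <- as.character(blocks)
  fold <- fold_of_block[as.character(hits$block)]
  res <- numeric(nrow(hits))
  for (f in seq_len(n_folds)) {
    held <- which(fold == f)
    if (!length(held)) next
    train <- hits[-held, , drop = FALSE]
    attr_keep <- attributes(hits)
    train <- hit_table(train$snp, train$maf, train$abs_z, train$n_eff,
                       block = train$block, trait = attr_keep$trait,
                       z_thresh = attr_keep$z_thresh,
                       maf_min = attr_keep$maf_min)
    fit <- fitter(train)
    res[held] <- residual_pvalue(hits$abs_z[held], hits$maf[held],
                                 fit$params, n = hits$n_eff[held])
  }
  out <- data.frame(snp = hits$snp, maf = hits$maf, abs_z = hits$abs_z,
                    fold = as.integer(fold), residual_p = res,
                    stringsAsFactors = FALSE)
  ks <- ks_uniform(res)
  structure(out, class = c("residual_report", "data.frame"),
            trait = attr(hits, "trait"), ks_D = ks$D, ks_p = ks$p,
            n_folds = n_folds, seed = seed)
}

#' In-sample residual report for a fitted model
#'
#' @param hits a [hit_table()].
#' @param params a [trait_params()] (e.g. from a fit).
#' @return A `residual_report` (fold 0 marks in-sample scoring).
#' @export
insample_residuals <- function(hits, params) {
  res <- residual_pvalue(hits$abs_z, hits$maf, params, n = hits$n_eff)
  ks <- ks_uniform(res)
  structure(
    data.frame(snp = hits$snp, maf = hits$maf, abs_z = hits$abs_z,
               fold = 0L, residual_p = res, stringsAsFactors = FALSE),
    class = c("residual_report", "data.frame"),
    trait = attr(hits, "trait"), ks_D = ks$D, ks_p = ks$p,
    n_folds = 0L, seed = NA_integer_)
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf(
    "Residual p-values for '%s': %d hits, KS D = %.3f (p = %.3g)\n",
    attr(x, "trait"), nrow(x), attr(x, "ks_D"), attr(x, "ks_p")))
  NextMethod()
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' @param pvals numeric vector in [0, 1].
#' @return List with statistic `D` and p-value `p`.
#' @export
ks_uniform <- function(pvals) {
  stopifnot(length(pvals) >= 1L, all(pvals >= 0 & pvals <= 1))
  kt <- suppressWarnings(stats::ks.test(pvals, "punif"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg rejections at a target FDR
#'
#' @param pvals named vector of per-trait goodness-of-fit p-values.
#' @param level target false discovery rate.
#' @return Character vector (or integer indices if unnamed) of rejected
#'   traits.
#' @export
bh_fdr <- function(pvals, level = 0.05) {
  stopifnot(level > 0, level < 1)
  adj <- stats::p.adjust(pvals, method = "BH")
  rej <- which(adj <= level)
  if (!is.null(names(pvals))) names(pvals)[rej] else rej
}

#' Bonferroni-flagged outlier hits
#'
#' Flags hits whose residual p-value stays significant after Bonferroni
#' correction for the number of tests: individually mis-modelled signals
#' (an FTO-like variant) rather than global misfit.
#'
#' @param report a `residual_report`.
#' @param n_tests number of tests corrected for (defaults to the number of
#'   hits in the report).
#' @param alpha family-wise level.
#' @return The flagged subset of the report (possibly 0 rows).
#' @export
flag_outliers <- function(report, n_tests = nrow(report), alpha = 0.05) {
  stopifnot(inherits(report, "residual_report"))
  if (nrow(report) == 0L) return(report[integer(0L), ])
  report[report$residual_p < alpha / max(1L, n_tests), , drop = FALSE]
}

# conditional nll of z | q, |z| > thresh under variance profile v2(q)
.cond_nll <- function(z, v, z_thresh) {
  -sum(stats::dnorm(z / v, log = TRUE) - log(v) + log(2) -
         stats::pnorm(z_thresh / v, lower.tail = FALSE, log.p = TRUE) -
         log(2))
}

#' Fit the alpha-model baseline by conditional maximum likelihood
#'
#' The alpha-model is the common heuristic linking effect-size variance to
#' allele frequency: beta | q ~ N(0, sigma2 * (2q(1-q))^alpha). Fitting is
#' by maximum likelihood on z | q conditional on ascertainment
#' (z | q ~ N(0, 1 + 2q(1-q) n sigma2 (2q(1-q))^alpha) truncated to
#' |z| > z_thresh), the same conditioning used for residual p-values, so
#' the baseline competes with the main model on identical terms.
#'
#' @param hits a [hit_table()].
#' @param fix_alpha optional: hold alpha fixed (0 gives the
#'   normal-effects model).
#' @return Object of class `alpha_fit` with `alpha`, `sigma2`, `nll`.
#' @export
fit_alpha_model <- function(hits, fix_alpha = NULL) {
  stopifnot(inherits(hits, "hit_table"), nrow(hits) > 0L)
  z <- hits$abs_z
  a <- 2 * hits$maf * (1 - hits$maf)
  an <- a * hits$n_eff
  zt <- attr(hits, "z_thresh")
  obj <- function(par) {
    sigma2 <- exp(par[1L])
    alpha <- if (is.null(fix_alpha)) par[2L] else fix_alpha
    if (!is.finite(sigma2) || abs(alpha) > 4) return(1e10)
    v <- sqrt(1 + an * sigma2 * a^alpha)
    .cond_nll(z, v, zt)
  }
  init <- c(log(stats::median(pmax(z^2 - 1, 1)) / stats::median(an)), 0)
  if (!is.null(fix_alpha)) {
    opt <- stats::optimize(function(p) obj(c(p, 0)),
                           interval = init[1L] + c(-14, 14))
    par <- c(opt$minimum, fix_alpha)
    val <- opt$objective
  } else {
    opt <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 500L, reltol = 1e-10))
    if (opt$convergence != 0)
      opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 500L))
    if (opt$value >= 1e10) stop("alpha-model fit failed to converge")
    par <- opt$par
    val <- opt$value
  }
  structure(list(sigma2 = exp(par[1L]), alpha = par[2L], nll = val,
                 z_thresh = zt, n_hits = nrow(hits),
                 trait = attr(hits, "trait")),
            class = "alpha_fit")
}

#' Fit the normal-effects baseline (alpha fixed at 0)
#'
#' @param hits a [hit_table()].
#' @return An `alpha_fit` with `alpha = 0`.
#' @export
fit_normal_model <- function(hits) {
  fit_alpha_model(hits, fix_alpha = 0)
}

#' Residual p-values under an alpha-model / normal baseline
#'
#' @param object an `alpha_fit`.
#' @param hits a [hit_table()] to score.
#' @param ... unused.
#' @return A `residual_report`.
#' @export
residuals.alpha_fit <- function(object, hits, ...) {
  a <- 2 * hits$maf * (1 - hits$maf)
  v <- sqrt(1 + a * hits$n_eff * object$sigma2 * a^object$alpha)
  res <- stats::pnorm(hits$abs_z / v, lower.tail = FALSE) /
    stats::pnorm(object$z_thresh / v, lower.tail = FALSE)
  res <- pmin(res, 1)
  ks <- ks_uniform(res)
  structure(
    data.frame(snp = hits$snp, maf = hits$maf, abs_z = hits$abs_z,
               fold = 0L, residual_p = res, stringsAsFactors = FALSE),
    class = c("residual_report", "data.frame"),
    trait = attr(hits, "trait"), ks_D = ks$D, ks_p = ks$p,
    n_folds = 0L, seed = NA_integer_)
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf(
    "%s baseline fit for '%s': alpha = %.3f, sigma2 = %.3g, nll = %.2f\n",
    if (x$alpha == 0) "Normal-effects" else "Alpha-model", x$trait,
    x$alpha, x$sigma2, x$nll))
  invisible(x)
}
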