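#' Rescale a hit table to the natural units of h2/L
#'
#' Divides z-scores (and implied effect sizes) by sqrt(h2/L). In these
#' units the architecture of genome-wide significant hits depends only on
#' f(s) and the scaled significance threshold z_thresh / sqrt(h2/L), so
#' traits sharing f(s) should collapse onto a common distribution once a
#' common scaled threshold is imposed.
#'
#' @param hits a [hit_table()].
#' @param h2_over_L the trait's heritability per site (> 0).
#' @param n effective sample size used for the implied effect size
#'   |beta| = z / sqrt(2 maf (1-maf) n); defaults to per-hit `n_eff`.
#' @return An object of class `scaled_hits`: data.frame with `maf`,
#'   `scaled_z`, `scaled_beta`; attribute `scaled_threshold`.
#' @export
rescale_hits <- function(hits, h2_over_L, n = NULL) {
  stopifnot(inherits(hits, "hit_table"))
  if (!is.numeric(h2_over_L) || h2_over_L <= 0)
    stop("h2_over_L must be positive")
  if (is.null(n)) n <- hits$n_eff
  root <- sqrt(h2_over_L)
  beta <- hits$abs_z / sqrt(2 * hits$maf * (1 - hits$maf) * n)
  structure(
    data.frame(snp = hits$snp, maf = hits$maf,
               scaled_z = hits$abs_z / root, scaled_beta = beta / root,
               stringsAsFactors = FALSE),
    class = c("scaled_hits", "data.frame"),
    trait = attr(hits, "trait"),
    scaled_threshold = attr(hits, "z_thresh") / root,
    h2_over_L = h2_over_L)
}

#' Compare two rescaled architectures at a common scaled threshold
#'
#' Filters both traits' scaled hits to the more stringent of the two
#' scaled significance thresholds and compares the surviving marginal
#' distributions of maf, scaled z and scaled effect size by two-sample
#' Kolmogorov-Smirnov tests. Under a shared f(s) all three marginals
#' should be indistinguishable; with different f(s) the maf marginal in
#' particular fails to collapse.
#'
#' @param scaled_a,scaled_b `scaled_hits` objects from [rescale_hits()].
#' @return Object of class `scaling_comparison`: per-marginal KS D and p,
#'   retained counts, and the applied threshold.
#' @export
common_threshold_compare <- function(scaled_a, scaled_b) {
  stopifnot(inherits(scaled_a, "scaled_hits"),
            inherits(scaled_b, "scaled_hits"))
  thr <- max(attr(scaled_a, "scaled_threshold"),
             attr(scaled_b, "scaled_threshold"))
  a <- scaled_a[scaled_a$scaled_z > thr, , drop = FALSE]
  b <- scaled_b[scaled_b$scaled_z > thr, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("no hits survive the common scaled threshold; ",
         "simulate larger target sizes")
  ks <- function(xa, xb) {
    kt <- suppressWarnings(stats::ks.test(xa, xb))
    c(D = unname(kt$statistic), p = kt$p.value)
  }
  structure(
    list(threshold = thr,
         n_a = nrow(a), n_b = nrow(b),
         trait_a = attr(scaled_a, "trait"), trait_b = attr(scaled_b, "trait"),
         maf = ks(a$maf, b$maf),
         scaled_z = ks(a$scaled_z, b$scaled_z),
         scaled_beta = ks(a$scaled_beta, b$scaled_beta)),
    class = "scaling_comparison")
}

#' @export
print.scaling_comparison <- function(x, ...) {
  cat(sprintf(
    "Scaled-architecture comparison '%s' (n=%d) vs '%s' (n=%d), threshold %.3g\n",
    x$trait_a, x$n_a, x$trait_b, x$n_b, x$threshold))
  for (mar in c("maf", "scaled_z", "scaled_beta"))
    cat(sprintf("  %-11s KS D = %.3f, p = %.3g\n", mar,
                x[[mar]]["D"], x[[mar]]["p"]))
  invisible(x)
}

#' Pooled scaling-collapse report for a panel of traits
#'
#' Applies the globally most stringent scaled threshold to every trait and
#' computes the pairwise and one-vs-pooled KS statistics of the maf,
#' scaled-z and scaled-effect marginals. Under a shared f(s) the fraction
#' of pairwise rejections should approach the test level.
#'
#' @param scaled_list list of `scaled_hits`.
#' @param alpha rejection level used in the summary counts.
#' @return Object of class `panel_collapse`: pairwise p-value matrices per
#'   marginal, per-trait rejection counts, retained counts.
#' @export
panel_collapse <- function(scaled_list, alpha = 0.05) {
  stopifnot(length(scaled_list) >= 1L,
            all(vapply(scaled_list, inherits, TRUE, "scaled_hits")))
  labs <- vapply(scaled_list, attr, "", "trait")
  thr <- max(vapply(scaled_list, attr, numeric(1L), "scaled_threshold"))
  kept <- lapply(scaled_list, function(sh)
    sh[sh$scaled_z > thr, , drop = FALSE])
  n_kept <- vapply(kept, nrow, integer(1L))
  if (any(n_kept == 0L))
    stop("trait(s) with no hits above the common scaled threshold: ",
         paste(labs[n_kept == 0L], collapse = ", "))
  k <- length(kept)
  marginals <- c("maf", "scaled_z", "scaled_beta")
  pmats <- lapply(marginals, function(mar) {
    m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
    if (k > 1L)
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        p <- suppressWarnings(
          stats::ks.test(kept[[i]][[mar]], kept[[j]][[mar]]))$p.value
        m[i, j] <- m[j, i] <- p
      }
    m
  })
  names(pmats) <- marginals
  rej <- sapply(pmats, function(m)
    if (k > 1L) rowSums(m < alpha, na.rm = TRUE) else
      stats::setNames(0L, labs))
  rej <- matrix(rej, nrow = k,
                dimnames = list(labs, marginals))
  structure(
    list(threshold = thr, n_kept = stats::setNames(n_kept, labs),
         pairwise_p = pmats, rejections = rej, alpha = alpha,
         pooled_p = vapply(marginals, function(mar) {
           pooled <- unlist(lapply(kept, `[[`, mar))
           min(vapply(seq_len(k), function(i)
             suppressWarnings(stats::ks.test(
               kept[[i]][[mar]], pooled))$p.value, numeric(1L)))
         }, numeric(1L))),
    class = "panel_collapse")
}

#' @export
print.panel_collapse <- function(x, ...) {
  k <- length(x$n_kept)
  cat(sprintf(
    "Panel collapse: %d traits at common scaled threshold %.3g\n",
    k, x$threshold))
  cat("  hits retained per trait:",
      paste(x$n_kept, collapse = ", "), "\n")
  if (k > 1L) {
    n_pairs <- k * (k - 1) / 2
    for (mar in colnames(x$rejections))
      cat(sprintf("  %-11s pairwise KS rejections at alpha=%.2f: %d / %d\n",
                  mar, x$alpha, sum(x$rejections[, mar]) / 2, n_pairs))
  }
  invisible(x)
}
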