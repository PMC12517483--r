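#' @export
print.tsd_fit <- function(x, ...) {
  cat(sprintf("Trait-specific (TSD) fit for '%s'\n",
              attr(x$hits, "trait")))
  cat(sprintf("  hits used: %d%s\n", x$n_hits_used,
              if (x$low_hits) " (below the 100-hit guidance)" else ""))
  cat(sprintf("  h2/L = %.3g, L = %.3g sites (h2 = %.3g), k = %.3f\n",
              x$h2_over_L, x$L, x$h2_over_L * x$L, x$params$k))
  cat(sprintf("  nll = %.2f (penalty weight %.3g), converged: %s\n",
              x$nll, x$penalty_weight, x$converged))
  invisible(x)
}

#' @export
summary.tsd_fit <- function(object, ...) {
  cdfs <- fs_cdf(object$fs, 10^object$fs$knot_x)
  cat(sprintf("TSD fit: %d hits, nll %.2f\n", object$n_hits_used,
              object$nll))
  cat(sprintf("  h2/L = %.3g, L = %.3g, h2 = %.3g\n", object$h2_over_L,
              object$L, object$h2_over_L * object$L))
  cat("  f(s) CDF at knots (log10 s = ",
      paste(object$fs$knot_x, collapse = ", "), "):\n    ",
      paste(sprintf("%.3f", cdfs), collapse = ", "), "\n", sep = "")
  cat(sprintf("  expected hits at fit: %.1f (observed %d)\n",
              expected_hits(object$params), object$n_hits_used))
  invisible(object)
}

#' @export
coef.tsd_fit <- function(object, ...) {
  c(stats::setNames(object$fs$knot_logdens,
                    paste0("logf_knot", seq_along(object$fs$knot_x))),
    h2_over_L = object$h2_over_L, L = object$L)
}

#' Residual p-values of a fitted trait model
#'
#' @param object a `tsd_fit`.
#' @param newdata optional [hit_table()] to score (defaults to the
#'   training hits: in-sample residuals).
#' @param ... unused.
#' @return A `residual_report`.
#' @export
residuals.tsd_fit <- function(object, newdata = NULL, ...) {
  hits <- if (is.null(newdata)) object$hits else newdata
  insample_residuals(hits, object$params)
}

#' Simulate hit tables from a fitted trait model
#'
#' @param object a `tsd_fit`.
#' @param nsim number of replicate tables.
#' @param seed integer seed.
#' @param cache an [sfs_cache()]; defaults to the cache inside the fitted
#'   parameters.
#' @param ... unused.
#' @return A list of [hit_table()] objects (length `nsim`).
#' @export
simulate.tsd_fit <- function(object, nsim = 1, seed = 1L, cache = NULL, ...) {
  if (is.null(cache)) cache <- object$params$cache
  lapply(seq_len(nsim), function(i) {
    sc <- trait_scenario(sprintf("%s_sim%d", attr(object$hits, "trait"), i),
                         object$fs, object$h2_over_L, object$L,
                         object$params$n, seed = seed + i - 1L)
    simulate_trait(sc, cache)$hits
  })
}

#' Model predictions for new hits
#'
#' @param object a `tsd_fit`.
#' @param newdata a [hit_table()] (defaults to the training hits).
#' @param type `"density"` for the joint (maf, |z|) hit density,
#'   `"residual_p"` for residual p-values, `"expected_hits"` for the
#'   expected significant-hit count at the fitted parameters.
#' @param ... unused.
#' @return Numeric vector (or scalar for `"expected_hits"`).
#' @export
predict.tsd_fit <- function(object, newdata = NULL,
                            type = c("density", "residual_p",
                                     "expected_hits"), ...) {
  type <- match.arg(type)
  hits <- if (is.null(newdata)) object$hits else newdata
  switch(type,
    density = hit_density(hits$maf, hits$abs_z, object$params,
                          n = hits$n_eff),
    residual_p = residual_pvalue(hits$abs_z, hits$maf, object$params,
                                 n = hits$n_eff),
    expected_hits = expected_hits(object$params))
}

#' Plot the fitted distribution of selection coefficients
#'
#' Draws the CDF of the fitted f(s) on a log10 s axis, with the bootstrap
#' envelope when one is supplied.
#'
#' @param x a `tsd_fit`.
#' @param envelope optional `bootstrap_envelope` from [bootstrap_fit()].
#' @param s_grid evaluation grid.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tsd_fit <- function(x, envelope = NULL, s_grid = default_s_grid(),
                         ...) {
  lx <- log10(s_grid)
  cdf <- fs_cdf(x$fs, s_grid)
  graphics::plot(lx, cdf, type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = expression(log[10] ~ s),
                 ylab = "CDF of f(s)", ...)
  if (!is.null(envelope)) {
    graphics::polygon(c(lx, rev(lx)),
                      c(envelope$cdf_lo, rev(envelope$cdf_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(lx, cdf, lwd = 2)
  }
  graphics::abline(v = x$fs$knot_x, lty = 3, col = "grey")
  invisible(x)
}

#' @export
print.ssd_fit <- function(x, ...) {
  cat(sprintf("Single-shared-distribution (SSD) fit: %d traits\n",
              length(x$per_trait)))
  cat(sprintf("  joint nll = %.2f (penalty weight %.3g)\n", x$joint_nll,
              x$penalty_weight))
  for (pt in x$per_trait)
    cat(sprintf("  %-12s h2/L = %.3g, L = %.3g, hits = %d\n",
                pt$trait, pt$h2_over_L, pt$L, pt$n_hits))
  invisible(x)
}

#' @export
coef.ssd_fit <- function(object, ...) {
  c(stats::setNames(object$fs$knot_logdens,
                    paste0("logf_knot", seq_along(object$fs$knot_x))),
    stats::setNames(vapply(object$per_trait, `[[`, numeric(1L),
                           "h2_over_L"),
                    paste0("h2_over_L.", names(object$per_trait))))
}

#' Residual p-values of an SSD fit for one member trait
#'
#' @param object an `ssd_fit`.
#' @param trait trait label (defaults to the first).
#' @param ... unused.
#' @return A `residual_report`.
#' @export
residuals.ssd_fit <- function(object, trait = NULL, ...) {
  if (is.null(trait)) trait <- names(object$per_trait)[1L]
  pt <- object$per_trait[[trait]]
  if (is.null(pt)) stop("unknown trait: ", trait)
  insample_residuals(object$hit_tables[[trait]], pt$params)
}
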