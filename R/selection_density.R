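#' Spline-parameterized distribution of selection coefficients
#'
#' f(s) is the density of selection coefficients among newly arising
#' trait-affecting mutations. It is parameterized by the log-density at
#' four knots on the log10 s axis, interpolated by a natural cubic spline,
#' extrapolated linearly in log-density beyond the terminal knots, and
#' truncated to a hard support range. The density is normalized so that
#' the probability mass on the support integrates to 1.
#'
#' Internally the object works with the density g(x) of x = log10 s
#' (so f(s) ds = g(x) dx); all quadrature is performed on the log10 grid.
#'
#' @param knot_logdens numeric length-4: unnormalized log densities (natural
#'   log of g) at the knots. Adding a constant to all four leaves the
#'   distribution unchanged.
#' @param knot_x knot positions on log10 s.
#' @param support log10 s support bounds (hard truncation).
#' @param label optional label.
#' @return An object of class `selection_density`.
#' @examples
#' fs <- selection_density(c(0, 1, 0, -1))
#' sum(fs_mass(fs, default_s_grid()))  # 1
#' @export
selection_density <- function(knot_logdens,
                              knot_x = c(-6, -4.5, -3, -1.5),
                              support = c(-7, -1),
                              label = "custom") {
  stopifnot(length(knot_logdens) == length(knot_x), length(knot_x) >= 3L,
            all(is.finite(knot_logdens)), all(diff(knot_x) > 0),
            support[1L] < knot_x[1L] || support[1L] <= knot_x[1L],
            support[2L] >= knot_x[length(knot_x)])
  knot_logdens <- knot_logdens - mean(knot_logdens)  # remove flat direction
  sf <- stats::splinefun(knot_x, knot_logdens, method = "natural")
  xg <- seq(support[1L], support[2L], length.out = 241L)
  wg <- rep(xg[2L] - xg[1L], length(xg))
  wg[c(1L, length(xg))] <- wg[1L] / 2
  lg <- sf(xg)
  lz <- max(lg) + log(sum(wg * exp(lg - max(lg))))   # log normalizer
  structure(
    list(knot_x = knot_x, knot_logdens = knot_logdens, support = support,
         logg = sf, log_norm = lz, label = label),
    class = "selection_density")
}

#' Named f(s) presets
#'
#' `"ssd-like"` has most mass under weak selection (roughly s below 1e-4,
#' comparable to drift) with a tail spanning several decades into strong
#' selection (about 10% of mass above 1e-3), the shape characteristic of
#' highly polygenic quantitative traits. `"weak"` concentrates mass at
#' nearly neutral s, `"strong"` at strongly selected s. All three have
#' (numerically) zero log-density extrapolation slopes at the terminal
#' knots, i.e. they are interior points of the family that the tail
#' penalty of [fs_penalty()] leaves untouched, so recovery experiments
#' that simulate from them probe the likelihood rather than the prior.
#'
#' @param name preset name.
#' @return A `selection_density`.
#' @export
selection_density_preset <- function(name = c("ssd-like", "weak", "strong")) {
  name <- match.arg(name)
  vals <- switch(name,
    "ssd-like" = c(0.313, 0.0, -1.25, -1.563),
    "weak" = c(1.25, 0.5, -2.5, -3.25),
    "strong" = c(-2.025, -1.5, 0.6, 1.125))
  selection_density(vals, label = name)
}

#' Degenerate (point-mass) distribution of selection coefficients
#'
#' All mutations share the same selection coefficient. Used for
#' limiting-case checks (e.g., the mutation-selection balance limit where
#' the scaling constant k approaches 1) and degenerate posteriors.
#'
#' @param s0 the common selection coefficient.
#' @return A `selection_density` with a `point_s` field.
#' @export
selection_density_point <- function(s0) {
  stopifnot(s0 > 0)
  structure(
    list(knot_x = log10(s0), knot_logdens = 0,
         support = log10(c(s0, s0)), logg = NULL, log_norm = 0,
         point_s = s0, label = sprintf("point mass s = %g", s0)),
    class = "selection_density")
}

#' Log density of log10 s under a selection density
#'
#' @param fs a `selection_density`.
#' @param x log10 s values.
#' @return Normalized log density g(x) of x = log10 s (`-Inf` outside the
#'   support).
#' @export
fs_logdensity_log10 <- function(fs, x) {
  stopifnot(inherits(fs, "selection_density"))
  out <- fs$logg(x) - fs$log_norm
  out[x < fs$support[1L] | x > fs$support[2L]] <- -Inf
  out
}

#' Probability masses of a selection density on an s grid
#'
#' Discretizes f(s) onto the given selection-coefficient grid by trapezoid
#' quadrature on log10 s and renormalizes, so the masses sum to exactly 1.
#' This is the representation used by every integral over s in the
#' likelihood and the moments.
#'
#' @param fs a `selection_density`.
#' @param s_values positive selection coefficients (log-spaced).
#' @return Numeric vector of masses summing to 1.
#' @export
fs_mass <- function(fs, s_values) {
  if (!is.null(fs$point_s)) {
    m <- numeric(length(s_values))
    m[which.min(abs(log10(s_values) - log10(fs$point_s)))] <- 1
    return(m)
  }
  x <- log10(s_values)
  n <- length(x)
  w <- numeric(n)
  if (n == 1L) {
    w[] <- 1
  } else {
    dx <- diff(x)
    w <- c(dx[1L] / 2, (dx[-1L] + dx[-(n - 1L)]) / 2, dx[n - 1L] / 2)
  }
  lg <- fs_logdensity_log10(fs, x)
  m <- w * exp(lg - max(lg[is.finite(lg)]))
  m[!is.finite(m)] <- 0
  m / sum(m)
}

#' CDF of a selection density on an s grid
#'
#' @param fs a `selection_density`.
#' @param s_values evaluation points (default: the default s grid).
#' @return Numeric vector of cumulative probabilities.
#' @export
fs_cdf <- function(fs, s_values = default_s_grid()) {
  cumsum(fs_mass(fs, s_values))
}

#' Extrapolation slopes of log f at the terminal knots
#'
#' The natural-spline parameterization extrapolates log-density linearly
#' beyond the first and last knots; these slopes (per decade of s) control
#' the tails where GWAS data carry little information.
#'
#' @param fs a `selection_density`.
#' @return Length-2 numeric: slopes at the lower and upper terminal knots.
#' @export
fs_tail_slopes <- function(fs) {
  if (is.null(fs$logg)) return(c(0, 0))
  c(fs$logg(fs$knot_x[1L], deriv = 1L),
    fs$logg(fs$knot_x[length(fs$knot_x)], deriv = 1L))
}

#' Regularization penalty on the tails of f(s)
#'
#' GWAS hits are nearly uninformative about very strongly selected
#' variants (too rare) and effectively neutral ones (effects too small),
#' so the likelihood is flat in the tails of f(s). The penalty
#' `lambda * (slope_low^2 + slope_high^2)` on the squared extrapolation
#' slopes of log f at the terminal knots keeps the tails flat unless the
#' data pull them away.
#'
#' @param fs a `selection_density`.
#' @param lambda penalty weight (>= 0).
#' @return Scalar penalty.
#' @export
fs_penalty <- function(fs, lambda = 1) {
  stopifnot(lambda >= 0)
  sl <- fs_tail_slopes(fs)
  lambda * sum(sl^2)
}

#' @export
print.selection_density <- function(x, ...) {
  cat(sprintf("Selection density f(s) '%s'\n", x$label))
  cat("  knots (log10 s):", paste(format(x$knot_x), collapse = ", "), "\n")
  cat("  knot log-densities:",
      paste(format(round(x$knot_logdens, 3)), collapse = ", "), "\n")
  cat(sprintf("  support: 10^%g .. 10^%g\n", x$support[1L], x$support[2L]))
  q <- stats::approx(fs_cdf(x), log10(default_s_grid()),
                     xout = c(0.25, 0.5, 0.75), ties = "ordered")$y
  cat(sprintf("  quartiles of s: 10^%.2f, 10^%.2f, 10^%.2f\n",
              q[1L], q[2L], q[3L]))
  invisible(x)
}
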