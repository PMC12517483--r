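#' Expected per-generation allele-frequency change under stabilizing selection
#'
#' Stabilizing selection on a pleiotropic trait induces underdominant
#' selection at each site: selection acts against the minor allele whatever
#' the direction of its phenotypic effect. The deterministic component of
#' the frequency dynamics is
#' \deqn{E[\Delta q] = -s\,q(1-q)(1/2-q),}
#' which vanishes at q = 0, 1/2, 1 and is antisymmetric about q = 1/2.
#'
#' @param s selection coefficient (>= 0).
#' @param q derived allele frequency in [0, 1]; vectorized.
#' @return Expected frequency change per generation.
#' @export
expected_delta_q <- function(s, q) {
  if (any(s < 0)) stop("s must be non-negative")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  -s * q * (1 - q) * (0.5 - q)
}

#' Logit-spaced frequency grid with quadrature weights
#'
#' Nodes are logit-spaced on (qmin, 1 - qmin), symmetric about 1/2. Cell
#' edges are midpoints between nodes, extended to 0 and 1, so the weights
#' (cell widths) sum exactly to 1.
#'
#' @param n number of nodes (even, so nodes pair q <-> 1-q).
#' @param qmin smallest node frequency.
#' @return List with `q` (nodes), `w` (weights), `edges`.
#' @export
frequency_grid <- function(n = 400L, qmin = 1e-7) {
  stopifnot(n >= 16L, n %% 2L == 0L, qmin > 0, qmin < 0.5)
  x <- seq(stats::qlogis(qmin), 0, length.out = n / 2L + 1L)[seq_len(n / 2L)]
  q_half <- stats::plogis(x)
  q <- c(q_half, rev(1 - q_half))   # exactly symmetric about 1/2
  edges <- c(0, (q[-n] + q[-1L]) / 2, 1)
  list(q = q, w = diff(edges), edges = edges, n = n, qmin = qmin)
}

# log((exp(d) - 1) / d), stable near d = 0
.log_e1m_over_d <- function(d) {
  out <- numeric(length(d))
  small <- abs(d) < 1e-8
  out[small] <- d[small] / 2
  dd <- d[!small]
  res <- numeric(length(dd))
  pos <- dd > 0
  res[pos] <- dd[pos] + log1p(-exp(-dd[pos])) - log(dd[pos])
  res[!pos] <- log1p(-exp(dd[!pos])) - log(-dd[!pos])
  out[!small] <- res
  out
}

# Bernoulli function x / (exp(x) - 1), stable
.bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

# sequential log-sum-exp cumulation of segment log-integrals
.logcumsum <- function(lx) {
  out <- numeric(length(lx))
  acc <- -Inf
  for (i in seq_along(lx)) {
    m <- max(acc, lx[i])
    acc <- m + log(exp(acc - m) + exp(lx[i] - m))
    out[i] <- acc
  }
  out
}

#' Closed-form equilibrium frequency spectrum under constant population size
#'
#' Wright's sojourn-time (influx) solution of the diffusion with drift
#' \eqn{M(q) = -s q(1-q)(1/2-q)} and variance \eqn{V(q) = q(1-q)/(2N)}:
#' mutations arise at rate \eqn{2N\mu} per site per generation at initial
#' frequency p0, and
#' \deqn{\lambda(q) = 8 N^2 \mu \; I_0(\min(q,p_0))\, I_1(\max(q,p_0)) /
#'       \{q(1-q)\,\psi(q)\, I_{tot}\},}
#' with \eqn{\psi(y) = \exp(2Ns\,y(1-y))} and \eqn{I_0}, \eqn{I_1},
#' \eqn{I_{tot}} the lower, upper and total integrals of \eqn{\psi}.
#' All integrals are computed in log space with exponentially fitted
#' segment quadrature, so the result is finite even for 2Ns in the
#' thousands. For s = 0 this reduces to the classic 4Nmu/q density above
#' p0 (and a constant below it).
#'
#' @param s selection coefficient (>= 0).
#' @param N constant diploid population size.
#' @param mu per-site per-generation mutation rate (mu * N << 1).
#' @param grid a [frequency_grid()].
#' @param p0 initial frequency of a new mutation; defaults to 1/(2N), the
#'   same origin the transient solver injects at.
#' @return Numeric vector: expected density of segregating derived alleles
#'   per site at the grid nodes.
#' @export
equilibrium_sfs <- function(s, N, mu, grid = frequency_grid(), p0 = NULL) {
  stopifnot(s >= 0, N >= 2, mu > 0)
  q <- grid$q
  n <- grid$n
  gamma <- 2 * N * s
  if (is.null(p0)) p0 <- 1 / (2 * N)
  lpsi <- gamma * q * (1 - q)
  # segment log-integrals of psi between consecutive nodes, plus end caps
  a <- c(0, q)
  b <- c(q, 1)
  la <- c(0, lpsi)   # log psi(0) = 0
  lb <- c(lpsi, 0)   # log psi(1) = 0
  lseg <- log(b - a) + la + .log_e1m_over_d(lb - la)
  lcum <- .logcumsum(lseg)                       # log int_0^{b_i} psi
  ltot <- lcum[n + 1L]
  # log int_0^{q_j} psi  and  log int_{q_j}^1 psi
  llo <- lcum[seq_len(n)]
  lhi_rev <- .logcumsum(rev(lseg))
  lhi <- rev(lhi_rev)[-1L]                       # log int_{q_j}^1 psi
  # integrals of psi up to / beyond p0 (log-interpolated between nodes)
  interp_at_p0 <- function(lvals) {
    j <- findInterval(p0, q)
    if (j < 1L) return(lvals[1L])
    if (j >= n) return(lvals[n])
    t_frac <- (log(p0) - log(q[j])) / (log(q[j + 1L]) - log(q[j]))
    lvals[j] * (1 - t_frac) + lvals[j + 1L] * t_frac
  }
  llo_p0 <- interp_at_p0(llo)
  lhi_p0 <- interp_at_p0(lhi)
  llo_a <- ifelse(q < p0, llo, llo_p0)
  lhi_b <- ifelse(q > p0, lhi, lhi_p0)
  # lambda = 8 N^2 mu I0(min(q,p0)) I1(max(q,p0)) / (q(1-q) psi(q) Itot);
  # for s = 0 and p0 = 1/(2N), I0(p0) = p0 gives the classic 4Nmu/q.
  loglam <- log(8 * mu) + 2 * log(N) + llo_a + lhi_b - log(q) - log1p(-q) -
    lpsi - ltot
  lam <- exp(loglam)
  if (any(!is.finite(lam))) stop("non-finite equilibrium density")
  lam
}

# Exponentially fitted (Scharfetter-Gummel) tridiagonal generator of the
# Wright-Fisher diffusion with influx, acting on node densities lambda.
# Returns list(M = sparse tridiagonal operator, src = source vector) with
# d lambda / dt = M lambda + src.
.sfs_operator <- function(s, N, mu, grid) {
  q <- grid$q
  n <- grid$n
  w <- grid$w
  gamma <- 2 * N * s
  V <- q * (1 - q) / (2 * N)
  # interfaces: (0,q1), (q1,q2), ..., (qn,1); ghost u = V*lambda = 0 at 0,1
  qa <- c(0, q)
  qb <- c(q, 1)
  Pe <- -gamma * (qb * (1 - qb) - qa * (1 - qa))
  dlt <- qb - qa
  Bm <- .bernoulli_fn(-Pe) / (2 * dlt)   # multiplies u at left node
  Bp <- .bernoulli_fn(Pe) / (2 * dlt)    # multiplies u at right node
  # flux F_i (i = 1..n+1): F_i = Bm_i * u_{i-1} - Bp_i * u_i (u_0=u_{n+1}=0)
  # d lambda_j/dt = (F_j - F_{j+1}) / w_j
  diag_main <- (-Bp[seq_len(n)] - Bm[2:(n + 1L)]) * V / w
  lower <- Bm[2:n] * V[seq_len(n - 1L)] / w[2:n]          # from node j-1
  upper <- Bp[2:n] * V[2:n] / w[seq_len(n - 1L)]          # from node j+1
  M <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(lower, diag_main, upper))
  # influx 2 N mu at p0 = 1/(2N), split log-linearly across the two
  # bracketing nodes so the equilibrium amplitude is first-order exact
  # in the node offset
  p0 <- 1 / (2 * N)
  src <- numeric(n)
  if (p0 <= q[1L]) {
    src[1L] <- 2 * N * mu / w[1L]
  } else {
    j0 <- findInterval(p0, q)
    t_frac <- (log(p0) - log(q[j0])) / (log(q[j0 + 1L]) - log(q[j0]))
    src[j0] <- 2 * N * mu * (1 - t_frac) / w[j0]
    src[j0 + 1L] <- 2 * N * mu * t_frac / w[j0 + 1L]
  }
  list(M = M, src = src)
}

#' Present-day frequency spectrum under piecewise-constant demography
#'
#' Solves the Wright-Fisher diffusion with underdominant drift, mutational
#' influx, and absorbing boundaries on a logit-spaced grid, using an
#' exponentially fitted finite-volume discretization. The population is
#' assumed at mutation-selection-drift balance in the oldest epoch (direct
#' linear solve of the stationary system), then the density is propagated
#' through each subsequent epoch by implicit-Euler time stepping. Under a
#' constant-size history the result coincides with [equilibrium_sfs()].
#'
#' @param s selection coefficient (>= 0).
#' @param demography a `demographic_model`.
#' @param mu mutation rate per site per generation.
#' @param grid a [frequency_grid()].
#' @param dt_max largest implicit time step in generations (steps are also
#'   capped at N/50 so drift is temporally resolved).
#' @return Numeric vector of per-site density of segregating derived
#'   alleles at the grid nodes.
#' @export
present_day_sfs <- function(s, demography, mu, grid = frequency_grid(),
                            dt_max = 25) {
  stopifnot(inherits(demography, "demographic_model"))
  n_ep <- length(demography$N)
  N_old <- demography$N[n_ep]
  op <- .sfs_operator(s, N_old, mu, grid)
  lam <- as.numeric(Matrix::solve(op$M, -op$src))
  if (any(!is.finite(lam)) || any(lam < -1e-9 * max(abs(lam))))
    stop("ancient equilibrium solve failed (non-finite or negative density); ",
         "refine the frequency grid")
  lam[lam < 0] <- 0
  if (n_ep == 1L) return(lam)
  Ident <- Matrix::Diagonal(grid$n)
  starts <- demography$start_gen
  for (i in seq(n_ep - 1L, 1L)) {
    N_i <- demography$N[i]
    dur <- starts[i + 1L] - starts[i]
    op <- .sfs_operator(s, N_i, mu, grid)
    dt <- max(1, min(dt_max, N_i / 50))
    n_steps <- ceiling(dur / dt)
    dt <- dur / n_steps
    A <- Ident - dt * op$M
    for (k in seq_len(n_steps))
      lam <- as.numeric(Matrix::solve(A, lam + dt * op$src))
  }
  lam[lam < 0] <- 0
  lam
}

#' Expectation of a function of frequency over the segregating density
#'
#' Computes the un-normalized per-site expectation
#' \eqn{\int g(q)\,\lambda(q\mid s)\,dq} by quadrature on the grid.
#'
#' @param s selection coefficient.
#' @param demography a `demographic_model`.
#' @param mu mutation rate.
#' @param g function of q (vectorized), or a numeric vector of values at
#'   the grid nodes.
#' @param grid a [frequency_grid()].
#' @param lambda optional precomputed density (skips the solve).
#' @return Scalar expectation.
#' @export
seg_moment <- function(s, demography, mu, g, grid = frequency_grid(),
                       lambda = NULL) {
  if (is.null(lambda)) lambda <- present_day_sfs(s, demography, mu, grid)
  gv <- if (is.function(g)) g(grid$q) else g
  sum(gv * lambda * grid$w)
}

#' Precomputed conditional frequency spectra on a selection-coefficient grid
#'
#' The cache holds, for every s on a log-spaced grid (plus the neutral
#' reference s = 0), the present-day density of derived allele frequency,
#' the per-site segregating probability, the per-site heterozygosity moment
#' E[2q(1-q) | s], and the folded (minor-allele) density used by the hit
#' likelihood. It is trait-independent, so one cache serves every fit under
#' a given demography and mutation rate.
#'
#' @param demography a `demographic_model`.
#' @param mu mutation rate per site per generation.
#' @param s_grid selection-coefficient grid (log-spaced; 0 is added
#'   automatically as the neutral reference column).
#' @param grid a [frequency_grid()].
#' @param cache_dir optional directory: if given, the cache is read from /
#'   written to an RDS file keyed by demography, mu and grid shape.
#' @param verbose print progress.
#' @return An object of class `sfs_cache`.
#' @export
sfs_cache <- function(demography, mu = 1.25e-8,
                      s_grid = default_s_grid(), grid = frequency_grid(),
                      cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(demography, "demographic_model"))
  key <- sprintf("sfscache_%s_%s_%d_%d_%s.rds",
                 gsub("[^a-zA-Z0-9]", "-", demography$label),
                 format(mu, digits = 8), grid$n, length(s_grid),
                 format(sum(demography$N) + sum(demography$start_gen),
                        digits = 10))
  if (!is.null(cache_dir)) {
    path <- file.path(cache_dir, key)
    if (file.exists(path)) {
      obj <- readRDS(path)
      if (inherits(obj, "sfs_cache")) return(obj)
    }
  }
  s_values <- c(0, sort(unique(s_grid)))
  lam <- matrix(0, grid$n, length(s_values))
  for (j in seq_along(s_values)) {
    lam[, j] <- present_day_sfs(s_values[j], demography, mu, grid)
    if (verbose && j %% 20 == 0)
      message("sfs_cache: ", j, "/", length(s_values))
  }
  seg_prob <- colSums(lam * grid$w)
  e2pq <- colSums(2 * grid$q * (1 - grid$q) * lam * grid$w)
  # fold to minor-allele frequency: nodes below 1/2 pair with mirror nodes
  half <- grid$n / 2L
  maf_q <- grid$q[seq_len(half)]
  lam_fold <- lam[seq_len(half), , drop = FALSE] +
    lam[grid$n:(half + 1L), , drop = FALSE]
  obj <- structure(
    list(s_values = s_values, lambda = lam, seg_prob = seg_prob,
         e2pq = e2pq, maf_q = maf_q, maf_w = grid$w[seq_len(half)],
         lambda_fold = lam_fold, grid = grid, mu = mu,
         demography = demography),
    class = "sfs_cache")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(obj, file.path(cache_dir, key))
  }
  obj
}

#' Default selection-coefficient grid
#'
#' 121 log-spaced values spanning s from 1e-7 to 1e-1 (0.05 steps on
#' log10 s).
#'
#' @param n number of grid points.
#' @param lo,hi log10 bounds of the supported range.
#' @return Numeric vector of selection coefficients.
#' @export
default_s_grid <- function(n = 121L, lo = -7, hi = -1) {
  10^seq(lo, hi, length.out = n)
}

#' @export
print.sfs_cache <- function(x, ...) {
  cat(sprintf(
    "SFS cache: %d s-values (incl. neutral), %d-point frequency grid\n",
    length(x$s_values), x$grid$n))
  cat(sprintf("  demography: %s; mu = %g\n", x$demography$label, x$mu))
  cat(sprintf("  seg prob: %.3g (neutral) .. %.3g (s = %.3g)\n",
              x$seg_prob[1L], x$seg_prob[length(x$s_values)],
              max(x$s_values)))
  invisible(x)
}

# interpolate log of the folded density at arbitrary minor allele
# frequencies; returns a length(m) x n_s matrix
.interp_lambda_fold <- function(cache, m) {
  stopifnot(all(m > 0 & m <= 0.5))
  lx <- log(cache$maf_q)
  ll <- log(pmax(cache$lambda_fold, 1e-300))
  xm <- log(pmin(pmax(m, cache$maf_q[1L]), cache$maf_q[length(lx)]))
  idx <- findInterval(xm, lx, all.inside = TRUE)
  t_frac <- (xm - lx[idx]) / (lx[idx + 1L] - lx[idx])
  exp(ll[idx, , drop = FALSE] * (1 - t_frac) +
        ll[idx + 1L, , drop = FALSE] * t_frac)
}

#' Self-consistency constant k of the effect-size scaling
#'
#' In the generative model the effect of a variant on the focal trait,
#' in trait standard deviations, is beta | s ~ N(0, (h2/L) k s / (4 mu)).
#' k is defined as the unique constant for which the heritability
#' decomposition h2 = L Int E[2 beta^2 q(1-q) | s] f(s) ds holds exactly:
#' \deqn{k = 4\mu \; / \; \int s\,E[2q(1-q)\mid s]\,f(s)\,ds.}
#' In the strong-selection (mutation-selection balance) limit
#' E[2q(1-q)|s] -> 4 mu / s, so k -> 1; for weakly selected distributions
#' k can exceed 1 substantially because heterozygosity saturates while s
#' shrinks.
#'
#' @param fs a [selection_density()].
#' @param cache an [sfs_cache()] (provides demography, mu and the
#'   heterozygosity moments).
#' @return Scalar k.
#' @export
compute_k <- function(fs, cache) {
  stopifnot(inherits(fs, "selection_density"), inherits(cache, "sfs_cache"))
  s <- cache$s_values[-1L]
  mass <- fs_mass(fs, s)
  denom <- sum(mass * s * cache$e2pq[-1L])
  if (denom < 0.1 * 4 * cache$mu) {
    warning("f(s) is concentrated at effectively neutral s; ",
            "k greatly exceeds 1")
  }
  4 * cache$mu / denom
}
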