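#' Discrete Wright-Fisher transition matrix
#'
#' Exact binomial-sampling transition matrix on copy-number states
#' 0..2N with the underdominant deterministic update applied to the
#' parental frequency. Used as a brute-force oracle for the diffusion
#' solver and the age simulator at small N.
#'
#' @param N diploid population size (keep small: the matrix is dense
#'   (2N+1)^2).
#' @param s selection coefficient.
#' @return A (2N+1) x (2N+1) matrix; rows index the current copy number,
#'   columns the next generation's.
#' @export
wf_transition_matrix <- function(N, s = 0) {
  states <- 0:(2 * N)
  q <- states / (2 * N)
  qd <- pmin(pmax(q + expected_delta_q(s, q), 0), 1)
  outer(qd, states, function(p, j) stats::dbinom(j, 2 * N, p))
}

#' Equilibrium frequency spectrum of the discrete Wright-Fisher oracle
#'
#' Expected count of segregating alleles per copy-number state under
#' recurrent influx of 2 N mu new mutations per generation (each at one
#' copy), obtained by solving the stationary balance of the interior
#' (segregating) states.
#'
#' @param N diploid size.
#' @param s selection coefficient.
#' @param mu mutation rate.
#' @return data.frame with `q` (frequency of each interior state) and
#'   `count` (expected segregating alleles per site at that state).
#' @export
wf_equilibrium_sfs <- function(N, s = 0, mu = 1.25e-8) {
  Tm <- wf_transition_matrix(N, s)
  interior <- 2:(2 * N)              # segregating states 1..2N-1 copies
  A <- t(Tm[interior, interior])     # expected-count propagation
  influx <- numeric(length(interior))
  influx[1L] <- 2 * N * mu
  counts <- solve(diag(length(interior)) - A, influx)
  data.frame(q = (1:(2 * N - 1)) / (2 * N), count = counts)
}

#' Age distribution of segregating alleles in the discrete oracle
#'
#' Propagates cohorts of new mutations through the Wright-Fisher matrix
#' and accumulates, for every interior state, the probability of being
#' present (unabsorbed) at each age up to `horizon`. The stationary joint
#' law of (frequency, age) for alleles segregating now is proportional to
#' those presence probabilities (origins uniform over past generations).
#'
#' @param N diploid size.
#' @param s selection coefficient.
#' @param horizon maximum age tracked, generations.
#' @return List: `q` interior frequencies, `mass` matrix
#'   (horizon x interior) of presence probabilities by age, `mean_age(qlo,
#'   qhi)` helper returning the mean age of alleles with frequency in
#'   (qlo, qhi].
#' @export
wf_age_oracle <- function(N, s = 0, horizon = 8L * N) {
  Tm <- wf_transition_matrix(N, s)
  interior <- 2:(2 * N)
  A <- Tm[interior, interior]
  v <- numeric(length(interior))
  v[1L] <- 1                         # cohort enters at one copy, age 0
  mass <- matrix(0, horizon, length(interior))
  for (a in seq_len(horizon)) {
    v <- as.numeric(v %*% A)         # survive one more generation
    mass[a, ] <- v
  }
  qs <- (1:(2 * N - 1)) / (2 * N)
  list(q = qs, mass = mass,
       mean_age = function(qlo, qhi) {
         cols <- which(qs > qlo & qs <= qhi)
         m <- rowSums(mass[, cols, drop = FALSE])
         sum(seq_len(horizon) * m) / sum(m)
       })
}
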