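#' Piecewise-constant demographic model
#'
#' A demographic history is a sequence of epochs, each with a constant
#' diploid population size. Epochs are indexed by their start time in
#' generations before present; the first epoch starts at generation 0
#' (the present) and the oldest epoch extends indefinitely into the past.
#'
#' @param start_gen integer vector of epoch start times (generations before
#'   present), strictly increasing, first element 0.
#' @param N integer vector of diploid population sizes, same length as
#'   `start_gen`, all at least 2.
#' @param label free-text label for the history.
#' @return An object of class `demographic_model` with elements
#'   `start_gen`, `N` and `label`.
#' @examples
#' dem <- demographic_model(c(0, 1000), c(1e5, 1e4))
#' size_at(dem, 1000)  # boundary generation belongs to the older epoch
#' @export
demographic_model <- function(start_gen, N, label = "custom") {
  if (length(start_gen) != length(N) || length(N) == 0L)
    stop("start_gen and N must be non-empty vectors of equal length")
  if (any(!is.finite(start_gen)) || any(!is.finite(N)))
    stop("non-finite entries in demographic model")
  if (start_gen[1L] != 0)
    stop("first epoch must start at generation 0 (the present)")
  if (any(diff(start_gen) <= 0))
    stop("epoch start times must be strictly increasing")
  if (any(start_gen < 0))
    stop("epoch start times must be non-negative")
  if (any(N <= 1))
    stop("all population sizes must be >= 2")
  structure(
    list(start_gen = as.numeric(start_gen), N = as.numeric(N),
         label = as.character(label)[1L]),
    class = "demographic_model")
}

#' Built-in demographic histories
#'
#' `"constant"` is a single-epoch N = 10,000 history used as the analytic
#' oracle throughout. `"ukb-default"` is a four-epoch bottleneck-plus-growth
#' caricature of north-west European history: ancestral N = 14,000, a
#' bottleneck to 3,000 between generations 2,500 and 2,400 before present,
#' N = 10,000 until generation 100, and a recent large epoch (N = 500,000)
#' standing in for explosive growth.
#'
#' @param name one of `"constant"`, `"ukb-default"`.
#' @return A `demographic_model`.
#' @export
demography_preset <- function(name = c("constant", "ukb-default")) {
  name <- match.arg(name)
  switch(name,
    "constant" = demographic_model(0, 10000, label = "constant"),
    "ukb-default" = demographic_model(
      start_gen = c(0, 100, 2400, 2500),
      N = c(500000, 10000, 3000, 14000),
      label = "ukb-default"))
}

#' Population size at a time in the past
#'
#' @param model a `demographic_model`.
#' @param t generations before present (vectorized, `t >= 0`); a boundary
#'   generation belongs to the older epoch that starts at it.
#' @return numeric vector of diploid sizes.
#' @export
size_at <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"))
  if (any(t < 0)) stop("t must be non-negative")
  idx <- findInterval(t, model$start_gen)  # boundary -> older epoch
  model$N[pmax(idx, 1L)]
}

#' Read a demographic model from a two-column text file
#'
#' Expected format: whitespace-delimited columns `start_generation
#' diploid_N`, optional header line, `#` comments allowed.
#'
#' @param path file path.
#' @param label optional label; defaults to the file name.
#' @return A `demographic_model`.
#' @export
load_demography <- function(path, label = NULL) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) stop("demography file is empty: ", path)
  parse_one <- function(ln, no) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed demography line %d: expected 2 fields, got %d",
                   no, length(parts)))
    suppressWarnings(as.numeric(parts))
  }
  vals <- mapply(parse_one, lines, lineno, SIMPLIFY = FALSE)
  first <- vals[[1L]]
  if (any(is.na(first))) {  # header line
    vals <- vals[-1L]
    lineno <- lineno[-1L]
    if (length(vals) == 0L) stop("demography file has a header but no data")
  }
  m <- do.call(rbind, vals)
  bad <- which(!is.finite(m[, 1L]) | !is.finite(m[, 2L]))
  if (length(bad))
    stop(sprintf("malformed demography line %d: non-numeric field", lineno[bad[1L]]))
  if (any(m[, 2L] <= 1))
    stop("population sizes must exceed 1 in ", path)
  demographic_model(m[, 1L], m[, 2L],
                    label = if (is.null(label)) basename(path) else label)
}

#' Write a demographic model to its text format
#'
#' @param model a `demographic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_demography <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  writeLines(c("start_generation diploid_N",
               sprintf("%.12g %.12g", model$start_gen, model$N)), path)
  invisible(path)
}

#' Rescale a demographic history for diffusion-invariant computation
#'
#' Multiplies every population size by `factor` and every epoch duration by
#' `factor`. Under the diffusion scaling (N s, N mu, t / N held fixed) a
#' computation at the rescaled history with `s / factor`, `mu / factor`
#' reproduces the original process with time measured in units of
#' `1 / factor` generations. Used to run trajectory simulations at tractable
#' population sizes.
#'
#' @param model a `demographic_model`.
#' @param factor positive scaling factor (< 1 shrinks the population).
#' @return A rescaled `demographic_model`.
#' @export
scale_demography <- function(model, factor) {
  stopifnot(inherits(model, "demographic_model"), factor > 0)
  demographic_model(round(model$start_gen * factor),
                    pmax(2, round(model$N * factor)),
                    label = sprintf("%s x%g", model$label, factor))
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model '%s' (%d epochs)\n", x$label,
              length(x$N)))
  to <- c(x$start_gen[-1L], Inf)
  for (i in seq_along(x$N))
    cat(sprintf("  gens [%g, %g): N = %g\n", x$start_gen[i], to[i], x$N[i]))
  invisible(x)
}
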