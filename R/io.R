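#' Read a GWAS hit table from TSV
#'
#' Expected columns: `snp  maf  abs_z  n_eff` and optionally `block`,
#' tab-delimited with a header. Rows violating the ascertainment region
#' are reported with 1-based data line numbers.
#'
#' @param path file path.
#' @param trait trait label (defaults to the file name).
#' @param z_thresh,maf_min ascertainment region to validate against.
#' @return A [hit_table()].
#' @export
read_hits <- function(path, trait = NULL, z_thresh = 5.45, maf_min = 0.01) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp", "maf", "abs_z", "n_eff")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("hit table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("maf", "abs_z", "n_eff")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at data line %d of %s",
                   col, bad[1L], path))
    df[[col]] <- v
  }
  hit_table(df$snp, df$maf, df$abs_z, df$n_eff,
            block = if ("block" %in% names(df)) df$block else NULL,
            trait = if (is.null(trait)) sub("\\.tsv$", "", basename(path))
                    else trait,
            z_thresh = z_thresh, maf_min = maf_min)
}

#' Write a hit table to TSV
#'
#' @param hits a [hit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(inherits(hits, "hit_table"))
  df <- as.data.frame(hits)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-trait fit results to CSV
#'
#' One row per trait: h2/L, L, implied h2, hit count, nll, convergence,
#' penalty weight.
#'
#' @param fits a `tsd_fit`, `ssd_fit`, or list of `tsd_fit`s.
#' @param path output path.
#' @return The data.frame written, invisibly.
#' @export
write_fit_csv <- function(fits, path) {
  rows <- if (inherits(fits, "ssd_fit")) {
    lapply(fits$per_trait, function(pt)
      data.frame(trait = pt$trait, model = "SSD",
                 h2_over_L = pt$h2_over_L, L = pt$L,
                 h2 = pt$h2_over_L * pt$L, n_hits = pt$n_hits,
                 nll = pt$nll, converged = TRUE,
                 lambda = fits$penalty_weight))
  } else {
    if (inherits(fits, "tsd_fit")) fits <- list(fits)
    lapply(fits, function(ft)
      data.frame(trait = attr(ft$hits, "trait"), model = "TSD",
                 h2_over_L = ft$h2_over_L, L = ft$L,
                 h2 = ft$h2_over_L * ft$L, n_hits = ft$n_hits_used,
                 nll = ft$nll, converged = ft$converged,
                 lambda = ft$penalty_weight))
  }
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Export a fitted f(s) (knots and CDF) to JSON
#'
#' @param fs a [selection_density()].
#' @param path output path.
#' @param s_grid grid for the CDF dump.
#' @return `path`, invisibly.
#' @export
write_fs_json <- function(fs, path, s_grid = default_s_grid()) {
  stopifnot(inherits(fs, "selection_density"))
  jsonlite::write_json(
    list(label = fs$label, knot_log10s = fs$knot_x,
         knot_logdens = fs$knot_logdens, support_log10s = fs$support,
         s_grid = s_grid, cdf = fs_cdf(fs, s_grid)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a selection density back from its JSON export
#'
#' @param path path written by [write_fs_json()].
#' @return A [selection_density()].
#' @export
read_fs_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  selection_density(obj$knot_logdens, knot_x = obj$knot_log10s,
                    support = obj$support_log10s, label = obj$label)
}

#' Write a residual report to TSV
#'
#' @param report a `residual_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(report, path) {
  stopifnot(inherits(report, "residual_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run configuration with full defaulting
#'
#' A single structured description of a pipeline run: demography, grids,
#' likelihood knots and penalty, optimizer, bootstrap, cross-validation
#' and the master seed. Every field has a default; a YAML file or
#' override list supplies only what differs. Sub-seeds for the
#' independent randomness streams (simulation, bootstrap, cross-validation,
#' optimizer starts) are derived deterministically from the master seed.
#'
#' @param ... overrides of the defaults (see the returned object for the
#'   full field list).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    demography = "ukb-default",     # preset name or file path
    mu = 1.25e-8,
    q_grid_points = 400L, q_min = 1e-7,
    s_grid_points = 121L, s_log10_range = c(-7, -1),
    knots = c(-6, -4.5, -3, -1.5),
    lambda = 2,
    n_starts = 8L, maxit = 300L,
    bootstrap_B = 50L,
    cv_folds = 10L,
    z_thresh = 5.45, maf_min = 0.01,
    seed = 1L,
    out_dir = "stabarch-out")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$sub_seeds <- list(simulate = cfg$seed * 1000L + 1L,
                        bootstrap = cfg$seed * 1000L + 2L,
                        cv = cfg$seed * 1000L + 3L,
                        starts = cfg$seed * 1000L + 4L)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields override [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' Write a resolved run configuration beside its outputs
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$sub_seeds <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Resolve the demography named by a configuration
#'
#' @param cfg a `run_config`.
#' @return A `demographic_model`.
#' @export
config_demography <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$demography %in% c("constant", "ukb-default"))
    demography_preset(cfg$demography)
  else
    load_demography(cfg$demography)
}
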