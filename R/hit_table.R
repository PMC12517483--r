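#' Table of ascertained GWAS hits for one trait
#'
#' A validated data.frame of independent genome-wide significant hits with
#' columns `snp`, `maf`, `abs_z`, `n_eff` and optionally `block` (an LD /
#' genome block id used for block bootstrap and cross-validation). All
#' rows must lie in the ascertainment region.
#'
#' @param snp variant identifiers.
#' @param maf minor allele frequencies, in [maf_min, 0.5].
#' @param abs_z absolute GWAS z-scores, all > z_thresh.
#' @param n_eff per-hit effective sample sizes (scalar recycled).
#' @param block optional block ids.
#' @param trait trait label.
#' @param z_thresh,maf_min ascertainment region.
#' @return A data.frame of class `hit_table`.
#' @export
hit_table <- function(snp, maf, abs_z, n_eff, block = NULL,
                      trait = "trait", z_thresh = 5.45, maf_min = 0.01) {
  k <- length(maf)
  stopifnot(length(abs_z) == k, k == length(snp))
  n_eff <- rep_len(n_eff, k)
  bad <- which(maf > 0.5 + 1e-12)
  if (length(bad))
    stop("maf exceeds 0.5 at row ", bad[1L], " (", format(maf[bad[1L]]), ")")
  bad <- which(maf < maf_min - 1e-12)
  if (length(bad))
    stop("maf below the ascertainment cutoff ", maf_min, " at row ", bad[1L])
  bad <- which(abs_z <= z_thresh - 1e-9)
  if (length(bad))
    stop("abs_z at or below the significance threshold ", z_thresh,
         " at row ", bad[1L])
  df <- data.frame(snp = as.character(snp), maf = maf, abs_z = abs_z,
                   n_eff = n_eff, stringsAsFactors = FALSE)
  if (!is.null(block)) df$block <- rep_len(block, k)
  structure(df, class = c("hit_table", "data.frame"),
            trait = trait, z_thresh = z_thresh, maf_min = maf_min)
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("GWAS hit table '%s': %d hits (maf >= %g, |z| > %g)\n",
              attr(x, "trait"), nrow(x), attr(x, "maf_min"),
              attr(x, "z_thresh")))
  if (nrow(x)) {
    cat(sprintf("  maf: median %.3f;  |z|: median %.2f, max %.2f;  n_eff: %.3g\n",
                stats::median(x$maf), stats::median(x$abs_z), max(x$abs_z),
                stats::median(x$n_eff)))
  }
  NextMethod()
  invisible(x)
}
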