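# Fixed-count spectral binning (bucketing).
#
# The ppm span is partitioned into n_bins contiguous equal-width intervals,
# half-open on the low-ppm side with the lowest interval closed, so every
# point lands in exactly one bin.  The default aggregator is the mean, which
# keeps binned intensities on the original scale; sums are available for
# workflows that expect integrated buckets.

#' Bin a spectral matrix to a fixed number of columns
#'
#' @param matrix a `spectral_matrix` on a shared (aligned) grid.
#' @param n_bins number of output columns; the default yields the standard
#'   1000-column analysis matrix.
#' @param agg per-bin aggregator: `"mean"` (default) or `"sum"`.
#' @return a `spectral_matrix` with exactly `n_bins` columns; the grid holds
#'   the descending bin centers and `provenance$bin_width_ppm` records the
#'   bin width.
#' @export
bin_matrix <- function(matrix, n_bins = 1000L, agg = c("mean", "sum")) {
  stopifnot(inherits(matrix, "spectral_matrix"))
  agg <- match.arg(agg)
  n_bins <- as.integer(n_bins)
  n_cols <- ncol(matrix$values)
  if (n_bins < 1L) nmr_error("io_error", "n_bins must be at least 1")
  if (n_bins > n_cols) {
    nmr_error("over_binning_error", sprintf(
      "cannot bin %d columns into %d bins: more bins than spectral points", n_cols, n_bins))
  }
  ppm <- matrix$grid_ppm
  hi <- ppm[1L]
  lo <- ppm[length(ppm)]
  width <- (hi - lo) / n_bins
  # bin j (1-based) covers (hi - j*width, hi - (j-1)*width]; the lowest bin
  # additionally includes its closed lower edge
  idx <- floor((hi - ppm) / width) + 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  if (any(counts == 0L)) {
    nmr_error("empty_bin_error", sprintf(
      "%d bin(s) capture no spectral point; use fewer bins", sum(counts == 0L)))
  }
  sums <- t(rowsum(t(matrix$values), group = idx))  # bins come out in 1..n_bins order
  dimnames(sums) <- NULL
  values <- if (agg == "mean") sweep(sums, 2L, counts, "/") else sums
  centers <- hi - (seq_len(n_bins) - 0.5) * width
  out <- new_spectral_matrix(matrix$sample_labels, centers, values,
                             provenance = matrix$provenance)
  out$provenance$n_bins <- n_bins
  out$provenance$bin_agg <- agg
  out$provenance$bin_width_ppm <- width
  out$provenance$bin_counts <- counts
  nmr_log("bin", sprintf("%d -> %d columns (%s, width %.5f ppm)",
                         n_cols, n_bins, agg, width))
  out
}

# "Bin.<ppm>" label with the ppm centre rounded to 4 decimals (round half
# to even), the precision analysis platforms display.
bin_label <- function(ppm) sprintf("Bin.%s", formatC(round(ppm, 4L), format = "f", digits = 4L))
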