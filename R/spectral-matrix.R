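# Sample-by-spectral-point matrix construction.
#
# "Alignment" here means ppm-grid harmonization (resampling every spectrum
# onto one shared grid), not peak alignment — peak alignment is a
# preprocessing step that belongs to the downstream analysis platforms.

new_spectral_matrix <- function(sample_labels, grid_ppm, values, provenance = list()) {
  stopifnot(nrow(values) == length(sample_labels),
            ncol(values) == length(grid_ppm))
  if (length(grid_ppm) > 1L && any(diff(grid_ppm) >= 0)) {
    nmr_error("io_error", "spectral grid must be strictly decreasing in ppm")
  }
  rownames(values) <- sample_labels
  structure(list(sample_labels = sample_labels, grid_ppm = grid_ppm,
                 values = values, provenance = provenance),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d sample%s x %d point%s, %.4f..%.4f ppm\n",
              nrow(x$values), if (nrow(x$values) == 1L) "" else "s",
              ncol(x$values), if (ncol(x$values) == 1L) "" else "s",
              x$grid_ppm[1L], x$grid_ppm[length(x$grid_ppm)]))
  if (!is.null(x$provenance$pulprog)) {
    cat(sprintf("  experiment type: %s\n", x$provenance$pulprog))
  }
  invisible(x)
}

#' @export
dim.spectral_matrix <- function(x) dim(x$values)

#' @export
as.matrix.spectral_matrix <- function(x, ...) x$values

#' Align spectra onto a common ppm grid
#'
#' The common grid is the descending uniform grid over the intersection of
#' all input ppm ranges, with as many points as the densest input offers
#' inside that range; each spectrum is resampled onto it by linear
#' interpolation (no extrapolation can occur, by construction).  When all
#' inputs already share one grid they pass through unchanged.
#'
#' @param spectra list of `nmr_spectrum` objects.
#' @return a `spectral_matrix` (rows ordered by sample label).
#' @export
align_to_common_grid <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  labels <- vapply(spectra, function(s) s$sample_label, character(1))
  ord <- order(labels, method = "radix")
  spectra <- spectra[ord]
  labels <- labels[ord]

  grids <- lapply(spectra, function(s) s$ppm)
  same <- all(vapply(grids[-1L], function(g) identical(g, grids[[1L]]), logical(1)))
  if (same || length(spectra) == 1L) {
    values <- do.call(rbind, lapply(spectra, function(s) s$intensity))
    return(new_spectral_matrix(labels, grids[[1L]], values))
  }

  # running intersection, in label order: the sample that empties it is the
  # one reported
  hi <- max(grids[[1L]]); lo <- min(grids[[1L]])
  for (k in seq_along(grids)[-1L]) {
    hi2 <- min(hi, max(grids[[k]]))
    lo2 <- max(lo, min(grids[[k]]))
    if (hi2 <= lo2) {
      nmr_error("no_overlap_error", sprintf(
        "ppm ranges have empty intersection (sample '%s' does not overlap the rest)",
        labels[k]))
    }
    hi <- hi2; lo <- lo2
  }
  n <- max(vapply(grids, function(g) sum(g >= lo & g <= hi), numeric(1)))
  grid <- seq(hi, lo, length.out = n)
  values <- t(vapply(spectra, function(s) {
    stats::approx(x = rev(s$ppm), y = rev(s$intensity), xout = grid)$y
  }, numeric(n)))
  new_spectral_matrix(labels, grid, values)
}

#' Import a study's spectra into a data matrix
#'
#' For every usable sample, reads the lowest-numbered experiment whose
#' acquisition pulse program matches `pulprog`, decodes its `1r` spectrum,
#' and aligns all spectra onto a common ppm grid.  Each row of the result is
#' one sample; each column one spectral point.  Samples with no matching
#' experiment are skipped with a warning.
#'
#' @param tree a validated `study_tree`.
#' @param pulprog the experiment type to import (a name from
#'   [list_experiment_types()]).
#' @param strict passed to [validate_study()].
#' @return a `spectral_matrix` with provenance recording the pulse program
#'   and the expno used per sample.
#' @export
import_data <- function(tree, pulprog, strict = FALSE) {
  stopifnot(inherits(tree, "study_tree"))
  report <- validate_study(tree, strict = strict)
  if (!report$valid) {
    nmr_error("validation_error", "study has no usable samples")
  }
  spectra <- list()
  expno_used <- integer(0)
  for (s in tree$samples) {
    if (!(s$label %in% report$usable_samples)) next
    match <- NULL
    for (e in s$experiments) {  # experiments are ordered by ascending expno
      if (experiment_usable(e) && identical(e$acqus$pulprog, pulprog)) {
        match <- e
        break
      }
    }
    if (is.null(match)) {
      nmr_warn(sprintf("sample '%s' has no usable '%s' experiment; skipped",
                       s$label, pulprog))
      next
    }
    spectra[[length(spectra) + 1L]] <- read_spectrum(s$label, match)
    expno_used[s$label] <- match$expno
  }
  if (!length(spectra)) {
    nmr_error("empty_selection_error",
              sprintf("no sample offers a usable experiment of type '%s'", pulprog))
  }
  mat <- align_to_common_grid(spectra)
  mat$provenance <- list(pulprog = pulprog,
                         expno_used = expno_used[mat$sample_labels])
  nmr_log("import", sprintf("%d samples x %d points (%s)",
                            nrow(mat$values), ncol(mat$values), pulprog))
  mat
}

#' Clean a spectral matrix
#'
#' Columns that are non-finite across every sample are dropped (the grid
#' shrinks accordingly); any remaining non-finite entry is replaced by 0.
#' The number of replacements is logged.  Row order and grid monotonicity
#' are preserved.
#'
#' @param matrix a `spectral_matrix`.
#' @return the cleaned `spectral_matrix`.
#' @export
clean_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "spectral_matrix"))
  v <- matrix$values
  bad <- !is.finite(v)
  all_bad_col <- colSums(bad) == nrow(v)
  if (any(all_bad_col)) {
    v <- v[, !all_bad_col, drop = FALSE]
    matrix$grid_ppm <- matrix$grid_ppm[!all_bad_col]
    nmr_log("clean", sprintf("dropped %d all-non-finite column(s)", sum(all_bad_col)))
    bad <- bad[, !all_bad_col, drop = FALSE]
  }
  n_rep <- sum(bad)
  if (n_rep > 0L) {
    v[bad] <- 0
    nmr_log("clean", sprintf("replaced %d non-finite value(s) with 0", n_rep))
  }
  matrix$values <- v
  matrix$provenance$n_cleaned <- n_rep
  matrix
}

#' Write the intermediate per-sample CSV
#'
#' One row per sample, one column per spectral point (columns named by ppm),
#' full numeric precision so re-parsing is lossless.
#'
#' @param matrix a `spectral_matrix`.
#' @param path output CSV path.
#' @export
write_intermediate_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "spectral_matrix"))
  header <- paste(c("Sample", sprintf("%.17g", matrix$grid_ppm)), collapse = ",")
  rows <- vapply(seq_len(nrow(matrix$values)), function(i) {
    paste(c(sanitize_label(matrix$sample_labels[i]),
            sprintf("%.17g", matrix$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
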