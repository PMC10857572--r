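# Exporters for the two downstream analysis platforms.
#
# MetaboAnalyst: one CSV, samples in rows — Sample, Label (class), then one
# column per spectral feature named Bin.<ppm to 4 decimals>.
# Workflows4Metabolomics: three tab-separated files — dataMatrix.tabular
# (features in rows, samples in columns; the transpose of the MetaboAnalyst
# numeric block), sampleMetadata.tabular (sample -> SampleOrder) and
# variableMetadata.tabular (variable -> VariableOrder).
#
# Numeric cells are rendered with up to 17 significant digits so re-parsing
# reproduces the exported matrix bit for bit.  Files are UTF-8 with LF line
# endings for cross-platform determinism.

fmt_num <- function(x) sprintf("%.17g", x)

write_lf <- function(lines, path) {
  con <- file(path, "wb")      # binary mode pins LF endings on all platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Export a MetaboAnalyst CSV
#'
#' Writes the samples-in-rows CSV MetaboAnalyst's statistical analysis
#' module expects: header `Sample,Label,Bin.<ppm>,...` with features in
#' descending ppm order, then one row per sample holding its name, its
#' class, and the intensities.  When `labels` is not supplied the class
#' cells are left empty for the analyst to fill in.
#'
#' @param matrix a `spectral_matrix` (usually binned).
#' @param labels optional named character vector or list mapping sample
#'   label to class (e.g. patient / control); names must be a subset of the
#'   matrix's samples.
#' @param out output CSV path.
#' @return the output path, invisibly.
#' @export
export_metaboanalyst <- function(matrix, labels = NULL, out) {
  stopifnot(inherits(matrix, "spectral_matrix"), nrow(matrix$values) >= 1L)
  cls <- rep("", length(matrix$sample_labels))
  names(cls) <- matrix$sample_labels
  if (!is.null(labels)) {
    labels <- unlist(labels)
    unknown <- setdiff(names(labels), matrix$sample_labels)
    if (length(unknown)) {
      nmr_error("io_error", sprintf("class labels given for unknown sample(s): %s",
                                    paste(unknown, collapse = ", ")))
    }
    cls[names(labels)] <- labels
  }
  header <- paste(c("Sample", "Label", bin_label(matrix$grid_ppm)), collapse = ",")
  rows <- vapply(seq_len(nrow(matrix$values)), function(i) {
    paste(c(sanitize_label(matrix$sample_labels[i]), cls[i],
            fmt_num(matrix$values[i, ])), collapse = ",")
  }, character(1))
  write_lf(c(header, rows), out)
  nmr_log("export", sprintf("MetaboAnalyst CSV: %s", out))
  invisible(out)
}

#' Read back a MetaboAnalyst CSV
#'
#' @param path a CSV written by [export_metaboanalyst()].
#' @return list with `sample_labels`, `classes`, `features` (column
#'   headers) and `values` (numeric matrix, samples in rows).
#' @export
read_metaboanalyst_csv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  cells <- strsplit(lines[-1L], ",", fixed = TRUE)
  values <- t(vapply(cells, function(r) as.numeric(r[-(1:2)]),
                     numeric(length(header) - 2L)))
  list(sample_labels = vapply(cells, `[`, character(1), 1L),
       classes = vapply(cells, function(r) if (length(r) >= 2L) r[2L] else "", character(1)),
       features = header[-(1:2)],
       values = values)
}

#' Export the Workflows4Metabolomics tabular trio
#'
#' Writes `dataMatrix.tabular` (header `variable` then sample names; one row
#' per spectral feature — the transpose of the MetaboAnalyst layout),
#' `sampleMetadata.tabular` (`sample`, `SampleOrder`: the sample's 1-based
#' column position in the data matrix) and `variableMetadata.tabular`
#' (`variable`, `VariableOrder`: the feature's 1-based row position).
#'
#' @param matrix a `spectral_matrix` (usually binned).
#' @param out_dir output directory (created if needed).
#' @param plain_ids strip the `Bin.` prefix and the decimal dot from feature
#'   ids (some ingestion routes expect bare digit ids).
#' @return named character vector of the three paths, invisibly.
#' @export
export_w4m <- function(matrix, out_dir, plain_ids = FALSE) {
  stopifnot(inherits(matrix, "spectral_matrix"), nrow(matrix$values) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- bin_label(matrix$grid_ppm)
  if (plain_ids) ids <- gsub("\\.", "", sub("^Bin\\.", "", ids))
  samples <- sanitize_label(matrix$sample_labels)

  dm <- file.path(out_dir, "dataMatrix.tabular")
  header <- paste(c("variable", samples), collapse = "\t")
  rows <- vapply(seq_along(ids), function(j) {
    paste(c(ids[j], fmt_num(matrix$values[, j])), collapse = "\t")
  }, character(1))
  write_lf(c(header, rows), dm)

  sm <- file.path(out_dir, "sampleMetadata.tabular")
  write_lf(c("sample\tSampleOrder",
             sprintf("%s\t%d", samples, seq_along(samples))), sm)

  vm <- file.path(out_dir, "variableMetadata.tabular")
  write_lf(c("variable\tVariableOrder",
             sprintf("%s\t%d", ids, seq_along(ids))), vm)

  nmr_log("export", sprintf("W4M trio in %s", out_dir))
  invisible(c(dataMatrix = dm, sampleMetadata = sm, variableMetadata = vm))
}

#' Read back a W4M data matrix
#'
#' @param path a `dataMatrix.tabular` written by [export_w4m()].
#' @return list with `features`, `sample_labels` and `values` (numeric
#'   matrix, features in rows).
#' @export
read_w4m_datamatrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  values <- t(vapply(cells, function(r) as.numeric(r[-1L]),
                     numeric(length(header) - 1L)))
  list(features = vapply(cells, `[`, character(1), 1L),
       sample_labels = header[-1L],
       values = values)
}

#' Package output files into a zip bundle
#'
#' Members are placed at the archive root in lexicographic order with zeroed
#' timestamps, so identical inputs yield byte-identical archives.
#'
#' @param paths files to include (all must exist).
#' @param out_zip output archive path.
#' @return the archive path, invisibly.
#' @export
package_outputs <- function(paths, out_zip) {
  if (!length(paths)) {
    nmr_error("io_error", "no files to package")
  }
  zip_create(paths, out_zip, arcnames = basename(paths))
  nmr_log("package", sprintf("%d file(s) -> %s", length(paths), out_zip))
  invisible(out_zip)
}
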