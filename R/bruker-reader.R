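# Bruker file readers: JCAMP-DX parameter files (acqu/acqus/procs) and the
# flat binary 1r file holding the real part of a processed 1D spectrum.
#
# Decoding contract (the standard Bruker one):
#   - DTYPP 0 -> 32-bit signed integers, DTYPP 2 -> 64-bit IEEE doubles
#   - BYTORDP 0 -> little-endian, 1 -> big-endian
#   - stored values are scaled by 2^NC_proc to recover intensities
#   - the ppm axis starts at OFFSET and steps down by SW_p/(SF*SI)

#' Parse a Bruker JCAMP-DX parameter file
#'
#' Reads `##$KEY= value` records; multi-line array values (introduced by a
#' `(0..N)` size header) are concatenated into numeric or character vectors;
#' scalar values are typed by content (integer, real, string) and
#' angle-bracket quoting around strings is stripped.
#'
#' @param path path to an `acqu`, `acqus` or `procs` file.
#' @return named list of parsed values; the complete set is also available
#'   unmodified under attribute `"raw"`.
#' @export
parse_param_file <- function(path) {
  if (!file.exists(path)) {
    nmr_error("io_error", sprintf("parameter file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^##\\$", lines)
  if (!length(starts)) {
    nmr_error("malformed_parameter_error",
              sprintf("no ##$ parameter records in %s", path))
  }
  out <- list()
  for (k in seq_along(starts)) {
    line <- lines[starts[k]]
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L) next
    key <- sub("^##\\$", "", substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (grepl("^\\(0\\.\\.[0-9]+\\)", val)) {
      # array value: remainder of this line plus following non-record lines
      val <- sub("^\\(0\\.\\.[0-9]+\\)", "", val)
      stop_at <- if (k < length(starts)) starts[k + 1L] else length(lines) + 1L
      follow <- lines[setdiff(seq(starts[k] + 1L, stop_at - 1L), integer(0))]
      follow <- follow[!grepl("^##", follow) & !grepl("^\\$\\$", follow)]
      tokens <- unlist(strsplit(trimws(c(val, follow)), "[[:space:]]+"))
      tokens <- tokens[nzchar(tokens)]
      parsed <- suppressWarnings(as.numeric(tokens))
      out[[key]] <- if (!anyNA(parsed)) parsed else tokens
    } else {
      out[[key]] <- parse_param_scalar(val)
    }
  }
  attr(out, "raw") <- out
  out
}

parse_param_scalar <- function(val) {
  if (grepl("^<.*>$", val)) return(substr(val, 2L, nchar(val) - 1L))
  if (grepl("^-?[0-9]+$", val)) {
    n <- suppressWarnings(as.numeric(val))
    return(if (abs(n) <= .Machine$integer.max) as.integer(n) else n)
  }
  n <- suppressWarnings(as.numeric(val))
  if (!is.na(n)) return(n)
  val
}

#' Parse acquisition parameters (acqus)
#'
#' @param path path to an `acqus` (or `acqu`) file.
#' @return an `acqus_params` object with fields `pulprog` (pulse program
#'   name), `bytorda` (acquisition byte order) and `raw` (all records).
#' @export
parse_acqus <- function(path) {
  raw <- parse_param_file(path)
  structure(list(
    pulprog = as.character(raw$PULPROG %||% ""),
    bytorda = as.integer(raw$BYTORDA %||% 0L),
    raw = raw
  ), class = "acqus_params")
}

#' Parse processing parameters (procs)
#'
#' @param path path to a `procs` file.
#' @return a `procs_params` object with the fields controlling 1r decoding
#'   and ppm referencing: `offset_ppm` (OFFSET, ppm of the first point),
#'   `sw_p_hz` (SW_p, spectral width in Hz), `sf_mhz` (SF, spectrometer
#'   frequency in MHz), `si` (SI, number of points), `nc_proc` (NC_proc,
#'   intensity scaling exponent), `bytordp` (BYTORDP), `dtypp` (DTYPP) and
#'   `raw`.
#' @export
parse_procs <- function(path) {
  raw <- parse_param_file(path)
  if (is.null(raw$BYTORDP)) {
    nmr_warn(sprintf("%s lacks BYTORDP; assuming little-endian", path))
  }
  p <- structure(list(
    offset_ppm = as.numeric(raw$OFFSET %||% NA_real_),
    sw_p_hz = as.numeric(raw$SW_p %||% NA_real_),
    sf_mhz = as.numeric(raw$SF %||% NA_real_),
    si = as.integer(raw$SI %||% NA_integer_),
    nc_proc = as.integer(raw$NC_proc %||% 0L),
    bytordp = as.integer(raw$BYTORDP %||% 0L),
    dtypp = as.integer(raw$DTYPP %||% 0L),
    raw = raw
  ), class = "procs_params")
  if (is.na(p$si) || p$si <= 0L) {
    nmr_error("malformed_parameter_error", sprintf("%s: SI missing or not positive", path))
  }
  if (!is.na(p$sw_p_hz) && p$sw_p_hz <= 0 || !is.na(p$sf_mhz) && p$sf_mhz <= 0) {
    nmr_error("malformed_parameter_error", sprintf("%s: SW_p and SF must be positive", path))
  }
  p
}

#' Decode a Bruker 1r binary
#'
#' Reads `SI` stored values honouring the byte order (`BYTORDP`) and word
#' type (`DTYPP`: 0 = int32, 2 = float64), then applies the
#' \eqn{2^{NC\_proc}} intensity scaling.  Trailing bytes beyond `SI` words
#' are ignored with a warning; a short file is an error.
#'
#' @param path path to a `1r` file.
#' @param procs a `procs_params` object.
#' @return numeric vector of `SI` intensities.
#' @export
read_1r <- function(path, procs) {
  stopifnot(inherits(procs, "procs_params"))
  if (!file.exists(path)) {
    nmr_error("io_error", sprintf("1r file not found: %s", path))
  }
  word <- switch(as.character(procs$dtypp),
                 "0" = 4L, "2" = 8L,
                 nmr_error("unsupported_dtype_error",
                           sprintf("unsupported DTYPP %d in %s (only 0 = int32 and 2 = float64)",
                                   procs$dtypp, path)))
  endian <- if (procs$bytordp == 1L) "big" else "little"
  size <- file.info(path)$size
  need <- as.numeric(procs$si) * word
  if (size < need) {
    nmr_error("truncated_file_error", sprintf(
      "1r file %s holds %d bytes but SI=%d DTYPP=%d requires %d",
      path, size, procs$si, procs$dtypp, need))
  }
  if (size > need) {
    nmr_warn(sprintf("%s: %d trailing bytes beyond SI words ignored", path, size - need))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  stored <- if (word == 4L) {
    readBin(con, integer(), n = procs$si, size = 4L, endian = endian)
  } else {
    readBin(con, double(), n = procs$si, size = 8L, endian = endian)
  }
  as.numeric(stored) * 2^procs$nc_proc
}

#' Chemical-shift axis for a processed spectrum
#'
#' `ppm[i] = OFFSET - i * SW_p / (SF * SI)` for `i = 0 ... SI-1`: the first
#' point sits at OFFSET and the axis decreases with constant step
#' `SW_p/(SF*SI)` (the dominant convention among reference Bruker readers).
#'
#' @param procs a `procs_params` object.
#' @return strictly decreasing numeric vector of length `SI`.
#' @export
ppm_axis <- function(procs) {
  stopifnot(inherits(procs, "procs_params"))
  if (procs$si < 2L) {
    nmr_error("malformed_parameter_error",
              sprintf("degenerate ppm axis: SI = %d", procs$si))
  }
  step <- procs$sw_p_hz / (procs$sf_mhz * procs$si)
  procs$offset_ppm - (seq_len(procs$si) - 1L) * step
}

# Read one experiment's spectrum (decoded + referenced).
read_spectrum <- function(sample_label, exp) {
  intensity <- read_1r(exp$path_1r, exp$procs)
  structure(list(
    sample_label = sample_label,
    expno = exp$expno,
    ppm = ppm_axis(exp$procs),
    intensity = intensity
  ), class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s expno %d: %d points, %.4f..%.4f ppm\n",
              x$sample_label, x$expno, length(x$ppm),
              x$ppm[1L], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' List experiment types present in a study
#'
#' Collects the pulse-program (`PULPROG`) names over all experiments that
#' are fully usable (1r + procs + acqus), with the number of samples
#' offering each.  Samples without a readable `acqus` contribute nothing and
#' trigger a warning.
#'
#' @param tree a `study_tree`.
#' @return named integer vector: pulse program -> number of samples.
#' @export
list_experiment_types <- function(tree) {
  stopifnot(inherits(tree, "study_tree"))
  counts <- integer(0)
  for (s in tree$samples) {
    progs <- character(0)
    saw_acqus <- FALSE
    for (e in s$experiments) {
      if (is.null(e$acqus)) next
      saw_acqus <- TRUE
      if (experiment_usable(e) && nzchar(e$acqus$pulprog)) {
        progs <- c(progs, e$acqus$pulprog)
      }
    }
    if (!saw_acqus && length(s$experiments)) {
      nmr_warn(sprintf("sample '%s' has no readable acqus; excluded from experiment listing",
                       s$label))
    }
    for (p in unique(progs)) {
      counts[p] <- (if (p %in% names(counts)) counts[[p]] else 0L) + 1L
    }
  }
  counts[order(names(counts), method = "radix")]
}
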