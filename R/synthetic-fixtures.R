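# Synthetic Bruker study generator.
#
# Builds complete, self-consistent study trees — Lorentzian spectra encoded
# as int32 1r binaries, JCAMP-DX parameter files, metadata stubs — in any
# catalogued layout dialect, with optional per-sample defect injection.
# Every other module is tested against these trees, so no repository
# download is ever needed.

#' Specification of a synthetic study
#'
#' @param n_samples number of samples.
#' @param si points per spectrum (SI).
#' @param offset_ppm chemical shift of the first point (OFFSET), ppm.
#' @param sw_p_hz spectral width (SW_p), Hz; the default spans 14 ppm at the
#'   default spectrometer frequency.
#' @param sf_mhz spectrometer frequency (SF), MHz.
#' @param peaks data frame with columns `center` (ppm), `width` (half width
#'   at half maximum, ppm), `amplitude`; all peak centers must lie inside
#'   the spectral window.
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units.
#' @param nc_proc intensity scaling exponent written to procs; stored
#'   integers are `round(intensity / 2^nc_proc)`.
#' @param pulprogs pulse program names; each sample gets one experiment per
#'   pulse program (expnos 10, 20, ...).
#' @param seed RNG seed controlling noise and per-sample amplitude jitter.
#' @param variant layout dialect the tree is scrambled into after
#'   generation (one of the shipped catalogue ids).
#' @param defects list of `c(sample_index, defect_code)` pairs (1-based
#'   sample index; codes `missing_1r`, `missing_procs`, `missing_acqus`,
#'   `empty_sample`).
#' @param sample_labels optional explicit sample directory names.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(n_samples = 5L, si = 16384L, offset_ppm = 12.0,
                       sf_mhz = 600.13, sw_p_hz = 14 * sf_mhz,
                       peaks = default_peaks(), noise_sd = 50,
                       nc_proc = -3L, pulprogs = "noesygppr1d",
                       seed = 1L, variant = "STD", defects = list(),
                       sample_labels = NULL) {
  stopifnot(n_samples >= 1L, si >= 2L, sw_p_hz > 0, sf_mhz > 0, noise_sd >= 0)
  lo <- offset_ppm - sw_p_hz / sf_mhz
  if (any(peaks$center >= offset_ppm | peaks$center <= lo)) {
    nmr_error("io_error", sprintf(
      "peak centers must lie inside the spectral window (%.3f, %.3f) ppm", lo, offset_ppm))
  }
  if (is.null(sample_labels)) {
    sample_labels <- sprintf("Sample%02d", seq_len(n_samples))
  }
  stopifnot(length(sample_labels) == n_samples, !anyDuplicated(sample_labels))
  structure(list(
    n_samples = as.integer(n_samples), si = as.integer(si),
    offset_ppm = offset_ppm, sw_p_hz = sw_p_hz, sf_mhz = sf_mhz,
    peaks = peaks, noise_sd = noise_sd, nc_proc = as.integer(nc_proc),
    pulprogs = pulprogs, seed = as.integer(seed), variant = variant,
    defects = defects, sample_labels = sample_labels
  ), class = "synth_spec")
}

# A handful of serum-like resonances: anomeric/glucose region, lactate
# doublet region, alanine, acetate-ish singlet, lipid envelope.
default_peaks <- function() {
  data.frame(
    center    = c(8.4963, 5.23, 4.10, 3.25, 2.04, 1.33, 0.90),
    width     = c(0.004, 0.006, 0.005, 0.008, 0.006, 0.010, 0.012),
    amplitude = c(2e5, 1.5e5, 3e5, 4e5, 2.5e5, 6e5, 3.5e5)
  )
}

lorentzian_mixture <- function(ppm, peaks) {
  y <- numeric(length(ppm))
  for (k in seq_len(nrow(peaks))) {
    w2 <- peaks$width[k]^2
    y <- y + peaks$amplitude[k] * w2 / ((ppm - peaks$center[k])^2 + w2)
  }
  y
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

write_acqus_file <- function(path, pulprog) {
  writeLines(c(
    "##TITLE= Parameter file, synthetic study",
    "##JCAMPDX= 5.0",
    "##DATATYPE= Parameter Values",
    sprintf("##$PULPROG= <%s>", pulprog),
    "##$BYTORDA= 0",
    "##$NS= 32",
    "##$TD= 32768",
    "##END="
  ), path)
}

write_procs_file <- function(path, spec) {
  writeLines(c(
    "##TITLE= Parameter file, synthetic study",
    "##JCAMPDX= 5.0",
    sprintf("##$OFFSET= %.10g", spec$offset_ppm),
    sprintf("##$SW_p= %.10g", spec$sw_p_hz),
    sprintf("##$SF= %.10g", spec$sf_mhz),
    sprintf("##$SI= %d", spec$si),
    sprintf("##$NC_proc= %d", spec$nc_proc),
    "##$BYTORDP= 0",
    "##$DTYPP= 0",
    "##END="
  ), path)
}

write_1r_file <- function(path, intensity, nc_proc) {
  stored <- round(intensity / 2^nc_proc)
  if (any(abs(stored) > .Machine$integer.max)) {
    nmr_error("amplitude_error",
              "amplitude too large: scaled intensities overflow int32; lower amplitudes or raise nc_proc")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(stored), con, size = 4L, endian = "little")
}

#' Generate a synthetic Bruker study tree
#'
#' Writes a complete study at `out_root`: per-sample Lorentzian-mixture
#' spectra (with per-sample amplitude jitter and Gaussian noise) quantized
#' to int32 `1r` binaries, `acqu`/`acqus` and `procs` parameter files,
#' metadata stubs — first in the canonical layout, then scrambled into
#' `spec$variant` with any requested defects applied.  Deterministic given
#' `spec$seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [synth_spec()].
#' @param out_root directory to create the study in (created; must not
#'   already contain a study).
#' @return list with `root` (the study path), `tree` (indexed
#'   [index_tree()] result), `truth` (per-pulprog list of pre-quantization
#'   sample-by-point intensity matrices, rows named by sample) and `ppm`
#'   (the ppm axis).
#' @export
generate_study <- function(spec, out_root) {
  stopifnot(inherits(spec, "synth_spec"))
  if (dir.exists(out_root) && length(list.files(out_root, all.files = TRUE, no.. = TRUE))) {
    nmr_error("io_error", sprintf("output directory not empty: %s", out_root))
  }
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

  step <- spec$sw_p_hz / (spec$sf_mhz * spec$si)
  ppm <- spec$offset_ppm - (seq_len(spec$si) - 1L) * step

  truth <- with_preserved_rng(spec$seed, {
    out <- lapply(spec$pulprogs, function(p) {
      m <- matrix(0, nrow = spec$n_samples, ncol = spec$si,
                  dimnames = list(spec$sample_labels, NULL))
      m
    })
    names(out) <- spec$pulprogs
    for (i in seq_len(spec$n_samples)) {
      jitter <- stats::runif(nrow(spec$peaks), 0.85, 1.15)
      pk <- spec$peaks
      pk$amplitude <- pk$amplitude * jitter
      base <- lorentzian_mixture(ppm, pk)
      for (j in seq_along(spec$pulprogs)) {
        noise <- if (spec$noise_sd > 0) stats::rnorm(spec$si, 0, spec$noise_sd) else 0
        out[[j]][i, ] <- base + noise
      }
    }
    out
  })

  # metadata stubs + audit
  writeLines("assay stub", file.path(out_root, "a_assay.txt"))
  writeLines("investigation stub", file.path(out_root, "i_investigation.txt"))
  writeLines("metabolite assignment stub", file.path(out_root, "m_metabolites.txt"))
  writeLines("sample metadata stub", file.path(out_root, "s_samples.txt"))
  writeLines("audit trail stub", file.path(out_root, "audit"))

  for (i in seq_len(spec$n_samples)) {
    lbl <- spec$sample_labels[i]
    for (j in seq_along(spec$pulprogs)) {
      expno <- 10L * j
      edir <- file.path(out_root, lbl, lbl, expno)
      pdir <- file.path(edir, "pdata", "1")
      dir.create(pdir, recursive = TRUE)
      write_acqus_file(file.path(edir, "acqus"), spec$pulprogs[j])
      file.copy(file.path(edir, "acqus"), file.path(edir, "acqu"))
      write_procs_file(file.path(pdir, "procs"), spec)
      write_1r_file(file.path(pdir, "1r"), truth[[j]][i, ], spec$nc_proc)
    }
  }

  apply_defects(out_root, spec)
  scramble_tree(out_root, spec$variant)

  list(root = out_root, tree = index_tree(out_root), truth = truth, ppm = ppm)
}

apply_defects <- function(root, spec) {
  for (d in spec$defects) {
    idx <- as.integer(d[[1L]])
    code <- as.character(d[[2L]])
    if (idx < 1L || idx > spec$n_samples) {
      nmr_error("io_error", sprintf("defect sample index %d out of range", idx))
    }
    lbl <- spec$sample_labels[idx]
    sdir <- file.path(root, lbl, lbl)
    switch(code,
      missing_1r = unlink(list.files(sdir, pattern = "^1r$", recursive = TRUE,
                                     full.names = TRUE)),
      missing_procs = unlink(list.files(sdir, pattern = "^procs$", recursive = TRUE,
                                        full.names = TRUE)),
      missing_acqus = unlink(list.files(sdir, pattern = "^acqus$", recursive = TRUE,
                                        full.names = TRUE)),
      empty_sample = {
        # strip each expno directory down to an empty shell: the sample is
        # still indexed (digit dirs remain) but offers no experiment
        for (e in list.dirs(sdir, recursive = FALSE)) {
          unlink(list.files(e, full.names = TRUE, all.files = TRUE, no.. = TRUE),
                 recursive = TRUE)
        }
      },
      nmr_error("io_error", sprintf("unknown defect code '%s'", code))
    )
  }
  invisible(root)
}

# Rewrite a canonical-layout tree in place into the requested dialect.
# Inverse of the variant's transform plan; covers the shipped catalogue.
scramble_tree <- function(root, variant_id) {
  switch(variant_id,
    STD = invisible(root),
    FLAT = {
      for (s in list.dirs(root, recursive = FALSE)) {
        inner <- file.path(s, basename(s))
        if (!dir.exists(inner)) next
        for (f in list.files(inner, full.names = TRUE, all.files = TRUE, no.. = TRUE)) {
          file.rename(f, file.path(s, basename(f)))
        }
        unlink(inner, recursive = TRUE)
      }
    },
    DOUBLE_WRAP = {
      wrapper <- file.path(root, "upload")
      dir.create(wrapper)
      for (f in list.files(root, full.names = TRUE, all.files = TRUE, no.. = TRUE)) {
        if (normalizePath(f) == normalizePath(wrapper)) next
        file.rename(f, file.path(wrapper, basename(f)))
      }
    },
    ZIPPED = {
      for (s in list.dirs(root, recursive = FALSE)) {
        zip_dir(s, paste0(s, ".zip"))
        unlink(s, recursive = TRUE)
      }
    },
    NO_PDATA_PROCNO = {
      pdatas <- list.dirs(root, recursive = TRUE)
      pdatas <- pdatas[basename(pdatas) == "pdata"]
      for (p in pdatas) {
        for (procno in list.dirs(p, recursive = FALSE)) {
          for (f in list.files(procno, full.names = TRUE)) {
            file.rename(f, file.path(p, basename(f)))
          }
          unlink(procno, recursive = TRUE)
        }
      }
    },
    LOOSE_META = {
      mdir <- file.path(root, "metadata")
      dir.create(mdir)
      for (f in list.files(root, full.names = TRUE)) {
        if (dir.exists(f)) next
        if (any(startsWith(basename(f), metadata_prefixes))) {
          file.rename(f, file.path(mdir, basename(f)))
        }
      }
    },
    nmr_error("io_error", sprintf("no scrambler for variant '%s'", variant_id))
  )
  invisible(root)
}
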