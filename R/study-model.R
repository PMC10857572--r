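# Study model: accession parsing, study-tree indexing, validation.
#
# The canonical ("standard") study layout this package converts everything
# into looks like:
#
#   <study>/
#     a_*, i_*, m_*, s_*, audit*          metadata files (optional)
#     <sample>/<sample>/<expno>/          doubled sample dir, numeric expno
#         acqu, acqus                     acquisition parameters (JCAMP-DX)
#         fid                             raw FID (optional; never read)
#         pdata/<procno>/procs, 1r        processing params + real spectrum
#
# Indexing never inspects file contents beyond parameter files: structure,
# not naming, identifies samples and experiments.

#' Parse a repository study accession
#'
#' Accessions beginning with `MTBLS` belong to MetaboLights and those
#' beginning with `ST` to Metabolomics Workbench; both prefixes are matched
#' case-insensitively and must be followed by at least one digit.
#'
#' @param text accession string, e.g. `"MTBLS326"` or `"ST000001"`.
#' @return a `study_id` object with fields `repository`
#'   (`"metabolights"` or `"workbench"`) and `accession` (upper-cased).
#' @examples
#' parse_study_id("MTBLS326")
#' parse_study_id("st000001")
#' @export
parse_study_id <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    nmr_error("invalid_accession_error",
              "study id must be a single non-empty string")
  }
  acc <- toupper(trimws(text))
  repository <- if (grepl("^MTBLS[0-9]+$", acc)) {
    "metabolights"
  } else if (grepl("^ST[0-9]+$", acc)) {
    "workbench"
  } else {
    nmr_error("invalid_accession_error", sprintf(
      "invalid study id '%s': accepted patterns are MTBLS<digits> (MetaboLights) or ST<digits> (Metabolomics Workbench)",
      text))
  }
  structure(list(repository = repository, accession = acc),
            class = "study_id")
}

#' @export
print.study_id <- function(x, ...) {
  cat(sprintf("<study_id> %s (%s)\n", x$accession, x$repository))
  invisible(x)
}

metadata_prefixes <- c(a = "a_", i = "i_", m = "m_", s = "s_", audit = "audit")

# A directory is an experiment directory when its name is all digits and it
# holds an acqus or fid file (or a pdata directory, so parameter-less but
# processed experiments are still indexed).  Bare all-digit directories make
# their ancestor a candidate sample but are not experiments themselves
# (pdata/<procno> directories never qualify: they hold procs/1r only).
is_experiment_dir <- function(path) {
  if (!grepl("^[0-9]+$", basename(path))) return(FALSE)
  file.exists(file.path(path, "acqus")) ||
    file.exists(file.path(path, "fid")) ||
    dir.exists(file.path(path, "pdata"))
}

# Locate every experiment directory below `root` (any depth).
find_experiment_dirs <- function(root) {
  dirs <- list.dirs(root, recursive = TRUE, full.names = TRUE)
  dirs[vapply(dirs, is_experiment_dir, logical(1))]
}

# Any all-digit directory below `root`, qualifying or not.
has_digit_dirs <- function(root) {
  dirs <- list.dirs(root, recursive = TRUE, full.names = FALSE)
  any(grepl("(^|/)[0-9]+$", dirs))
}

# Lowest-numbered procno under pdata that holds a 1r; falls back to a bare
# pdata/1r (non-standard layouts) with procno recorded as NA.
locate_1r <- function(exp_path) {
  pdata <- file.path(exp_path, "pdata")
  if (dir.exists(pdata)) {
    procnos <- list.dirs(pdata, recursive = FALSE, full.names = TRUE)
    procnos <- procnos[grepl("^[0-9]+$", basename(procnos))]
    if (length(procnos)) {
      procnos <- procnos[order(as.integer(basename(procnos)))]
      for (p in procnos) {
        if (file.exists(file.path(p, "1r"))) {
          return(list(procno = as.integer(basename(p)),
                      path_1r = file.path(p, "1r"),
                      path_procs = if (file.exists(file.path(p, "procs")))
                        file.path(p, "procs") else NA_character_))
        }
      }
    }
    if (file.exists(file.path(pdata, "1r"))) {
      return(list(procno = NA_integer_,
                  path_1r = file.path(pdata, "1r"),
                  path_procs = if (file.exists(file.path(pdata, "procs")))
                    file.path(pdata, "procs") else NA_character_))
    }
  }
  list(procno = NA_integer_, path_1r = NA_character_, path_procs = NA_character_)
}

index_experiment <- function(exp_path) {
  loc <- locate_1r(exp_path)
  acqus_path <- file.path(exp_path, "acqus")
  acqus <- if (file.exists(acqus_path)) {
    tryCatch(parse_acqus(acqus_path), error = function(e) NULL)
  } else NULL
  procs <- if (!is.na(loc$path_procs)) {
    tryCatch(parse_procs(loc$path_procs), error = function(e) NULL)
  } else NULL
  fid <- file.path(exp_path, "fid")
  structure(list(
    expno = as.integer(basename(exp_path)),
    path = exp_path,
    procno = loc$procno,
    path_1r = loc$path_1r,
    path_fid = if (file.exists(fid)) fid else NA_character_,
    path_acqus = if (file.exists(acqus_path)) acqus_path else NA_character_,
    path_procs = loc$path_procs,
    acqus = acqus,
    procs = procs
  ), class = "experiment_entry")
}

#' Index a study directory into a study tree
#'
#' Walks a study directory (or a `.zip` archive, which is first extracted to
#' a scratch directory) and enumerates samples, experiments and top-level
#' metadata files.  A sample is any top-level directory containing, at any
#' depth, an experiment directory (an all-digit directory holding `acqus`,
#' `fid` or `pdata`); metadata files are matched by their leading-character
#' convention (`a_`, `i_`, `m_`, `s_`, `audit`).  Only structure and
#' parameter files are read.  Sample ordering is lexicographic by label, so
#' indexing is deterministic.
#'
#' @param root path to a study directory or zip archive.
#' @return a `study_tree` object.
#' @export
index_tree <- function(root) {
  if (!file.exists(root)) {
    nmr_error("io_error", sprintf("study root does not exist: %s", root))
  }
  if (!dir.exists(root) && grepl("\\.zip$", root, ignore.case = TRUE)) {
    scratch <- tempfile("nmrbridge_unzip_")
    zip_extract(root, scratch)
    # if the archive wraps everything in a single directory, descend into it
    entries <- list.files(scratch, full.names = TRUE)
    root <- if (length(entries) == 1L && dir.exists(entries[1L])) entries[1L] else scratch
  }
  if (!dir.exists(root)) {
    nmr_error("io_error", sprintf("study root is not a directory: %s", root))
  }
  root <- normalizePath(root, winslash = "/")

  top_files <- list.files(root, full.names = TRUE)
  meta <- lapply(metadata_prefixes, function(p) {
    hit <- top_files[!dir.exists(top_files) & startsWith(basename(top_files), p)]
    if (length(hit)) hit[order(basename(hit))][1L] else NA_character_
  })

  top_dirs <- top_files[dir.exists(top_files)]
  samples <- list()
  for (d in top_dirs[order(basename(top_dirs), method = "radix")]) {
    if (!has_digit_dirs(d)) next     # not a sample; extra data are ignored
    exps <- find_experiment_dirs(d)
    exps <- exps[order(as.integer(basename(exps)))]
    entries <- lapply(exps, index_experiment)
    # expnos must be unique within a sample; duplicates cannot arise from a
    # filesystem walk but nested duplicates (same expno at two depths) can:
    # keep the shallowest.
    expnos <- vapply(entries, function(e) e$expno, integer(1))
    if (anyDuplicated(expnos)) {
      depth <- lengths(strsplit(exps, "/", fixed = TRUE))
      keep <- !duplicated(expnos[order(depth)])[order(order(depth))]
      entries <- entries[keep]
      expnos <- expnos[keep]
      entries <- entries[order(expnos)]
    }
    samples[[length(samples) + 1L]] <- structure(
      list(label = basename(d), path = d, experiments = entries),
      class = "sample_entry")
  }
  structure(list(
    root = root,
    study_label = basename(root),
    metadata_files = meta,
    samples = samples
  ), class = "study_tree")
}

sample_labels <- function(tree) {
  vapply(tree$samples, function(s) s$label, character(1))
}

#' @export
print.study_tree <- function(x, ...) {
  cat(sprintf("<study_tree> '%s' at %s\n", x$study_label, x$root))
  cat(sprintf("  samples: %d\n", length(x$samples)))
  present <- names(x$metadata_files)[!vapply(x$metadata_files, is.na, logical(1))]
  cat(sprintf("  metadata files: %s\n",
              if (length(present)) paste(present, collapse = ", ") else "none"))
  for (s in utils::head(x$samples, 8L)) {
    cat(sprintf("  - %s (%d experiment%s)\n", s$label, length(s$experiments),
                if (length(s$experiments) == 1L) "" else "s"))
  }
  if (length(x$samples) > 8L) cat(sprintf("  ... and %d more\n", length(x$samples) - 8L))
  invisible(x)
}

# An experiment is fully usable when 1r, procs and acqus are all present.
experiment_usable <- function(e) {
  !is.na(e$path_1r) && !is.null(e$procs) && !is.null(e$acqus)
}

#' Validate a study tree
#'
#' Checks that each sample offers at least one experiment with a readable
#' `1r` spectrum plus its `procs` and `acqus` parameter files.  Under the
#' default policy, defective samples are flagged and dropped from
#' `usable_samples` while the study remains valid as long as one usable
#' sample remains; with `strict = TRUE` any per-sample issue invalidates the
#' whole study.  Files beyond the canonical set are ignored.
#'
#' @param tree a `study_tree`.
#' @param strict reject the study outright on any per-sample defect.
#' @return a `validation_report` with fields `valid`, `per_sample_issues`
#'   (named list of issue codes: `missing_1r`, `missing_procs`,
#'   `missing_acqus`, `empty_sample`) and `usable_samples`.
#' @export
validate_study <- function(tree, strict = FALSE) {
  stopifnot(inherits(tree, "study_tree"))
  issues <- list()
  usable <- character(0)
  for (s in tree$samples) {
    codes <- character(0)
    if (!length(s$experiments)) {
      codes <- "empty_sample"
    } else {
      with_1r <- Filter(function(e) !is.na(e$path_1r), s$experiments)
      if (!length(with_1r)) {
        codes <- "missing_1r"
      } else {
        if (!any(vapply(with_1r, function(e) !is.null(e$procs), logical(1))))
          codes <- c(codes, "missing_procs")
        if (!any(vapply(with_1r, function(e) !is.null(e$acqus), logical(1))))
          codes <- c(codes, "missing_acqus")
      }
    }
    if (length(codes)) {
      issues[[s$label]] <- codes
      nmr_log("validate", sprintf("sample '%s' skipped: %s",
                                  s$label, paste(codes, collapse = ", ")), level = 2L)
    } else {
      usable <- c(usable, s$label)
    }
  }
  valid <- length(usable) > 0L && !(strict && length(issues) > 0L)
  structure(list(valid = valid, per_sample_issues = issues,
                 usable_samples = usable),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d usable sample%s, %d with issues\n",
              if (x$valid) "valid" else "INVALID",
              length(x$usable_samples),
              if (length(x$usable_samples) == 1L) "" else "s",
              length(x$per_sample_issues)))
  for (lbl in names(x$per_sample_issues)) {
    cat(sprintf("  - %s: %s\n", lbl, paste(x$per_sample_issues[[lbl]], collapse = ", ")))
  }
  invisible(x)
}

# Export-safe sample label: whitespace collapsed to underscores.
sanitize_label <- function(label) gsub("[[:space:]]+", "_", label)
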