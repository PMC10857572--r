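# Standardizer: rewrite a raw study into the canonical layout by applying a
# detected variant's transform plan to a copy of the tree.  The source is
# never modified (copy-then-transform), so the raw and canonical studies can
# coexist and both be handed back to the user.

copy_tree <- function(src, dst) {
  dir.create(dst, recursive = TRUE, showWarnings = FALSE)
  entries <- list.files(src, full.names = TRUE, all.files = TRUE, no.. = TRUE)
  ok <- file.copy(entries, dst, recursive = TRUE, copy.date = FALSE)
  if (!all(ok)) {
    nmr_error("io_error", sprintf("failed to copy study tree from %s to %s", src, dst))
  }
  invisible(dst)
}

apply_transform_step <- function(root, step) {
  p <- step$parameters
  rule <- p$rule %||% ""
  switch(step$kind,
    wrap_dir = {
      # double_sample_dirs: give each sample dir a same-named inner dir
      stopifnot(rule == "double_sample_dirs")
      for (s in list.dirs(root, recursive = FALSE)) {
        if (!has_digit_dirs(s)) next
        if (dir.exists(file.path(s, basename(s)))) next
        tmp <- file.path(root, paste0(".nmrbridge_wrap_", basename(s)))
        if (!file.rename(s, tmp)) {
          nmr_error("transform_error", sprintf("wrap_dir: cannot stage %s", s))
        }
        dir.create(s)
        if (!file.rename(tmp, file.path(s, basename(s)))) {
          nmr_error("transform_error", sprintf("wrap_dir: cannot nest %s", s))
        }
      }
    },
    unwrap_dir = {
      # single_top_dir: hoist the contents of the lone top-level directory
      stopifnot(rule == "single_top_dir")
      tops <- list.files(root, full.names = TRUE, all.files = TRUE, no.. = TRUE)
      dirs <- tops[dir.exists(tops)]
      if (length(dirs) != 1L || length(tops) != 1L) {
        nmr_error("transform_error",
                  sprintf("unwrap_dir: expected a single wrapper directory under %s", root))
      }
      for (f in list.files(dirs[1L], full.names = TRUE, all.files = TRUE, no.. = TRUE)) {
        target <- file.path(root, basename(f))
        if (file.exists(target)) {
          nmr_error("transform_error", sprintf("unwrap_dir: collision at %s", target))
        }
        file.rename(f, target)
      }
      unlink(dirs[1L], recursive = TRUE)
    },
    extract_archive = {
      pattern <- p$pattern %||% "\\.zip$"
      archives <- list.files(root, pattern = pattern, full.names = TRUE)
      if (!length(archives)) {
        nmr_error("transform_error",
                  sprintf("extract_archive: no archive matching '%s' under %s", pattern, root))
      }
      for (a in archives) {
        zip_extract(a, root)
        if (isTRUE(p$remove)) unlink(a)
      }
    },
    create_missing_dir = {
      stopifnot(rule == "procno_under_pdata")
      pdatas <- list.dirs(root, recursive = TRUE)
      pdatas <- pdatas[basename(pdatas) == "pdata"]
      for (pd in pdatas) {
        sub <- list.dirs(pd, recursive = FALSE)
        if (!any(grepl("^[0-9]+$", basename(sub)))) {
          dir.create(file.path(pd, p$name %||% "1"), showWarnings = FALSE)
        }
      }
    },
    move_files = {
      if (rule == "pdata_files_into_procno") {
        pdatas <- list.dirs(root, recursive = TRUE)
        pdatas <- pdatas[basename(pdatas) == "pdata"]
        for (pd in pdatas) {
          dest <- file.path(pd, p$procno %||% "1")
          if (!dir.exists(dest)) next
          files <- list.files(pd, full.names = TRUE)
          files <- files[!dir.exists(files)]
          for (f in files) file.rename(f, file.path(dest, basename(f)))
        }
      } else if (rule == "metadata_to_root") {
        dirs <- list.dirs(root, recursive = FALSE)
        moved_from <- character(0)
        for (d in dirs) {
          if (has_digit_dirs(d)) next  # never touch sample trees
          files <- list.files(d, full.names = TRUE)
          meta <- files[!dir.exists(files) &
                          apply_prefix_any(basename(files))]
          for (f in meta) {
            target <- file.path(root, basename(f))
            if (file.exists(target)) {
              nmr_error("transform_error", sprintf("move_files: collision at %s", target))
            }
            file.rename(f, target)
            moved_from <- c(moved_from, d)
          }
        }
        for (d in unique(moved_from)) {
          if (!length(list.files(d, all.files = TRUE, no.. = TRUE))) unlink(d, recursive = TRUE)
        }
      } else {
        nmr_error("transform_error", sprintf("move_files: unknown rule '%s'", rule))
      }
    },
    rename_by_pattern = {
      # from/to regular expressions applied to basenames at any depth
      files <- list.files(root, recursive = TRUE, full.names = TRUE, include.dirs = TRUE)
      hits <- files[grepl(p$from, basename(files))]
      for (f in hits) {
        file.rename(f, file.path(dirname(f), sub(p$from, p$to, basename(f))))
      }
    },
    nmr_error("transform_error", sprintf("unknown transform step kind '%s'", step$kind))
  )
  invisible(root)
}

apply_prefix_any <- function(basenames) {
  res <- rep(FALSE, length(basenames))
  for (p in metadata_prefixes) res <- res | startsWith(basenames, p)
  res
}

#' Standardize a study into the canonical layout
#'
#' Copies the study to `out_root` and applies the variant's transform plan,
#' yielding the canonical layout: metadata files at top level, one directory
#' per sample containing a same-named subdirectory, numeric expno
#' directories with `acqu`/`acqus` (and `fid` when present) and
#' `pdata/<procno>/` holding `procs` and `1r`.  The source tree is never
#' modified.
#'
#' @param tree a `study_tree` (or path / zip archive, indexed first).
#' @param variant the detected `layout_variant`; defaults to
#'   [detect_format()] on the tree.
#' @param out_root destination directory for the standardized study.
#' @param force overwrite a non-empty `out_root`.
#' @param make_zip also write `<study>_standard.zip` next to `out_root`
#'   (the archive form accepted by W4M's NMR_Read).
#' @return the re-indexed standardized `study_tree`; when `make_zip` is
#'   set the archive path is attached as attribute `"zip"`.
#' @export
standardize <- function(tree, variant = NULL, out_root, force = FALSE,
                        make_zip = FALSE) {
  if (is.character(tree)) tree <- index_tree(tree)
  stopifnot(inherits(tree, "study_tree"))
  if (is.null(variant)) variant <- detect_format(tree)
  stopifnot(inherits(variant, "layout_variant"))
  if (normalizePath(out_root, mustWork = FALSE) == tree$root) {
    nmr_error("io_error", "out_root must differ from the source tree root")
  }
  if (dir.exists(out_root) &&
      length(list.files(out_root, all.files = TRUE, no.. = TRUE))) {
    if (!force) {
      nmr_error("io_error",
                sprintf("output directory %s is not empty (use force)", out_root))
    }
    unlink(out_root, recursive = TRUE)
  }
  copy_tree(tree$root, out_root)
  nmr_log("standardize", sprintf("variant %s: applying %d transform step(s)",
                                 variant$variant_id, length(variant$transform_plan)))
  for (step in variant$transform_plan) {
    apply_transform_step(out_root, step)
  }
  out <- index_tree(out_root)
  if (make_zip) {
    zip_path <- file.path(dirname(normalizePath(out_root)),
                          paste0(basename(out_root), "_standard.zip"))
    zip_dir(out_root, zip_path)
    attr(out, "zip") <- zip_path
  }
  out
}

# Sorted relative file paths: the structural fingerprint used by the
# idempotence and round-trip checks.
tree_structure <- function(root) {
  paths <- list.files(root, recursive = TRUE, full.names = FALSE, all.files = TRUE)
  sort(paths)
}
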