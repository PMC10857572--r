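# Repository client: fetch a study's raw files by accession.
#
# All network specifics live behind a transport object, so the rest of the
# package (and the whole test suite) never touches the network: tests use
# local_transport() over a fixture directory.  Endpoint URL templates for
# the real repositories live in inst/extdata/endpoints.yaml, not in code,
# because repository layouts drift.
#
# A transport is a list with two functions:
#   manifest(id)               -> data.frame(relpath, size) for the study,
#                                 or signal a not_found_error
#   fetch(id, relpath, dest)   -> download one file to dest (TRUE on success)

#' Local-directory transport
#'
#' Serves studies from `<base_dir>/<accession>/...`; the transport used by
#' the test suite and by air-gapped deployments with a local mirror.
#'
#' @param base_dir directory holding one subdirectory per accession.
#' @return a transport object.
#' @export
local_transport <- function(base_dir) {
  list(
    manifest = function(id) {
      root <- file.path(base_dir, id$accession)
      if (!dir.exists(root)) {
        nmr_error("not_found_error",
                  sprintf("accession %s not found under %s", id$accession, base_dir))
      }
      files <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
      files <- files[!dir.exists(file.path(root, files))]
      data.frame(relpath = sort(files),
                 size = file.info(file.path(root, sort(files)))$size,
                 stringsAsFactors = FALSE)
    },
    fetch = function(id, relpath, dest) {
      src <- file.path(base_dir, id$accession, relpath)
      if (!file.exists(src)) return(FALSE)
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      file.copy(src, dest, overwrite = TRUE)
    }
  )
}

#' HTTP transport from an endpoint configuration
#'
#' Builds URLs from the templates in a YAML endpoint configuration (fields
#' `manifest_url` and `file_url`, with `{accession}` / `{relpath}`
#' placeholders; the manifest endpoint must return `relpath<TAB>size`
#' lines).  Requires network access; never used by the test suite.
#'
#' @param config parsed endpoint configuration for one repository.
#' @return a transport object.
#' @export
http_transport <- function(config) {
  fill <- function(template, id, relpath = NULL) {
    out <- gsub("{accession}", id$accession, template, fixed = TRUE)
    if (!is.null(relpath)) out <- gsub("{relpath}", relpath, out, fixed = TRUE)
    out
  }
  list(
    manifest = function(id) {
      lines <- tryCatch(readLines(fill(config$manifest_url, id), warn = FALSE),
                        error = function(e) {
                          nmr_error("not_found_error",
                                    sprintf("cannot list %s: %s", id$accession,
                                            conditionMessage(e)))
                        })
      parts <- strsplit(lines, "\t", fixed = TRUE)
      data.frame(relpath = vapply(parts, `[`, character(1), 1L),
                 size = as.numeric(vapply(parts, `[`, character(1), 2L)),
                 stringsAsFactors = FALSE)
    },
    fetch = function(id, relpath, dest) {
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      status <- tryCatch(utils::download.file(fill(config$file_url, id, relpath),
                                              dest, quiet = TRUE, mode = "wb"),
                         error = function(e) 1L)
      status == 0L
    }
  )
}

#' Default transport for an accession
#'
#' Reads `inst/extdata/endpoints.yaml` and returns an [http_transport()]
#' for the accession's repository.
#'
#' @param id a `study_id`.
#' @return a transport object.
#' @export
default_transport <- function(id) {
  path <- system.file("extdata", "endpoints.yaml", package = "nmrbridge")
  cfg <- yaml::read_yaml(path)
  http_transport(cfg[[id$repository]])
}

# Only these files are worth downloading for conversion: Bruker parameter
# and spectral files, per-sample archives, and the top-level metadata files.
bruker_relevant <- function(relpaths) {
  base <- basename(relpaths)
  grepl("^(acqus?|acqu\\.orig|fid|procs?|proc\\.orig|1r|1i)$", base) |
    grepl("\\.zip$", base, ignore.case = TRUE) |
    (!grepl("/", relpaths) & apply_prefix_any(base))
}

#' Fetch a study from a repository
#'
#' Downloads a study's files under `out_root/<accession>` through the given
#' transport, with up to `retries` attempts per file (exponential backoff)
#' and a size check against the manifest.  Fetching is resumable: files
#' already present with the manifest's size are skipped.  Archives are left
#' unextracted (extraction is the standardizer's job).  By default only
#' conversion-relevant files (Bruker parameter/spectral files, per-sample
#' archives, top-level metadata) are fetched; `all = TRUE` fetches
#' everything.
#'
#' @param id a `study_id` (see [parse_study_id()]).
#' @param out_root destination directory.
#' @param transport a transport object; defaults to the network transport
#'   configured for the accession's repository.
#' @param all fetch every manifest entry, not just conversion-relevant ones.
#' @param retries attempts per file.
#' @param backoff initial backoff in seconds (doubled per retry).
#' @return the study root path (`out_root/<accession>`), invisibly.
#' @export
fetch_study <- function(id, out_root, transport = default_transport(id),
                        all = FALSE, retries = 3L, backoff = 1) {
  stopifnot(inherits(id, "study_id"))
  manifest <- transport$manifest(id)
  if (!all) {
    keep <- bruker_relevant(manifest$relpath)
    nmr_log("fetch", sprintf("%d of %d manifest entries are conversion-relevant",
                             sum(keep), nrow(manifest)))
    manifest <- manifest[keep, , drop = FALSE]
  }
  root <- file.path(out_root, id$accession)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    relpath <- manifest$relpath[i]
    expected <- manifest$size[i]
    dest <- file.path(root, relpath)
    if (file.exists(dest) && !is.na(expected) &&
        isTRUE(file.info(dest)$size == expected)) {
      nmr_log("fetch", sprintf("skip %s (already complete)", relpath), level = 2L)
      next
    }
    ok <- FALSE
    for (attempt in seq_len(retries)) {
      ok <- isTRUE(transport$fetch(id, relpath, dest))
      if (ok) break
      nmr_warn(sprintf("fetch of %s failed (attempt %d/%d)", relpath, attempt, retries))
      if (attempt < retries) Sys.sleep(backoff * 2^(attempt - 1L))
    }
    if (!ok) {
      nmr_error("transport_error",
                sprintf("could not fetch %s after %d attempts", relpath, retries))
    }
    got <- file.info(dest)$size
    if (!is.na(expected) && !isTRUE(got == expected)) {
      nmr_error("transport_error", sprintf(
        "integrity check failed for %s: %d bytes downloaded, manifest says %d",
        relpath, got, expected))
    }
  }
  nmr_log("fetch", sprintf("%s: %d file(s) under %s", id$accession, nrow(manifest), root))
  invisible(root)
}
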