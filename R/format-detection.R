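# Layout-variant detection.
#
# Raw studies arrive in many directory dialects.  Each catalogued dialect is
# a layout_variant: a structural detection signature plus an ordered
# transform plan that rewrites the dialect into the canonical layout.
# Detection looks only at structure (path shapes), never at file contents.
#
# Signatures are lists of required / forbidden path patterns relative to the
# study root.  Pattern components are separated by "/" and each component is
# one of:
#   "#"        an all-digit name (expno / procno directories)
#   "=N"       a backreference: equals the N-th matched component
#   a glob     anything else, matched with shell-style wildcards (* ?)
# A required pattern must match at least one path in the tree; a forbidden
# pattern must match none.  Patterns match full relative paths (component
# counts must agree), which is what keeps e.g. the flat and doubled sample
# layouts structurally disjoint.

match_component <- function(comp, value, seen) {
  if (comp == "#") return(grepl("^[0-9]+$", value))
  if (grepl("^=[0-9]+$", comp)) {
    idx <- as.integer(substring(comp, 2L))
    return(idx <= length(seen) && identical(value, seen[idx]))
  }
  grepl(utils::glob2rx(comp), value)
}

path_matches_pattern <- function(relpath, pattern) {
  pc <- strsplit(pattern, "/", fixed = TRUE)[[1L]]
  vc <- strsplit(relpath, "/", fixed = TRUE)[[1L]]
  if (length(pc) != length(vc)) return(FALSE)
  for (i in seq_along(pc)) {
    if (!match_component(pc[i], vc[i], vc[seq_len(i - 1L)])) return(FALSE)
  }
  TRUE
}

any_path_matches <- function(relpaths, pattern) {
  for (p in relpaths) if (path_matches_pattern(p, pattern)) return(TRUE)
  FALSE
}

relative_paths <- function(root) {
  paths <- list.files(root, recursive = TRUE, full.names = FALSE,
                      all.files = TRUE, include.dirs = TRUE, no.. = TRUE)
  sort(paths)
}

signature_satisfied <- function(sig, relpaths) {
  req <- vapply(sig$required, function(p) any_path_matches(relpaths, p), logical(1))
  forb <- vapply(sig$forbidden %||% character(0),
                 function(p) any_path_matches(relpaths, p), logical(1))
  list(ok = all(req) && !any(forb),
       n_satisfied = sum(req) + sum(!forb),
       n_predicates = length(req) + length(forb))
}

#' Construct a layout variant
#'
#' @param variant_id short unique identifier, e.g. `"FLAT"`.
#' @param description human-readable account of the dialect.
#' @param required path patterns that must each match at least one path.
#' @param forbidden path patterns that must match no path.
#' @param transform_plan ordered list of transform steps (see
#'   [transform_step()]).
#' @return a `layout_variant` object.
#' @export
layout_variant <- function(variant_id, description, required,
                           forbidden = character(0), transform_plan = list()) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L, nzchar(variant_id))
  structure(list(
    variant_id = variant_id,
    description = description,
    signature = list(required = required, forbidden = forbidden),
    transform_plan = transform_plan
  ), class = "layout_variant")
}

#' @export
print.layout_variant <- function(x, ...) {
  cat(sprintf("<layout_variant> %s: %s\n", x$variant_id, x$description))
  cat(sprintf("  required: %s\n", paste(x$signature$required, collapse = " ; ")))
  if (length(x$signature$forbidden)) {
    cat(sprintf("  forbidden: %s\n", paste(x$signature$forbidden, collapse = " ; ")))
  }
  cat(sprintf("  transform steps: %d\n", length(x$transform_plan)))
  invisible(x)
}

#' Construct a transform step
#'
#' A transform step is a pure path manipulation (no file-content edits) of
#' one of the kinds `wrap_dir`, `unwrap_dir`, `rename_by_pattern`,
#' `extract_archive`, `create_missing_dir`, `move_files`; its `parameters`
#' select the paths it acts on (see the shipped catalogue for the rules in
#' use).
#'
#' @param kind step kind.
#' @param parameters named list of parameters.
#' @return a `transform_step` object.
#' @export
transform_step <- function(kind, parameters = list()) {
  kind <- match.arg(kind, c("wrap_dir", "unwrap_dir", "rename_by_pattern",
                            "extract_archive", "create_missing_dir", "move_files"))
  structure(list(kind = kind, parameters = parameters), class = "transform_step")
}

# ---------------------------------------------------------------------------
# Shipped catalogue.  The registry order is the documented resolution order:
# detection returns the FIRST variant whose signature is satisfied, with the
# canonical layout (STD) checked first.

meta_below_top <- paste0("*/", c("a_*", "i_*", "m_*", "s_*"))

builtin_variants <- function() {
  list(
    layout_variant("STD",
      "canonical layout: doubled sample dir, numeric expno, pdata/<procno>, metadata at top level",
      required = "*/=1/#/pdata/#",
      forbidden = c("*.zip", meta_below_top),
      transform_plan = list()),
    layout_variant("FLAT",
      "sample directories hold expno directories directly (no doubled sample level)",
      required = "*/#/pdata/#",
      forbidden = "*/=1/#/pdata/#",
      transform_plan = list(transform_step("wrap_dir", list(rule = "double_sample_dirs")))),
    layout_variant("DOUBLE_WRAP",
      "entire canonical study nested inside one extra top-level wrapper directory",
      required = "*/*/=2/#/pdata/#",
      forbidden = "*/=1/#/pdata/#",
      transform_plan = list(transform_step("unwrap_dir", list(rule = "single_top_dir")))),
    layout_variant("ZIPPED",
      "each sample shipped as a top-level zip archive",
      required = "*.zip",
      forbidden = c("*/=1/#/pdata/#", "*/#/pdata/#"),
      transform_plan = list(transform_step("extract_archive",
                                           list(pattern = "\\.zip$", remove = TRUE)))),
    layout_variant("NO_PDATA_PROCNO",
      "processed files sit directly under pdata, without a procno directory",
      required = "*/=1/#/pdata",
      forbidden = "*/=1/#/pdata/#",
      transform_plan = list(
        transform_step("create_missing_dir", list(rule = "procno_under_pdata", name = "1")),
        transform_step("move_files", list(rule = "pdata_files_into_procno", procno = "1")))),
    layout_variant("LOOSE_META",
      "canonical spectral layout but metadata files collected in a subdirectory",
      required = c("*/=1/#/pdata/#", meta_below_top),
      forbidden = character(0),
      transform_plan = list(transform_step("move_files", list(rule = "metadata_to_root"))))
  )
}

.registry <- new.env(parent = emptyenv())

registry_state <- function() {
  if (is.null(.registry$variants)) {
    .registry$variants <- builtin_variants()
    names(.registry$variants) <- vapply(.registry$variants,
                                        function(v) v$variant_id, character(1))
  }
  .registry$variants
}

#' The layout-variant registry
#'
#' @return named list of registered `layout_variant` objects, in resolution
#'   order.
#' @export
variant_registry <- function() registry_state()

#' Reset the registry to the shipped catalogue
#' @export
reset_variant_registry <- function() {
  .registry$variants <- NULL
  invisible(registry_state())
}

#' Register an additional layout variant
#'
#' Extends the registry (appended after the shipped catalogue, so built-in
#' resolution order is unchanged).  Registration is rejected when the id is
#' already taken or when the new signature matches one of the bundled
#' fixture trees already claimed by an existing variant, which would make
#' detection ambiguous.
#'
#' @param variant a `layout_variant`.
#' @param fixtures optional named list `variant_id -> fixture root` used for
#'   the mutual-exclusivity check; defaults to freshly generated miniature
#'   fixtures for the shipped catalogue.
#' @return the updated registry, invisibly.
#' @export
register_variant <- function(variant, fixtures = NULL) {
  stopifnot(inherits(variant, "layout_variant"))
  reg <- registry_state()
  if (variant$variant_id %in% names(reg)) {
    nmr_error("registry_error",
              sprintf("variant id '%s' is already registered", variant$variant_id))
  }
  if (is.null(fixtures)) fixtures <- bundled_variant_fixtures()
  for (vid in names(fixtures)) {
    relpaths <- relative_paths(fixtures[[vid]])
    if (signature_satisfied(variant$signature, relpaths)$ok) {
      nmr_error("registry_error", sprintf(
        "signature of '%s' also matches the fixture claimed by variant '%s'",
        variant$variant_id, vid))
    }
  }
  reg[[variant$variant_id]] <- variant
  .registry$variants <- reg
  invisible(reg)
}

# Miniature fixture per shipped variant (1 sample, 64 points) in a
# session-cached temp dir; used only for registration collision checks.
bundled_variant_fixtures <- function() {
  if (!is.null(.registry$fixtures) && all(dir.exists(unlist(.registry$fixtures)))) {
    return(.registry$fixtures)
  }
  base <- file.path(tempdir(), "nmrbridge_registry_fixtures")
  unlink(base, recursive = TRUE)
  fixtures <- list()
  for (v in builtin_variants()) {
    root <- file.path(base, v$variant_id, "study")
    spec <- synth_spec(n_samples = 1L, si = 64L, seed = 97L,
                       variant = v$variant_id)
    generate_study(spec, root)
    fixtures[[v$variant_id]] <- root
  }
  .registry$fixtures <- fixtures
  fixtures
}

#' Detect the layout variant of a study tree
#'
#' Evaluates the registered signatures in registry order against the tree's
#' path structure and returns the first match.  Detection depends only on
#' directory structure, never on file contents or timestamps.
#'
#' @param tree a `study_tree` (or a path, which is indexed first).
#' @return the matching `layout_variant`.
#' @export
detect_format <- function(tree) {
  if (is.character(tree)) tree <- index_tree(tree)
  stopifnot(inherits(tree, "study_tree"))
  relpaths <- relative_paths(tree$root)
  partial <- list()
  for (v in registry_state()) {
    res <- signature_satisfied(v$signature, relpaths)
    if (res$ok) return(v)
    partial[[v$variant_id]] <- sprintf("%d/%d predicates satisfied",
                                       res$n_satisfied, res$n_predicates)
  }
  nmr_error("unrecognized_format_error",
            paste0("no registered layout variant matches this study; closest: ",
                   paste(sprintf("%s (%s)", names(partial), unlist(partial)),
                         collapse = ", ")),
            partial_matches = partial)
}

#' Write the registry to a YAML file
#'
#' @param path output path.
#' @param registry registry to serialize; defaults to the active one.
#' @export
write_variant_registry <- function(path, registry = variant_registry()) {
  payload <- lapply(unname(registry), function(v) {
    list(variant_id = v$variant_id,
         description = v$description,
         required = as.list(v$signature$required),
         forbidden = as.list(v$signature$forbidden),
         transform_plan = lapply(v$transform_plan, function(s) {
           list(kind = s$kind, parameters = s$parameters)
         }))
  })
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read a registry from a YAML file
#'
#' @param path YAML file written by [write_variant_registry()].
#' @return named list of `layout_variant` objects (does not replace the
#'   active registry; assign via [register_variant()] or use directly).
#' @export
read_variant_registry <- function(path) {
  payload <- yaml::read_yaml(path)
  out <- lapply(payload, function(v) {
    layout_variant(v$variant_id, v$description,
                   required = unlist(v$required),
                   forbidden = unlist(v$forbidden) %||% character(0),
                   transform_plan = lapply(v$transform_plan, function(s) {
                     transform_step(s$kind, s$parameters)
                   }))
  })
  names(out) <- vapply(out, function(v) v$variant_id, character(1))
  out
}
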