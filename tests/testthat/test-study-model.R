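test_that("accession parsing infers the repository and normalizes case", {
  id <- parse_study_id("MTBLS326")
  expect_s3_class(id, "study_id")
  expect_equal(id$repository, "metabolights")
  expect_equal(id$accession, "MTBLS326")

  id <- parse_study_id("st000001")
  expect_equal(id$repository, "workbench")
  expect_equal(id$accession, "ST000001")

  expect_error(parse_study_id("XYZ123"), class = "invalid_accession_error")
  expect_error(parse_study_id("MTBLS"), class = "invalid_accession_error")
  expect_error(parse_study_id(""), class = "invalid_accession_error")
  # the error must name both accepted patterns
  expect_error(parse_study_id("XYZ123"), "MTBLS.*ST")
})

test_that("indexing enumerates samples, experiments and metadata files", {
  st <- local_study(n_samples = 3L)
  tree <- index_tree(st$root)
  expect_s3_class(tree, "study_tree")
  expect_length(tree$samples, 3L)
  expect_true(all(lengths(lapply(tree$samples, `[[`, "experiments")) == 1L))
  meta <- tree$metadata_files
  expect_false(anyNA(unlist(meta[c("a", "i", "m", "s", "audit")])))
  # sample labels unique and sorted
  labels <- vapply(tree$samples, `[[`, character(1), "label")
  expect_false(anyDuplicated(labels) > 0)
  expect_equal(labels, sort(labels))
})

test_that("sample names with whitespace survive indexing untouched", {
  st <- local_study(n_samples = 2L, sample_labels = c("Sam ple-01", "other s"))
  tree <- index_tree(st$root)
  labels <- vapply(tree$samples, `[[`, character(1), "label")
  expect_setequal(labels, c("Sam ple-01", "other s"))
  expect_equal(tree$samples[[1L]]$experiments[[1L]]$expno, 10L)
})

test_that("multiple experiments per sample are ordered by ascending expno", {
  st <- local_study(pulprogs = c("noesygppr1d", "cpmgpr1d"))
  tree <- index_tree(st$root)
  expnos <- vapply(tree$samples[[1L]]$experiments, `[[`, integer(1), "expno")
  expect_equal(expnos, c(10L, 20L))
})

test_that("indexing is deterministic and tolerates an empty directory", {
  st <- local_study()
  t1 <- index_tree(st$root)
  t2 <- index_tree(st$root)
  expect_identical(t1, t2)

  empty <- withr::local_tempdir()
  tree <- index_tree(empty)
  expect_length(tree$samples, 0L)
  expect_false(validate_study(tree)$valid)

  expect_error(index_tree(file.path(empty, "missing")), class = "io_error")
})

test_that("a zip archive can be indexed directly", {
  st <- local_study(n_samples = 2L)
  zip <- file.path(withr::local_tempdir(), "study.zip")
  nmrbridge:::zip_dir(st$root, zip)
  tree <- index_tree(zip)
  expect_length(tree$samples, 2L)
})

test_that("a fully conformant study validates with no issues", {
  quiet_logs()
  st <- local_study(n_samples = 3L)
  rep <- validate_study(index_tree(st$root))
  expect_true(rep$valid)
  expect_length(rep$per_sample_issues, 0L)
  expect_length(rep$usable_samples, 3L)
})

test_that("removing the 1r spectrum from every sample invalidates the study", {
  quiet_logs()
  st <- local_study(n_samples = 3L,
                    defects = list(c(1, "missing_1r"), c(2, "missing_1r"),
                                   c(3, "missing_1r")))
  rep <- validate_study(index_tree(st$root))
  expect_false(rep$valid)
  expect_length(rep$usable_samples, 0L)
  expect_true(all(vapply(rep$per_sample_issues, function(x) "missing_1r" %in% x,
                         logical(1))))
})

test_that("a single defective sample is dropped, not the whole study", {
  quiet_logs()
  st <- local_study(n_samples = 3L, defects = list(c(1, "missing_1r")))
  tree <- index_tree(st$root)
  rep <- validate_study(tree)
  expect_true(rep$valid)
  expect_length(rep$usable_samples, 2L)
  expect_equal(names(rep$per_sample_issues), "Sample01")
  expect_equal(rep$per_sample_issues[["Sample01"]], "missing_1r")

  # strict policy: any defect rejects the study outright
  expect_false(validate_study(tree, strict = TRUE)$valid)
})

test_that("missing parameter files and emptied samples are flagged by code", {
  quiet_logs()
  st <- local_study(n_samples = 4L,
                    defects = list(c(1, "missing_procs"), c(2, "missing_acqus"),
                                   c(3, "empty_sample")))
  rep <- validate_study(index_tree(st$root))
  expect_true(rep$valid)
  expect_equal(rep$usable_samples, "Sample04")
  expect_equal(rep$per_sample_issues[["Sample01"]], "missing_procs")
  expect_equal(rep$per_sample_issues[["Sample02"]], "missing_acqus")
  expect_equal(rep$per_sample_issues[["Sample03"]], "empty_sample")
})

test_that("usable samples are always a subset of the indexed samples", {
  quiet_logs()
  for (seed in 1:3) {
    st <- local_study(n_samples = 3L, seed = seed,
                      defects = if (seed == 2L) list(c(2, "missing_1r")) else list())
    tree <- index_tree(st$root)
    rep <- validate_study(tree)
    labels <- vapply(tree$samples, `[[`, character(1), "label")
    expect_true(all(rep$usable_samples %in% labels))
  }
})
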