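# Helpers to write parameter files / binaries directly (independent of the
# package's synthetic-study writers).
write_params <- function(lines, env = parent.frame()) {
  path <- file.path(withr::local_tempdir(.local_envir = env), "procs")
  writeLines(lines, path)
  path
}

write_int32 <- function(values, endian = "little", env = parent.frame()) {
  path <- file.path(withr::local_tempdir(.local_envir = env), "1r")
  con <- file(path, "wb")
  writeBin(as.integer(values), con, size = 4L, endian = endian)
  close(con)
  path
}

make_procs <- function(si, nc_proc = 0L, bytordp = 0L, dtypp = 0L,
                       offset = 10, sw_p = 1200, sf = 600) {
  structure(list(offset_ppm = offset, sw_p_hz = sw_p, sf_mhz = sf,
                 si = as.integer(si), nc_proc = as.integer(nc_proc),
                 bytordp = as.integer(bytordp), dtypp = as.integer(dtypp),
                 raw = list()),
            class = "procs_params")
}

test_that("JCAMP-DX records parse with content-based typing", {
  p <- write_params(c("##TITLE= t", "##$SI= 65536", "##$OFFSET= 14.8022",
                      "##$PULPROG= <noesygppr1d>", "##$BYTORDP= 0", "##END="))
  got <- parse_param_file(p)
  expect_identical(got$SI, 65536L)
  expect_identical(got$OFFSET, 14.8022)
  expect_identical(got$PULPROG, "noesygppr1d")  # angle brackets stripped
  expect_identical(got$BYTORDP, 0L)
})

test_that("multi-line array values are concatenated and typed", {
  p <- write_params(c("##$D= (0..3)", "0 0.5", "1.5 2", "##$SI= 8", "##END="))
  got <- parse_param_file(p)
  expect_equal(got$D, c(0, 0.5, 1.5, 2))
  expect_identical(got$SI, 8L)
})

test_that("missing and malformed parameter files fail loudly", {
  expect_error(parse_param_file(file.path(tempdir(), "nope")), class = "io_error")
  p <- write_params(c("just some text", "no records here"))
  expect_error(parse_param_file(p), class = "malformed_parameter_error")
})

test_that("1r decoding honours the 2^NC_proc scaling law", {
  f <- write_int32(0:3)
  expect_equal(read_1r(f, make_procs(4L, nc_proc = 0L)), c(0, 1, 2, 3))
  expect_equal(read_1r(f, make_procs(4L, nc_proc = 2L)), c(0, 4, 8, 12))
  expect_equal(read_1r(f, make_procs(4L, nc_proc = -1L)), c(0, 0.5, 1, 1.5))
})

test_that("1r decoding honours byte order and word type", {
  f_be <- write_int32(c(1L, -2L, 300000L), endian = "big")
  expect_equal(read_1r(f_be, make_procs(3L, bytordp = 1L)), c(1, -2, 300000))

  # float64 payload (DTYPP 2)
  path <- file.path(withr::local_tempdir(), "1r")
  con <- file(path, "wb")
  writeBin(c(0.25, -1.5, 1e7), con, size = 8L, endian = "little")
  close(con)
  expect_equal(read_1r(path, make_procs(3L, dtypp = 2L)), c(0.25, -1.5, 1e7))
})

test_that("short files, unknown dtypes and trailing bytes are handled", {
  f <- write_int32(0:3)
  expect_error(read_1r(f, make_procs(5L)), class = "truncated_file_error")
  expect_error(read_1r(f, make_procs(4L, dtypp = 1L)),
               class = "unsupported_dtype_error")
  expect_warning(got <- read_1r(f, make_procs(3L)), "trailing")
  expect_equal(got, c(0, 1, 2))
})

test_that("decoding agrees exactly with an independent numpy reader", {
  set.seed(404)
  values <- as.integer(runif(64L, -2^30, 2^30))
  f <- write_int32(values)
  got <- read_1r(f, make_procs(64L, nc_proc = -3L))
  script <- paste(
    "import sys, numpy as np",
    "a = np.fromfile(sys.argv[1], dtype='<i4') * 2.0**int(sys.argv[2])",
    "print('\\n'.join(repr(float(x)) for x in a))",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script), shQuote(f), "-3"),
                 stdout = TRUE)
  expect_equal(got, as.numeric(out), tolerance = 0)
})

test_that("decoding agrees with a brute-force byte-level reader", {
  # independent oracle: assemble each int32 from its raw bytes by hand
  set.seed(77)
  values <- as.integer(runif(32L, -2^28, 2^28))
  f <- write_int32(values, endian = "big")
  bytes <- as.integer(readBin(f, "raw", n = 128L))
  oracle <- vapply(seq_len(32L), function(i) {
    b <- bytes[(4L * (i - 1L) + 1L):(4L * i)]          # big-endian order
    u <- ((b[1] * 256 + b[2]) * 256 + b[3]) * 256 + b[4]
    if (u >= 2^31) u <- u - 2^32
    u * 2^-2
  }, numeric(1))
  expect_equal(read_1r(f, make_procs(32L, nc_proc = -2L, bytordp = 1L)), oracle)
})

test_that("the ppm axis follows OFFSET - i * SW_p/(SF*SI)", {
  expect_equal(ppm_axis(make_procs(4L, offset = 10, sw_p = 1200, sf = 600)),
               c(10.0, 9.5, 9.0, 8.5))
  # first element is always OFFSET; spacing is constant; length is SI
  p <- make_procs(65536L, offset = 14.8, sw_p = 12019.23, sf = 600.13)
  ax <- ppm_axis(p)
  expect_length(ax, 65536L)
  expect_equal(ax[1L], 14.8)
  steps <- diff(ax)
  expect_lt(max(abs(steps - mean(steps))), 1e-12)
  # brute-force loop evaluation of the closing point
  i <- 65535
  expect_equal(ax[65536L], 14.8 - i * 12019.23 / (600.13 * 65536))

  expect_error(ppm_axis(make_procs(1L)), class = "malformed_parameter_error")
})

test_that("experiment types are listed with per-pulprog sample counts", {
  quiet_logs()
  st <- local_study(n_samples = 3L, si = 128L)
  types <- list_experiment_types(index_tree(st$root))
  expect_equal(types, c(noesygppr1d = 3L))

  st2 <- local_study(n_samples = 2L, si = 128L,
                     pulprogs = c("noesygppr1d", "cpmgpr1d"))
  types2 <- list_experiment_types(index_tree(st2$root))
  expect_equal(types2, c(cpmgpr1d = 2L, noesygppr1d = 2L))
})

test_that("samples without acqus drop out of the experiment listing", {
  quiet_logs()
  st <- local_study(n_samples = 3L, si = 128L,
                    defects = list(c(1, "missing_acqus")))
  expect_warning(types <- list_experiment_types(index_tree(st$root)),
                 "no readable acqus")
  expect_equal(types, c(noesygppr1d = 2L))
})

test_that("generator-written spectra round-trip within quantization error", {
  st <- local_study(n_samples = 2L, si = 256L, noise_sd = 0)
  tree <- index_tree(st$root)
  for (i in seq_along(tree$samples)) {
    e <- tree$samples[[i]]$experiments[[1L]]
    got <- read_1r(e$path_1r, e$procs)
    truth <- st$truth[[1L]][tree$samples[[i]]$label, ]
    expect_lt(max(abs(got - truth)), import_tolerance(nc_proc = -3L))
  }
})
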