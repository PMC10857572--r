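make_spectrum <- function(label, ppm, intensity) {
  structure(list(sample_label = label, expno = 10L, ppm = ppm,
                 intensity = intensity), class = "nmr_spectrum")
}

test_that("importing a homogeneous study yields one row per sample on one grid", {
  quiet_logs()
  st <- local_study(n_samples = 3L, si = 512L)
  mat <- import_data(index_tree(st$root), "noesygppr1d")
  expect_s3_class(mat, "spectral_matrix")
  expect_equal(dim(mat), c(3L, 512L))
  expect_equal(mat$sample_labels, sprintf("Sample%02d", 1:3))
  expect_equal(mat$grid_ppm, st$ppm)  # identical grids pass through unchanged
  expect_equal(mat$provenance$pulprog, "noesygppr1d")
})

test_that("the lowest matching expno wins and is recorded in provenance", {
  quiet_logs()
  st <- local_study(n_samples = 2L, si = 128L,
                    pulprogs = c("noesygppr1d", "noesygppr1d"))
  mat <- import_data(index_tree(st$root), "noesygppr1d")
  expect_true(all(mat$provenance$expno_used == 10L))
})

test_that("importing an absent experiment type is an explicit error", {
  quiet_logs()
  st <- local_study(n_samples = 2L, si = 128L)
  expect_error(suppressWarnings(import_data(index_tree(st$root), "doesnotexist")),
               class = "empty_selection_error")
})

test_that("imported values match the generator's ground truth", {
  quiet_logs()
  noise_sd <- 50
  st <- local_study(n_samples = 3L, si = 512L, noise_sd = noise_sd)
  mat <- import_data(index_tree(st$root), "noesygppr1d")
  truth <- st$truth[[1L]][mat$sample_labels, ]
  # truth is pre-quantization, so only the int32 rounding remains
  expect_lt(max(abs(mat$values - truth)), 2^-3)
})

test_that("importing the same study twice is bit-identical", {
  quiet_logs()
  st <- local_study(n_samples = 2L, si = 256L)
  m1 <- import_data(index_tree(st$root), "noesygppr1d")
  m2 <- import_data(index_tree(st$root), "noesygppr1d")
  expect_identical(m1$values, m2$values)
  expect_identical(m1$grid_ppm, m2$grid_ppm)
})

test_that("alignment reproduces affine spectra exactly at grid points", {
  # linear interpolation is exact on affine functions
  ppm_a <- seq(10, 0, length.out = 101)
  ppm_b <- seq(9.5, -0.5, length.out = 81)
  f <- function(x) 3 * x + 7
  mat <- align_to_common_grid(list(make_spectrum("a", ppm_a, f(ppm_a)),
                                   make_spectrum("b", ppm_b, f(ppm_b))))
  expect_equal(mat$grid_ppm[1L], 9.5)                 # intersection upper end
  expect_equal(mat$grid_ppm[length(mat$grid_ppm)], 0) # intersection lower end
  expect_equal(mat$values[1L, ], f(mat$grid_ppm))
  expect_equal(mat$values[2L, ], f(mat$grid_ppm))
})

test_that("resampling matches a brute-force two-point interpolation oracle", {
  set.seed(12)
  ppm_a <- seq(10, 0, length.out = 41)
  step <- ppm_a[1L] - ppm_a[2L]
  ppm_b <- ppm_a - step / 2       # grid offset by half a step
  ya <- rnorm(41); yb <- rnorm(41)
  mat <- align_to_common_grid(list(make_spectrum("a", ppm_a, ya),
                                   make_spectrum("b", ppm_b, yb)))
  brute <- function(ppm, y, x) {
    vapply(x, function(xi) {
      hi <- max(which(ppm >= xi)); lo <- min(which(ppm <= xi))
      if (hi == lo) return(y[hi])
      w <- (ppm[hi] - xi) / (ppm[hi] - ppm[lo])
      (1 - w) * y[hi] + w * y[lo]
    }, numeric(1))
  }
  expect_equal(mat$values["a", ], brute(ppm_a, ya, mat$grid_ppm))
  expect_equal(mat$values["b", ], brute(ppm_b, yb, mat$grid_ppm))
})

test_that("alignment preserves spectral area for smooth synthetic spectra", {
  quiet_logs()
  st <- local_study(n_samples = 1L, si = 2048L, noise_sd = 0)
  base <- make_spectrum("a", st$ppm, st$truth[[1L]][1L, ])
  shifted <- make_spectrum("b", st$ppm - diff(range(st$ppm)) / (2048 * 3),
                           st$truth[[1L]][1L, ])
  mat <- align_to_common_grid(list(base, shifted))
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  area_in <- trapz(rev(st$ppm), rev(base$intensity))
  area_out <- trapz(rev(mat$grid_ppm), rev(mat$values["a", ]))
  expect_lt(abs(area_out - area_in) / abs(area_in), 0.005)
})

test_that("disjoint ppm ranges fail with the offending sample named", {
  a <- make_spectrum("inrange", seq(10, 5, length.out = 11), rep(1, 11))
  b <- make_spectrum("outlier", seq(2, 0, length.out = 11), rep(1, 11))
  err <- tryCatch(align_to_common_grid(list(a, b)), condition = function(c) c)
  expect_s3_class(err, "no_overlap_error")
  expect_match(conditionMessage(err), "outlier")
})

test_that("cleaning zeroes isolated non-finite values and drops dead columns", {
  quiet_logs()
  grid <- seq(10, 1, length.out = 10)
  v <- matrix(rnorm(30), nrow = 3)
  mat <- nmrbridge:::new_spectral_matrix(c("a", "b", "c"), grid, v)

  expect_identical(clean_matrix(mat)$values, mat$values)  # nothing to clean

  v2 <- v; v2[2, 4] <- NaN
  m2 <- clean_matrix(nmrbridge:::new_spectral_matrix(c("a", "b", "c"), grid, v2))
  expect_equal(unname(m2$values[2, 4]), 0)
  expect_equal(m2$provenance$n_cleaned, 1L)
  expect_equal(dim(m2), c(3L, 10L))

  v3 <- v; v3[, 7] <- Inf
  m3 <- clean_matrix(nmrbridge:::new_spectral_matrix(c("a", "b", "c"), grid, v3))
  expect_equal(dim(m3), c(3L, 9L))
  expect_equal(m3$grid_ppm, grid[-7])
  expect_true(all(is.finite(m3$values)))
})

test_that("the intermediate CSV re-parses losslessly", {
  quiet_logs()
  st <- local_study(n_samples = 2L, si = 128L)
  mat <- import_data(index_tree(st$root), "noesygppr1d")
  path <- file.path(withr::local_tempdir(), "intermediate.csv")
  write_intermediate_csv(mat, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_identical(unname(as.matrix(back[, -1L])), unname(mat$values))
})
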