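# Fixture helpers: every study tree used by the suite is generated in a
# self-deleting temp dir by the package's own synthetic-study module.

# All catalogued layout dialect ids, in registry order.
all_variants <- c("STD", "FLAT", "DOUBLE_WRAP", "ZIPPED", "NO_PDATA_PROCNO",
                  "LOOSE_META")

# Generate a small synthetic study and return the generate_study() result
# (root, tree, truth, ppm).  Lives until the calling test finishes.
local_study <- function(variant = "STD", n_samples = 3L, si = 512L,
                        seed = 42L, noise_sd = 50, defects = list(),
                        pulprogs = "noesygppr1d", sample_labels = NULL,
                        env = parent.frame()) {
  root <- file.path(withr::local_tempdir(.local_envir = env), "study")
  generate_study(
    synth_spec(n_samples = n_samples, si = si, seed = seed, variant = variant,
               noise_sd = noise_sd, defects = defects, pulprogs = pulprogs,
               sample_labels = sample_labels),
    root)
}

# Quantization + noise tolerance for imported-vs-truth comparisons.
import_tolerance <- function(nc_proc = -3L, noise_sd = 0) 2^nc_proc + 3 * noise_sd

# Byte-level fingerprint of a tree: relative path -> md5, in sorted order.
tree_checksums <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE, all.files = TRUE))
  sums <- unname(tools::md5sum(file.path(root, files)))
  stats::setNames(sums, files)
}

quiet_logs <- function(env = parent.frame()) {
  withr::local_options(nmrbridge.log_level = 0L, .local_envir = env)
}
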