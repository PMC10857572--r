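# Deterministic ZIP archives.
#
# Archives written here are byte-reproducible: members are stored (no
# compression), ordered lexicographically by archive name, and carry zeroed
# DOS timestamps.  Reproducibility is part of the pipeline contract (same
# inputs => byte-identical outputs, archives included), which rules out
# system zip tools that embed mtimes.

.crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  if (length(bytes)) {
    ints <- as.integer(bytes)
    for (b in ints) {
      crc <- bitwXor(bitwShiftR(crc, 8L),
                     .crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
    }
  }
  bitwXor(crc, -1L)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
write_u32 <- function(con, x) {
  # accept signed int32 representation or non-negative double < 2^32
  if (is.double(x) && x > .Machine$integer.max) x <- as.integer(x - 4294967296)
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

#' Create a deterministic ZIP archive
#'
#' Stores the given files (no compression) under the supplied archive names,
#' in lexicographic order of archive name and with zeroed timestamps, so the
#' same inputs always produce a byte-identical archive.
#'
#' @param files character vector of paths to existing files.
#' @param zipfile output archive path (overwritten).
#' @param arcnames archive member names; defaults to `basename(files)`.
#'   Forward slashes are the directory separator.
#' @return the archive path, invisibly.
#' @export
zip_create <- function(files, zipfile, arcnames = basename(files)) {
  if (length(files) == 0L) {
    nmr_error("io_error", "cannot create a zip archive with no members")
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    nmr_error("io_error", sprintf("zip member missing on disk: %s", missing[1L]))
  }
  if (anyDuplicated(arcnames)) {
    nmr_error("io_error", "duplicate archive member names")
  }
  ord <- order(arcnames, method = "radix")
  files <- files[ord]
  arcnames <- arcnames[ord]

  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  crcs <- integer(length(files))
  sizes <- numeric(length(files))
  pos <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", n = file.info(files[i])$size)
    name <- charToRaw(arcnames[i])
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    offsets[i] <- pos
    write_u32(con, 0x04034b50)      # local file header signature
    write_u16(con, 20L)             # version needed
    write_u16(con, 0L)              # flags
    write_u16(con, 0L)              # method: store
    write_u16(con, 0L)              # mod time (zeroed)
    write_u16(con, 0x21)            # mod date: 1980-01-01
    write_u32(con, crcs[i])
    write_u32(con, sizes[i])        # compressed size
    write_u32(con, sizes[i])        # uncompressed size
    write_u16(con, length(name))
    write_u16(con, 0L)              # extra length
    writeBin(name, con)
    if (length(data)) writeBin(data, con)
    pos <- pos + 30 + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    name <- charToRaw(arcnames[i])
    write_u32(con, 0x02014b50)      # central directory header
    write_u16(con, 20L)             # version made by
    write_u16(con, 20L)             # version needed
    write_u16(con, 0L); write_u16(con, 0L)
    write_u16(con, 0L); write_u16(con, 0x21)
    write_u32(con, crcs[i])
    write_u32(con, sizes[i]); write_u32(con, sizes[i])
    write_u16(con, length(name))
    write_u16(con, 0L); write_u16(con, 0L)
    write_u16(con, 0L); write_u16(con, 0L)
    write_u32(con, 0L)              # external attrs
    write_u32(con, offsets[i])
    writeBin(name, con)
    pos <- pos + 46 + length(name)
  }
  write_u32(con, 0x06054b50)        # end of central directory
  write_u16(con, 0L); write_u16(con, 0L)
  write_u16(con, length(files)); write_u16(con, length(files))
  write_u32(con, pos - cd_start)
  write_u32(con, cd_start)
  write_u16(con, 0L)
  invisible(zipfile)
}

# Extract an archive; relies on R's built-in unzip implementation.
zip_extract <- function(zipfile, exdir) {
  if (!file.exists(zipfile)) {
    nmr_error("io_error", sprintf("archive not found: %s", zipfile))
  }
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  utils::unzip(zipfile, exdir = exdir)
  invisible(exdir)
}

# Zip a directory tree rooted at `dir`, archive names relative to `dir`'s
# parent (so the tree unpacks under its own top-level directory).
zip_dir <- function(dir, zipfile) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE, all.files = TRUE,
                      no.. = TRUE)
  files <- files[!dir.exists(files)]
  base <- dirname(normalizePath(dir, winslash = "/"))
  rel <- substring(normalizePath(files, winslash = "/"), nchar(base) + 2L)
  zip_create(files, zipfile, arcnames = rel)
}
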