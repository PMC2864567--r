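# Minimal ZIP writer (no external zip executable required).
#
# Entries are deflate-compressed: memCompress() emits a zlib stream
# (2-byte header, deflate data, Adler-32 trailer), from which the raw
# deflate payload is cut; the CRC-32 a zip entry needs is computed here.
# Timestamps are fixed at 1980-01-01 so archives are byte-deterministic.
# Reading is left to utils::unzip.

le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320 as a signed 32-bit int
      tab <<- vapply(0:255, function(i) {
        c <- as.integer(i)
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L)) bitwXor(poly, bitwShiftR(c, 1L))
               else bitwShiftR(c, 1L)
        c
      }, integer(1))
    }
    tab
  }
})

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(data))
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

deflate_entry <- function(data) {
  zl <- memCompress(data, type = "gzip")  # zlib framing
  stopifnot(length(zl) > 6, zl[1] == as.raw(0x78))
  list(deflated = zl[3:(length(zl) - 4)],
       crc = le_bytes(crc32(data), 4),
       usize = length(data))
}

write_zip <- function(zipfile, root, files) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  entries <- vector("list", length(files))
  pos <- 0L
  for (k in seq_along(files)) {
    fp <- file.path(root, files[k])
    data <- readBin(fp, "raw", n = file.size(fp))
    e <- deflate_entry(data)
    nm <- charToRaw(files[k])
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                   le_bytes(20, 2),      # version needed
                   le_bytes(0, 2),       # flags
                   le_bytes(8, 2),       # method: deflate
                   le_bytes(0x21, 2),    # mod time (00:01:02, arbitrary)
                   le_bytes(0x21, 2),    # mod date (1980-01-01)
                   e$crc,
                   le_bytes(length(e$deflated), 4),
                   le_bytes(e$usize, 4),
                   le_bytes(length(nm), 2),
                   le_bytes(0, 2))       # extra length
    offsets[k] <- pos
    writeBin(c(local_hdr, nm, e$deflated), con)
    pos <- pos + length(local_hdr) + length(nm) + length(e$deflated)
    entries[[k]] <- e
  }
  cd_start <- pos
  cd_size <- 0L
  for (k in seq_along(files)) {
    e <- entries[[k]]
    nm <- charToRaw(files[k])
    central <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                 le_bytes(20, 2), le_bytes(20, 2),
                 le_bytes(0, 2), le_bytes(8, 2),
                 le_bytes(0x21, 2), le_bytes(0x21, 2),
                 e$crc,
                 le_bytes(length(e$deflated), 4),
                 le_bytes(e$usize, 4),
                 le_bytes(length(nm), 2),
                 le_bytes(0, 2), le_bytes(0, 2),  # extra, comment
                 le_bytes(0, 2), le_bytes(0, 2),  # disk, internal attrs
                 le_bytes(0, 4),                  # external attrs
                 le_bytes(offsets[k], 4))
    writeBin(c(central, nm), con)
    cd_size <- cd_size + length(central) + length(nm)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(files), 2), le_bytes(length(files), 2),
            le_bytes(cd_size, 4), le_bytes(cd_start, 4),
            le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(zipfile)
}
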