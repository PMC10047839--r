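# Minimal deterministic ZIP writer (STORE method, fixed timestamps) used for
# ImageJ ROI archives. Readable by utils::unzip and by ImageJ. Written by
# hand because the runtime image ships no zip-writing tool or package.

crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  tab <- integer(256)
  for (n in 0:255) {
    c <- as.integer(n)
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes))
    c <- bitwXor(bitwShiftR(c, 8L), crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  bitwXor(c, -1L)
}

uint32_le <- function(v) {
  # v: signed int32 or double in [0, 2^32); emit 4 little-endian bytes
  u <- if (v < 0) as.double(v) + 4294967296 else as.double(v)
  as.raw(c(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256,
           (u %/% 16777216) %% 256))
}

uint16_le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256))

write_store_zip <- function(entries, path) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    header <- c(uint32_le(67324752),          # local file header signature
                uint16_le(20), uint16_le(0),  # version, flags
                uint16_le(0),                 # method = STORE
                uint16_le(0), uint16_le(33),  # fixed mod time/date (1981-01-01)
                uint32_le(crcs[i]),
                uint32_le(length(data)), uint32_le(length(data)),
                uint16_le(length(name)), uint16_le(0))
    writeBin(c(header, name, data), con)
    pos <- pos + length(header) + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    rec <- c(uint32_le(33639248),             # central directory signature
             uint16_le(20), uint16_le(20), uint16_le(0), uint16_le(0),
             uint16_le(0), uint16_le(33),
             uint32_le(crcs[i]),
             uint32_le(length(data)), uint32_le(length(data)),
             uint16_le(length(name)), uint16_le(0), uint16_le(0),
             uint16_le(0), uint16_le(0), uint32_le(0),
             uint32_le(offsets[i]))
    writeBin(c(rec, name), con)
    pos <- pos + length(rec) + length(name)
  }
  eocd <- c(uint32_le(101010256), uint16_le(0), uint16_le(0),
            uint16_le(length(entries)), uint16_le(length(entries)),
            uint32_le(pos - cd_start), uint32_le(cd_start), uint16_le(0))
  writeBin(eocd, con)
  invisible(path)
}
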