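# Minimal little-endian MAT v5 writer used only to exercise the container
# reader. Writes uncompressed real double arrays.
write_mat5_stub <- function(path, arrays) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, synthetic test stub%s",
                              strrep(" ", 200)))[1:116]
  writeBin(header, con)
  writeBin(raw(8), con)                      # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)       # version 0x0100 (little-endian)
  writeBin(charToRaw("IM"), con)
  pad8 <- function(n) (8 - n %% 8) %% 8
  for (nm in names(arrays)) {
    A <- as.matrix(arrays[[nm]])
    name_raw <- charToRaw(nm)
    body_len <- 16 +                                   # array flags element
      16 +                                             # dims element
      8 + length(name_raw) + pad8(length(name_raw)) +  # name element
      8 + 8 * length(A)                                # data element
    writeBin(as.integer(c(14L, body_len)), con, size = 4)  # miMATRIX tag
    writeBin(as.integer(c(6L, 8L)), con, size = 4)         # flags tag miUINT32
    writeBin(as.integer(c(6L, 0L)), con, size = 4)         # mxDOUBLE_CLASS
    writeBin(as.integer(c(5L, 8L)), con, size = 4)         # dims tag miINT32
    writeBin(as.integer(dim(A)), con, size = 4)
    writeBin(as.integer(c(1L, length(name_raw))), con, size = 4)  # name miINT8
    writeBin(name_raw, con)
    if (pad8(length(name_raw))) writeBin(raw(pad8(length(name_raw))), con)
    writeBin(as.integer(c(9L, 8L * length(A))), con, size = 4)    # miDOUBLE
    writeBin(as.numeric(A), con, size = 8)
  }
  invisible(path)
}
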