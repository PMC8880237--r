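# Minimal MATLAB level-5 container reader.
#
# Only what the corn benchmark needs: real numeric arrays (double, single,
# integer classes), zlib-compressed elements, and struct/object arrays (the
# Eigenvector "dataset" objects), from which the numeric "data" field is
# extracted. Complex, sparse, cell and char payloads beyond array names are
# out of scope.

mi_sizes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
              `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_numeric <- function(raw, type, n, endian) {
  sz <- mi_sizes[[as.character(type)]]
  if (is.null(sz)) stop("unsupported MAT data type ", type)
  what <- if (type %in% c(7, 9)) "double" else "integer"
  signed <- !(type %in% c(2, 4))
  if (type %in% c(6, 13)) {
    # uint32/uint64: read as signed and fix up the sign bit for uint32
    v <- readBin(raw, "integer", n = n, size = min(sz, 4L),
                 signed = TRUE, endian = endian)
    v <- as.numeric(v)
    v[v < 0] <- v[v < 0] + 2^32
    return(v)
  }
  as.numeric(readBin(raw, what, n = n, size = sz, signed = signed,
                     endian = endian))
}

# One tagged data element starting at offset `pos` (1-based) in `buf`.
# Returns list(type, bytes, next_pos) honoring the small-element format.
mat5_element <- function(buf, pos, endian) {
  tagword <- readBin(buf[pos:(pos + 3)], "integer", size = 4, endian = endian)
  small_size <- bitwAnd(bitwShiftR(tagword, 16), 0xFFFF)
  type <- bitwAnd(tagword, 0xFFFF)
  if (small_size > 0) {
    bytes <- buf[(pos + 4):(pos + 3 + small_size)]
    list(type = type, bytes = bytes, next_pos = pos + 8)
  } else {
    nbytes <- readBin(buf[(pos + 4):(pos + 7)], "integer", size = 4,
                      endian = endian)
    bytes <- if (nbytes > 0) buf[(pos + 8):(pos + 7 + nbytes)] else raw(0)
    pad <- (8 - nbytes %% 8) %% 8
    list(type = type, bytes = bytes, next_pos = pos + 8 + nbytes + pad)
  }
}

mat5_parse_matrix <- function(bytes, endian) {
  pos <- 1L
  flags <- mat5_element(bytes, pos, endian)
  pos <- flags$next_pos
  flagword <- readBin(flags$bytes[1:4], "integer", size = 4, endian = endian)
  class_id <- bitwAnd(flagword, 0xFF)
  dims_el <- mat5_element(bytes, pos, endian)
  pos <- dims_el$next_pos
  dims <- read_mi_numeric(dims_el$bytes, dims_el$type,
                          length(dims_el$bytes) %/% 4L, endian)
  name_el <- mat5_element(bytes, pos, endian)
  pos <- name_el$next_pos
  name <- rawToChar(name_el$bytes[name_el$bytes != as.raw(0)])

  value <- NULL
  if (class_id %in% c(6, 7, 9, 10, 11, 12, 13, 14, 15)) {
    data_el <- mat5_element(bytes, pos, endian)
    n <- prod(dims)
    v <- read_mi_numeric(data_el$bytes, data_el$type, n, endian)
    value <- if (length(dims) == 2) matrix(v, dims[1], dims[2]) else v
  } else if (class_id %in% c(2, 3)) {
    # struct (2) or object (3); objects carry a class-name element first
    if (class_id == 3) {
      cls_el <- mat5_element(bytes, pos, endian)
      pos <- cls_el$next_pos
    }
    fl_el <- mat5_element(bytes, pos, endian)   # field name length (int32)
    pos <- fl_el$next_pos
    flen <- readBin(fl_el$bytes[1:4], "integer", size = 4, endian = endian)
    fn_el <- mat5_element(bytes, pos, endian)   # packed field names
    pos <- fn_el$next_pos
    nfields <- length(fn_el$bytes) %/% flen
    fields <- vapply(seq_len(nfields), function(i) {
      b <- fn_el$bytes[((i - 1) * flen + 1):(i * flen)]
      rawToChar(b[b != as.raw(0)])
    }, character(1))
    vals <- vector("list", nfields)
    for (i in seq_len(nfields)) {
      sub_el <- mat5_element(bytes, pos, endian)
      pos <- sub_el$next_pos
      vals[[i]] <- tryCatch(mat5_parse_matrix(sub_el$bytes, endian)$value,
                            error = function(e) NULL)
    }
    names(vals) <- fields
    # Eigenvector dataset objects keep the spectra in a "data" field,
    # sometimes nested one level down inside a cell-like wrapper.
    value <- vals[["data"]]
    if (is.null(value)) {
      numeric_fields <- Filter(function(v) is.matrix(v) && is.numeric(v), vals)
      if (length(numeric_fields)) {
        value <- numeric_fields[[which.max(vapply(numeric_fields, length,
                                                  numeric(1)))]]
      } else {
        value <- vals
      }
    }
  }
  list(name = name, value = value)
}

#' Read numeric arrays from a MATLAB v5 file
#'
#' Supports real numeric arrays, zlib-compressed elements, and struct/object
#' arrays whose numeric `data` field is returned in their place. Intended for
#' the corn benchmark container; not a general `.mat` reader.
#'
#' @param path file path.
#' @return named list of numeric matrices.
#' @export
read_mat5 <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 128) stop("not a MAT v5 file: too short")
  endian_ind <- rawToChar(buf[127:128])
  endian <- if (endian_ind == "IM") "little" else if (endian_ind == "MI")
    "big" else stop("not a MAT v5 file: bad endian indicator")
  pos <- 129L
  out <- list()
  while (pos + 7 <= length(buf)) {
    el <- mat5_element(buf, pos, endian)
    pos <- el$next_pos
    body <- el$bytes
    type <- el$type
    if (type == 15) {                       # miCOMPRESSED: zlib stream
      body <- memDecompress(body, type = "gzip")
      inner <- mat5_element(body, 1L, endian)
      type <- inner$type
      body <- inner$bytes
    }
    if (type == 14) {                       # miMATRIX
      m <- tryCatch(mat5_parse_matrix(body, endian), error = function(e) NULL)
      if (!is.null(m) && nzchar(m$name) && !is.null(m$value))
        out[[m$name]] <- m$value
    }
  }
  out
}
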