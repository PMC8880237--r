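#' Spectral dataset container
#'
#' A `spectra_set` bundles an absorbance matrix (samples x wavelengths), its
#' wavelength axis in nanometres, the reference property vector `y` (one value
#' per sample, e.g. % oil or g/cm^3 density) and sample identifiers. It is the
#' unit of data every other function in the package consumes.
#'
#' @param spectra numeric matrix, `n_samples x n_wavelengths`.
#' @param wavelengths strictly increasing numeric vector (nm), length equal to
#'   `ncol(spectra)`.
#' @param y numeric vector of reference values, length `nrow(spectra)`.
#' @param ids character vector of sample labels; defaults to `"s1".."sn"`.
#' @return An object of class `spectra_set`: a list with elements `spectra`,
#'   `wavelengths`, `y`, `ids`.
#' @examples
#' s <- spectra_set(matrix(rnorm(12), 3, 4), c(1100, 1102, 1104, 1106), c(1, 2, 3))
#' dim(s$spectra)
#' @export
spectra_set <- function(spectra, wavelengths, y, ids = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  y <- as.numeric(y)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(spectra)))
  ids <- as.character(ids)
  if (length(wavelengths) != ncol(spectra))
    stop("wavelength axis length (", length(wavelengths),
         ") does not match spectra column count (", ncol(spectra), ")")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(y) != nrow(spectra))
    stop("y length (", length(y), ") does not match sample count (",
         nrow(spectra), ")")
  if (length(ids) != nrow(spectra))
    stop("ids length does not match sample count")
  if (anyDuplicated(ids))
    stop("sample ids must be unique")
  if (!all(is.finite(spectra)))
    stop("spectra contain non-finite entries")
  if (!all(is.finite(wavelengths)) || !all(is.finite(y)))
    stop("wavelengths and y must be finite")
  structure(list(spectra = spectra, wavelengths = wavelengths, y = y,
                 ids = ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$spectra), " samples x ", ncol(x$spectra),
      " wavelengths [", x$wavelengths[1], "-",
      x$wavelengths[length(x$wavelengths)], " nm], y range [",
      signif(min(x$y), 4), ", ", signif(max(x$y), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

#' Subset a spectra_set by sample and/or wavelength index
#'
#' @param set a `spectra_set`.
#' @param samples integer/logical index of samples to keep (default all).
#' @param wavelengths integer/logical index of wavelength columns to keep.
#' @return the subsetted `spectra_set`.
#' @export
subset_samples <- function(set, samples = NULL, wavelengths = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(samples)) samples <- seq_len(nrow(set$spectra))
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(set$spectra))
  spectra_set(set$spectra[samples, wavelengths, drop = FALSE],
              set$wavelengths[wavelengths],
              set$y[samples], set$ids[samples])
}

#' Paired master/slave datasets
#'
#' Binds two `spectra_set`s measured on the same physical samples — a master
#' instrument (whose calibration model is kept) and a slave instrument (whose
#' spectra must be mapped into the master's space). Both members must share
#' the wavelength axis and carry the same samples in the same order.
#'
#' @param master,slave `spectra_set` objects.
#' @param axis_tol absolute tolerance (nm) for wavelength-axis equality;
#'   axes are metadata, not measurements, so the default is tight.
#' @return object of class `paired_sets`, a list with `master` and `slave`.
#' @export
paired_sets <- function(master, slave, axis_tol = 1e-9) {
  stopifnot(inherits(master, "spectra_set"), inherits(slave, "spectra_set"))
  if (ncol(master$spectra) != ncol(slave$spectra) ||
      max(abs(master$wavelengths - slave$wavelengths)) > axis_tol)
    stop("master and slave wavelength axes differ beyond tolerance")
  if (!identical(master$ids, slave$ids))
    stop("master and slave sample ids differ; use align_pair() first")
  structure(list(master = master, slave = slave), class = "paired_sets")
}

#' @export
print.paired_sets <- function(x, ...) {
  cat("<paired_sets>\n  master: ")
  print(x$master)
  cat("  slave:  ")
  print(x$slave)
  invisible(x)
}

#' Align a slave dataset to a master's sample order
#'
#' Reorders slave rows so ids match the master ordering, then constructs the
#' validated pair. Idempotent: aligning an already aligned pair is a no-op.
#'
#' @inheritParams paired_sets
#' @return a `paired_sets` object.
#' @export
align_pair <- function(master, slave, axis_tol = 1e-9) {
  stopifnot(inherits(master, "spectra_set"), inherits(slave, "spectra_set"))
  if (!setequal(master$ids, slave$ids) ||
      length(master$ids) != length(slave$ids))
    stop("pairing error: master and slave sample id sets differ")
  ord <- match(master$ids, slave$ids)
  slave2 <- subset_samples(slave, ord)
  paired_sets(master, slave2, axis_tol = axis_tol)
}

#' Subset both members of a pair with the same indices
#'
#' @param pair a `paired_sets`.
#' @param samples,wavelengths indices applied identically to both members.
#' @return a `paired_sets`.
#' @export
subset_pair <- function(pair, samples = NULL, wavelengths = NULL) {
  stopifnot(inherits(pair, "paired_sets"))
  paired_sets(subset_samples(pair$master, samples, wavelengths),
              subset_samples(pair$slave, samples, wavelengths))
}

#' Read a delimited spectral file
#'
#' The expected layout is UTF-8 comma-separated text with one reserved column
#' for the sample id, one for the reference property, and the remaining column
#' names parsing as a strictly increasing numeric wavelength axis in nm.
#'
#' @param path file path.
#' @param y_column name of the reference-property column (default `"y"`).
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @param sep field separator.
#' @return a `spectra_set`.
#' @export
read_delimited <- function(path, y_column = "y", id_column = "sample_id",
                           sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (!(y_column %in% nm)) stop("format error: missing y column '", y_column, "'")
  if (!(id_column %in% nm)) stop("format error: missing id column '", id_column, "'")
  wl_cols <- setdiff(nm, c(y_column, id_column))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl)))
    stop("format error: non-numeric wavelength header entries: ",
         paste(utils::head(wl_cols[is.na(wl)], 3), collapse = ", "))
  if (any(diff(wl) <= 0))
    stop("format error: wavelength header is not strictly increasing")
  spectra <- as.matrix(df[, wl_cols, drop = FALSE])
  if (!is.numeric(spectra)) stop("format error: non-numeric spectral values")
  dimnames(spectra) <- NULL
  spectra_set(spectra, wl, df[[y_column]], df[[id_column]])
}

#' Write a spectra_set as delimited text
#'
#' Values are formatted with 17 significant digits so that
#' `read_delimited(write_delimited(x))` round-trips doubles exactly.
#'
#' @param set a `spectra_set`.
#' @param path output file path.
#' @inheritParams read_delimited
#' @return `path`, invisibly.
#' @export
write_delimited <- function(set, path, y_column = "y",
                            id_column = "sample_id", sep = ",") {
  stopifnot(inherits(set, "spectra_set"))
  header <- c(id_column, y_column, format(set$wavelengths, digits = 17,
                                          trim = TRUE, scientific = FALSE))
  rows <- vapply(seq_len(nrow(set$spectra)), function(i) {
    paste(c(set$ids[i],
            format(c(set$y[i], set$spectra[i, ]), digits = 17, trim = TRUE)),
          collapse = sep)
  }, character(1))
  writeLines(c(paste(header, collapse = sep), rows), path)
  invisible(path)
}

#' Read one instrument/property slice of the corn benchmark container
#'
#' The public corn benchmark ships as a MATLAB v5 container holding spectra
#' of 80 samples measured on several instruments over 1100-2498 nm (700
#' points, 2 nm step) plus an 80 x 4 table of moisture, oil, protein and
#' starch contents. Array names inside the container are not standardized
#' across mirrors, so the mapping from instrument/property names to container
#' keys is configurable; the defaults match the Eigenvector distribution
#' (`m5spec`/`mp5spec`/`mp6spec` dataset objects and `propvals`).
#'
#' @param path path to the `.mat` container.
#' @param instrument `"mp5"` or `"mp6"` (also `"m5"` if present).
#' @param property one of `"moisture"`, `"oil"`, `"protein"`, `"starch"`.
#' @param key_map named list mapping instrument names to container array
#'   names, plus entries `properties` (array name of the property table) and
#'   `property_order` (column order of that table).
#' @return a `spectra_set` (80 x 700 for the canonical container).
#' @export
read_corn_container <- function(path, instrument = c("mp5", "mp6", "m5"),
                                property = c("oil", "moisture", "protein",
                                             "starch"),
                                key_map = corn_key_map()) {
  instrument <- match.arg(instrument)
  property <- match.arg(property)
  arrays <- read_mat5(path)
  ikey <- key_map[[instrument]]
  if (is.null(ikey) || !(ikey %in% names(arrays)))
    stop("lookup error: no container array for instrument '", instrument, "'")
  pkey <- key_map$properties
  if (is.null(pkey) || !(pkey %in% names(arrays)))
    stop("lookup error: no container array for the property table")
  X <- arrays[[ikey]]
  P <- arrays[[pkey]]
  pcol <- match(property, key_map$property_order)
  if (is.na(pcol) || pcol > ncol(P))
    stop("lookup error: property '", property, "' not in container table")
  n_wl <- ncol(X)
  wl <- seq(1100, by = 2, length.out = n_wl)
  spectra_set(X, wl, P[, pcol], paste0("corn", seq_len(nrow(X))))
}

#' Default key map for the corn container
#' @return named list used by [read_corn_container()].
#' @export
corn_key_map <- function() {
  list(m5 = "m5spec", mp5 = "mp5spec", mp6 = "mp6spec",
       properties = "propvals",
       property_order = c("moisture", "oil", "protein", "starch"))
}
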