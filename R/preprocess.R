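#' Standard normal variate transformation
#'
#' Centers and scales every spectrum (row) to mean 0 and unit sample standard
#' deviation (denominator n-1). SNV removes multiplicative scatter and
#' additive offset effects caused by particle size and path-length variation.
#'
#' @param spectra numeric matrix (samples x wavelengths) or `spectra_set`.
#' @return object of the same kind with transformed spectra.
#' @export
snv <- function(spectra) {
  if (inherits(spectra, "spectra_set")) {
    out <- spectra
    out$spectra <- snv(spectra$spectra)
    return(out)
  }
  X <- as.matrix(spectra)
  if (ncol(X) < 2) stop("snv needs at least 2 points per row")
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  bad <- which(sdv == 0)
  if (length(bad))
    stop("degenerate (constant) row(s) in snv: ",
         paste(utils::head(bad, 5), collapse = ", "))
  (X - mu) / sdv
}

# Savitzky-Golay convolution weights for one output position.
# offsets: integer window offsets relative to the evaluation point;
# returns weights w so that sum(w * y[window]) estimates the deriv-th
# derivative (in index units) of the local polyorder-degree LS polynomial.
sg_weights <- function(offsets, polyorder, deriv) {
  A <- outer(offsets, 0:polyorder, `^`)
  # row `deriv` of the pseudo-inverse, times deriv!
  G <- solve(crossprod(A), t(A))
  G[deriv + 1, ] * factorial(deriv)
}

#' Savitzky-Golay filtering / derivative
#'
#' Row-wise local least-squares polynomial smoothing with optional first
#' derivative. Edges are handled by evaluating the polynomial fitted on
#' one-sided windows, so the output keeps every wavelength column and
#' wavelength indices remain aligned between master and slave spectra.
#' With `deriv = 1` the result is divided by the wavelength step so the
#' units are d(absorbance)/d(nm); the axis must then be (near) uniform.
#'
#' @param spectra numeric matrix or `spectra_set`.
#' @param window odd window width in points (default 21).
#' @param polyorder polynomial degree, must be `< window` (default 2).
#' @param deriv 0 (smoothing) or 1 (first derivative).
#' @param wavelengths wavelength axis in nm; needed for `deriv = 1` when
#'   `spectra` is a bare matrix (step defaults to 1 otherwise).
#' @return filtered matrix or `spectra_set`.
#' @export
savgol <- function(spectra, window = 21L, polyorder = 2L, deriv = 0L,
                   wavelengths = NULL) {
  if (inherits(spectra, "spectra_set")) {
    out <- spectra
    out$spectra <- savgol(spectra$spectra, window, polyorder, deriv,
                          wavelengths = spectra$wavelengths)
    return(out)
  }
  X <- as.matrix(spectra)
  p <- ncol(X)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("parameter error: window must be odd")
  if (window <= polyorder)
    stop("parameter error: window must exceed polyorder")
  if (window > p) stop("parameter error: window exceeds spectrum length")
  if (!deriv %in% c(0L, 1L)) stop("parameter error: deriv must be 0 or 1")
  h <- (window - 1L) %/% 2L
  # Filter matrix W (p x p): row i holds the weights producing output i.
  W <- matrix(0, p, p)
  interior <- sg_weights(-h:h, polyorder, deriv)
  for (i in seq_len(p)) {
    if (i <= h) {                       # left edge: one-sided window 1..window
      off <- (1:window) - i
      W[i, 1:window] <- sg_weights(off, polyorder, deriv)
    } else if (i > p - h) {             # right edge
      off <- ((p - window + 1):p) - i
      W[i, (p - window + 1):p] <- sg_weights(off, polyorder, deriv)
    } else {
      W[i, (i - h):(i + h)] <- interior
    }
  }
  out <- X %*% t(W)
  if (deriv == 1L) {
    step <- if (is.null(wavelengths)) 1 else mean(diff(wavelengths))
    out <- out / step
  }
  out
}

#' Compose a preprocessing pipeline from named steps
#'
#' Builds a function applying the listed pretreatments in order. Step grammar:
#' `"snv"`, `"savgol"` or `"savgol:<window>:<polyorder>"`, `"deriv"` or
#' `"deriv:<order>"` (Savitzky-Golay first derivative, `order` must be 1).
#' The empty list yields the identity. Typical defaults are `c("snv")` for
#' between-instrument transfer of the corn benchmark and
#' `c("savgol:21:2", "deriv:1", "snv")` for scatter-prone solid samples.
#'
#' @param steps character vector of step specifications.
#' @return function mapping a `spectra_set` (or matrix) to its pretreated
#'   version.
#' @export
preprocess_pipeline <- function(steps = character()) {
  fns <- lapply(steps, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    if (name == "snv") {
      function(x) snv(x)
    } else if (name == "savgol") {
      w <- if (length(parts) >= 2) as.integer(parts[2]) else 21L
      po <- if (length(parts) >= 3) as.integer(parts[3]) else 2L
      function(x) savgol(x, window = w, polyorder = po, deriv = 0L)
    } else if (name == "deriv") {
      d <- if (length(parts) >= 2) as.integer(parts[2]) else 1L
      if (d != 1L) stop("configuration error: only first derivative supported")
      w <- if (length(parts) >= 3) as.integer(parts[3]) else 21L
      function(x) savgol(x, window = w, polyorder = 2L, deriv = 1L)
    } else {
      stop("configuration error: unknown preprocessing step '", name, "'")
    }
  })
  function(x) {
    for (f in fns) x <- f(x)
    x
  }
}

#' Apply a pipeline to both members of a pair
#'
#' Pretreatments here are strictly per-spectrum (no training-set statistics),
#' so applying them before or after sample-set partitioning is equivalent.
#'
#' @param pair a `paired_sets`.
#' @param steps step vector as in [preprocess_pipeline()].
#' @return pretreated `paired_sets`.
#' @export
preprocess_pair <- function(pair, steps = character()) {
  stopifnot(inherits(pair, "paired_sets"))
  f <- preprocess_pipeline(steps)
  paired_sets(f(pair$master), f(pair$slave))
}
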