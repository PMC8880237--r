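# Synthetic paired master/slave NIR emulator.
#
# Master spectra are Gaussian-peak mixtures tied to a latent property;
# the slave instrument re-measures the same samples with a wavelength shift,
# multiplicative gain, its own baseline polynomial and noise, plus
# band-localized instability: inside designated bands each instrument gets
# its own fixed random spectral profile, modulated by per-sample random
# amplitudes drawn independently per instrument. (A purely constant band
# offset would be removed by mean-centering and could never destabilize
# regression coefficients, so the amplitude modulation is what plants
# between-instrument instability for SAFS to reject.)

#' Specification of a synthetic paired dataset
#'
#' @param n_samples number of samples (default 120).
#' @param n_wavelengths number of wavelength points (default 200; axis is
#'   1100 nm upward in 2 nm steps).
#' @param peaks data.frame with columns `component`, `center` (nm), `width`
#'   (nm), `amplitude`; defaults to three single-peak components.
#' @param n_components number of latent chemical components.
#' @param y_weights contribution of each component concentration to y.
#' @param y_noise_sd measurement noise on y.
#' @param slave_shift wavelength shift of the slave instrument in nm
#'   (applied by linear interpolation onto the shared axis).
#' @param slave_gain multiplicative gain of the slave.
#' @param baseline_master,baseline_slave polynomial coefficients (constant
#'   first) of each instrument's baseline over the axis rescaled to [0, 1].
#' @param unstable_bands data.frame with columns `start`, `end` (column
#'   indices, inclusive) and `sd` (perturbation scale).
#' @param noise_sd spectral white-noise standard deviation (absorbance).
#' @param seed RNG seed.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 120L, n_wavelengths = 200L,
                       peaks = NULL, n_components = 3L,
                       y_weights = c(1, 0.6, 0.8), y_noise_sd = 0.01,
                       slave_shift = 2, slave_gain = 1.05,
                       baseline_master = c(0.10, 0.05),
                       baseline_slave = c(0.15, -0.03),
                       unstable_bands = NULL,
                       noise_sd = 0.05, seed = 7L) {
  wl <- seq(1100, by = 2, length.out = n_wavelengths)
  if (is.null(peaks)) {
    # Components are plateau-like bands built from three overlapping
    # Gaussians each, so the stability index is roughly uniform inside a
    # band and thresholds act on whole bands, as absorption bands do in
    # real NIR. Component 2's core deliberately sits inside the first
    # default unstable band: a band that carries genuine signal but is
    # corrupted on the slave is what damages full-spectrum transfer and
    # what SAFS is supposed to reject (its tails stay clean, so the
    # chemical information survives selection).
    frac <- list(c(0.20, 0.25, 0.30), c(0.50, 0.55, 0.60), 0.75)
    amp <- c(1, 0.9, 0.8)
    peaks <- do.call(rbind, lapply(1:3, function(k) {
      at <- pmax(2L, round(n_wavelengths * frac[[k]]))
      data.frame(component = k, center = wl[at],
                 width = diff(range(wl)) * 0.045, amplitude = amp[k])
    }))
  }
  if (is.null(unstable_bands)) {
    unstable_bands <- data.frame(
      start = pmax(1L, round(n_wavelengths * c(0.50, 0.85))),
      end = round(n_wavelengths * c(0.60, 0.93)),
      sd = c(0.30, 0.30))
  }
  stopifnot(length(y_weights) == n_components,
            all(peaks$component <= n_components),
            all(peaks$center >= wl[1] & peaks$center <= wl[n_wavelengths]),
            all(unstable_bands$start >= 1 &
                  unstable_bands$end <= n_wavelengths),
            noise_sd >= 0)
  if (abs(slave_shift) >= wl[n_wavelengths] - wl[1])
    stop("spec error: slave_shift larger than the axis span")
  structure(list(n_samples = as.integer(n_samples),
                 n_wavelengths = as.integer(n_wavelengths),
                 wavelengths = wl, peaks = peaks,
                 n_components = as.integer(n_components),
                 y_weights = y_weights, y_noise_sd = y_noise_sd,
                 slave_shift = slave_shift, slave_gain = slave_gain,
                 baseline_master = baseline_master,
                 baseline_slave = baseline_slave,
                 unstable_bands = unstable_bands, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

poly_baseline <- function(coefs, n) {
  if (!length(coefs)) return(numeric(n))
  x <- seq(0, 1, length.out = n)
  drop(outer(x, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Generate a synthetic paired master/slave dataset with ground truth
#'
#' With `slave_shift = 0`, `slave_gain = 1`, no slave baseline, no noise and
#' no unstable bands the slave equals the master bit-for-bit, which gives a
#' closed-form degenerate case for the stability index. Ground truth returned
#' alongside marks the informative wavelengths (where y-linked peaks have
#' support) and the planted unstable-band wavelengths.
#'
#' @param spec a [synth_spec()].
#' @return list with `pair` (a `paired_sets`), `truth` (list with
#'   `informative` and `unstable` column indices), `concentrations`, and
#'   `spec`.
#' @export
generate_pair <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples; p <- spec$n_wavelengths
  wl <- spec$wavelengths
  # component signature spectra
  sig <- matrix(0, spec$n_components, p)
  for (r in seq_len(nrow(spec$peaks))) {
    pk <- spec$peaks[r, ]
    sig[pk$component, ] <- sig[pk$component, ] +
      pk$amplitude * exp(-0.5 * ((wl - pk$center) / pk$width)^2)
  }
  with_seed(spec$seed, {
    conc <- matrix(stats::runif(n * spec$n_components), n)
    master <- conc %*% sig
    master <- master + matrix(poly_baseline(spec$baseline_master, p), n, p,
                              byrow = TRUE)
    if (spec$noise_sd > 0)
      master <- master + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n)
    y <- drop(conc %*% spec$y_weights)
    if (spec$y_noise_sd > 0) y <- y + stats::rnorm(n, sd = spec$y_noise_sd)

    # slave starts from the master measurement of the same samples
    slave <- master
    if (spec$slave_shift != 0) {
      slave <- t(apply(slave, 1, function(row)
        stats::approx(wl, row, xout = wl + spec$slave_shift, rule = 2)$y))
    }
    slave <- slave * spec$slave_gain
    if (length(spec$baseline_slave))
      slave <- slave + matrix(poly_baseline(spec$baseline_slave, p), n, p,
                              byrow = TRUE)
    # Band-localized instability: the band stays clean on the master (so a
    # full-spectrum master model loads on any signal there) but the slave
    # re-measures it through a per-sample multiplicative distortion plus a
    # little structured additive noise. No fixed linear slave-to-master map
    # can invert a sample-dependent gain, so transfer of this band fails in
    # a way calibration standards cannot teach away -- emulating band-local
    # path-length/scatter and peak-shape changes between instruments.
    unstable_idx <- integer(0)
    if (nrow(spec$unstable_bands)) {
      for (b in seq_len(nrow(spec$unstable_bands))) {
        band <- spec$unstable_bands$start[b]:spec$unstable_bands$end[b]
        sdv <- spec$unstable_bands$sd[b]
        if (sdv > 0) {
          gain_s <- 1 + stats::rnorm(n, sd = sdv)     # per-sample band gain
          prof_s <- stats::rnorm(length(band), sd = sdv / 3)
          amp_s <- stats::rnorm(n)
          slave[, band] <- slave[, band] * gain_s + amp_s %o% prof_s
        }
        unstable_idx <- union(unstable_idx, band)
      }
    }
    if (spec$noise_sd > 0)  # slave re-measurement noise, independent draw
      slave <- slave + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n)
    ids <- sprintf("syn%03d", seq_len(n))
    m_set <- spectra_set(master, wl, y, ids)
    s_set <- spectra_set(slave, wl, y, ids)
    # "informative" ground truth = core peak support: wavelengths carrying
    # at least 30% of the maximum y-weighted signal. Peak tails are excluded:
    # they are redundant with the core and a prediction-driven selector has
    # no reason to keep them all.
    strength <- colSums(abs(spec$y_weights * sig))
    informative <- which(strength > 0.3 * max(strength))
    list(pair = paired_sets(m_set, s_set),
         truth = list(informative = sort(setdiff(informative, unstable_idx)),
                      unstable = sort(unstable_idx)),
         concentrations = conc, spec = spec)
  })
}

#' Plant y-outliers into a dataset
#'
#' Shifts the reference value of `k` randomly chosen samples by
#' `y_shift_sd` standard deviations of y, for exercising outlier screening.
#'
#' @param set a `spectra_set`.
#' @param k number of outliers to plant.
#' @param y_shift_sd shift size in units of `sd(y)` (default 10).
#' @param seed RNG seed.
#' @return list with `set` (modified) and `planted` (indices).
#' @export
generate_outliers <- function(set, k, y_shift_sd = 10, seed = 1L) {
  stopifnot(inherits(set, "spectra_set"), k < nrow(set$spectra))
  if (k == 0) return(list(set = set, planted = integer(0)))
  with_seed(seed, {
    planted <- sort(sample.int(nrow(set$spectra), k))
    y <- set$y
    y[planted] <- y[planted] +
      y_shift_sd * stats::sd(y) * sign(stats::runif(k) - 0.5)
    list(set = spectra_set(set$spectra, set$wavelengths, y, set$ids),
         planted = planted)
  })
}
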