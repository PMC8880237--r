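# Shared fixtures, all generated in code.

toy_set <- function(n = 6, p = 8, seed = 42) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p), n, p),
              seq(1100, by = 2, length.out = p),
              rnorm(n), sprintf("id%02d", seq_len(n)))
}

# small linear-world set where y is an exact function of the spectra
linear_set <- function(n = 30, p = 10, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(2, -1, rep(0, p - 2))
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  spectra_set(X, seq(1500, by = 2, length.out = p), y)
}

# small paired world used by the quicker SAFS/transfer tests
small_demo_pair <- function(seed = 7, n = 80, p = 120) {
  generate_pair(synth_spec(n_samples = n, n_wavelengths = p, seed = seed))
}

# naive reference for the stability index: explicit double loop, one
# wavelength and one draw at a time, written directly from the formula
naive_stability <- function(A, B) {
  p <- nrow(A); K <- ncol(A)
  out <- numeric(p)
  for (i in seq_len(p)) {
    am <- sum(A[i, ]) / K
    bm <- sum(B[i, ]) / K
    sa <- sqrt(sum((A[i, ] - am)^2) / (K - 1))
    sb <- sqrt(sum((B[i, ] - bm)^2) / (K - 1))
    num <- abs(am * bm)
    out[i] <- if (sa * sb > 0) num / (sa * sb) else if (num > 0) Inf else 0
  }
  out
}
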