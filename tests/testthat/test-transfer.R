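test_that("SBC recovers affine distortions exactly", {
  s <- linear_set(n = 20, p = 5, noise = 0, seed = 2)
  model <- fit_pls(s$spectra, s$y, 2)
  # exact predictions -> identity correction
  m1 <- fit_sbc(model, s)
  expect_equal(m1$slope, 1, tolerance = 1e-8)
  expect_equal(m1$bias, 0, tolerance = 1e-8)
  expect_equal(apply_transfer(m1, c(1, 2, 3)), c(1, 2, 3), tolerance = 1e-8)
  # yhat = (y - 5) / 2  ->  slope 2, bias 5
  yhat <- (s$y - 5) / 2
  fit <- stats::lm.fit(cbind(1, yhat), s$y)
  expect_equal(unname(fit$coefficients), c(5, 2), tolerance = 1e-10)
  m2 <- structure(list(method = "sbc", bias = 5, slope = 2),
                  class = "transfer_model")
  expect_equal(apply_transfer(m2, yhat), s$y, tolerance = 1e-10)
  # idempotence in the noiseless affine case: correcting corrected
  # predictions refits to slope 1 / bias 0
  corrected <- apply_transfer(m2, yhat)
  refit <- stats::lm.fit(cbind(1, corrected), s$y)
  expect_equal(unname(refit$coefficients), c(0, 1), tolerance = 1e-10)
  # constant standards give zero prediction variance
  const <- spectra_set(matrix(rep(c(1, 2, 3, 4, 5), each = 3), 3),
                       s$wavelengths, c(1, 2, 3))
  expect_error(fit_sbc(model, const), "zero variance")
})

test_that("SBC correction beats raw predictions under offset drift", {
  g <- generate_pair(synth_spec(n_samples = 60, n_wavelengths = 60,
                                seed = 13))
  pair <- g$pair
  sp <- spxy_split(pair$master, 35, 12, 13)
  r <- nirct:::transfer_eval_core(pair, sp$cal, sp$pred, NULL, "sbc",
                                  max_latent = 8, val_idx = sp$val)
  m <- fit_pls(pair$master$spectra[sp$cal, ], pair$master$y[sp$cal],
               r$n_latent)
  raw <- sqrt(mean((predict(m, pair$slave$spectra[sp$pred, ]) -
                      pair$slave$y[sp$pred])^2))
  expect_lt(r$rmse, raw)
})

test_that("PDS is an identity on identical instruments and validates input", {
  g <- small_demo_pair(seed = 3, n = 40, p = 60)
  m_std <- subset_samples(g$pair$master, 1:20)
  pds <- fit_pds(m_std, m_std, window = 9, n_latent_local = 9)
  expect_lt(max(abs(apply_transfer(pds, m_std$spectra) - m_std$spectra)),
            1e-8)
  expect_error(fit_pds(m_std, m_std, window = 8), "odd")
  expect_error(fit_pds(m_std, m_std, window = 121), "exceeds")
  expect_error(apply_transfer(pds, m_std$spectra[, 1:10]), "mismatch")
})

test_that("full-window PDS equals the direct-standardization oracle", {
  set.seed(2)
  Xm <- matrix(rnorm(30 * 40), 30)
  Xs <- Xm + matrix(rnorm(30 * 40, sd = 0.1), 30)
  wl <- seq(1100, by = 2, length.out = 40)
  sm <- spectra_set(Xm, wl, rnorm(30))
  ss <- spectra_set(Xs, wl, sm$y)
  pds <- fit_pds(sm, ss, window = 79, n_latent_local = 29)
  # DS oracle: column-wise minimum-norm least squares on centered data
  Xsc <- scale(Xs, scale = FALSE)
  Fds <- MASS::ginv(Xsc) %*% scale(Xm, scale = FALSE)
  pred_ds <- sweep(Xsc %*% Fds, 2, colMeans(Xm), `+`)
  expect_lt(max(abs(pred_ds - apply_transfer(pds, Xs))), 1e-6)
})

test_that("PDS repairs a one-index wavelength shift", {
  g <- generate_pair(synth_spec(n_samples = 50, n_wavelengths = 80,
                                seed = 12, slave_shift = 0, slave_gain = 1,
                                baseline_slave = numeric(),
                                unstable_bands = data.frame(start = 1L,
                                                            end = 1L,
                                                            sd = 0),
                                noise_sd = 0.01))
  M <- g$pair$master$spectra
  S <- cbind(M[, -1], M[, 80])
  wl <- g$pair$master$wavelengths
  sm <- spectra_set(M[1:30, ], wl, g$pair$master$y[1:30])
  ss <- spectra_set(S[1:30, ], wl, sm$y)
  pds <- fit_pds(sm, ss, window = 9)
  err_t <- mean(abs(apply_transfer(pds, S[31:50, ]) - M[31:50, ]))
  err_0 <- mean(abs(S[31:50, ] - M[31:50, ]))
  expect_lt(err_t, err_0 / 5)
})

test_that("SST is exact on identical and low-rank paired data", {
  g <- small_demo_pair(seed = 5, n = 30, p = 24)
  m_std <- subset_samples(g$pair$master, 1:18)
  sst <- fit_sst(m_std, m_std, n_factors = 4)
  expect_lt(max(abs(apply_transfer(sst, m_std$spectra) - m_std$spectra)),
            1e-8)
  # rank-2 world: held-out slave spectra map exactly to their master twins
  set.seed(9)
  TT <- matrix(rnorm(80), 40, 2)
  P1 <- matrix(rnorm(24), 12); P2 <- matrix(rnorm(24), 12)
  Xm <- TT %*% t(P1); Xs <- TT %*% t(P2)
  wl <- seq(1100, by = 2, length.out = 12)
  sm <- spectra_set(Xm[1:25, ], wl, rnorm(25))
  ss <- spectra_set(Xs[1:25, ], wl, sm$y)
  mdl <- fit_sst(sm, ss, n_factors = 2)
  expect_lt(max(abs(apply_transfer(mdl, Xs[26:40, ]) - Xm[26:40, ])), 1e-8)
  expect_error(fit_sst(sm, ss, n_factors = 40), "rank")
})

test_that("SST auto mode picks the factor count minimizing validation RMSE", {
  g <- small_demo_pair(seed = 6, n = 60, p = 40)
  sp <- spxy_split(g$pair$master, 35, 12, 13)
  cal_m <- subset_samples(g$pair$master, sp$cal)
  cal_s <- subset_samples(g$pair$slave, sp$cal)
  master <- fit_pls(cal_m$spectra, cal_m$y, 4)
  vp <- subset_pair(g$pair, sp$val)
  mdl <- fit_sst(cal_m, cal_s, n_factors = "auto", master_model = master,
                 val_pair = vp)
  expect_identical(mdl$n_factors, which.min(mdl$rmsev_scan))
})

test_that("OSC scores are exactly y-orthogonal and n_osc = 0 is identity", {
  set.seed(7)
  X <- matrix(rnorm(50 * 30), 50)
  y <- drop(X %*% rnorm(30)) + rnorm(50)
  osc <- fit_osc(X, y, 2)
  S <- osc_scores(osc, X)
  expect_lt(max(abs(stats::cor(S, y))), 1e-8)
  osc0 <- fit_osc(X, y, 0)
  expect_equal(apply_transfer(osc0, X), X)
})

test_that("OSC removal rescues a 1-LV model from structured nuisance", {
  set.seed(11)
  n <- 60; p <- 40
  sigd <- exp(-0.5 * ((1:p - 12) / 4)^2)
  noised <- exp(-0.5 * ((1:p - 18) / 5)^2)
  conc <- runif(n); y <- conc + rnorm(n, sd = 0.01)
  Xm <- conc %o% sigd + rnorm(n) %o% noised * 0.6 +
    matrix(rnorm(n * p, sd = 0.01), n)
  Xs <- conc %o% sigd + rnorm(n) %o% noised * 1.2 +
    matrix(rnorm(n * p, sd = 0.01), n)
  cal <- 1:40; prd <- 41:60
  osc <- fit_osc(Xm[cal, ], y[cal], 1)
  m0 <- fit_pls(Xm[cal, ], y[cal], 1)
  m1 <- fit_pls(apply_transfer(osc, Xm[cal, ]), y[cal], 1)
  r0 <- sqrt(mean((predict(m0, Xs[prd, ]) - y[prd])^2))
  r1 <- sqrt(mean((predict(m1, apply_transfer(osc, Xs[prd, ])) - y[prd])^2))
  expect_lt(r1, r0)
})

test_that("prediction-set rows never influence fitted transfer parameters", {
  g <- small_demo_pair(seed = 15, n = 40, p = 30)
  sp <- spxy_split(g$pair$master, 24, 8, 8)
  fit_all <- function(pair) {
    r <- lapply(c("sbc", "pds", "sst", "osc"), function(m)
      nirct:::transfer_eval_core(pair, sp$cal, sp$pred, NULL, m,
                                 max_latent = 4, val_idx = sp$val))
    lapply(r, function(x) x$transfer_model[setdiff(names(x$transfer_model),
                                                   "rmsev_scan")])
  }
  a <- fit_all(g$pair)
  # corrupt only prediction-set slave spectra
  pert <- g$pair
  pert$slave$spectra[sp$pred, ] <- pert$slave$spectra[sp$pred, ] + 5
  b <- fit_all(pert)
  expect_identical(a, b)
})
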