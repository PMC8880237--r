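test_that("generation is bit-reproducible from the seed", {
  a <- generate_pair(synth_spec(n_samples = 20, n_wavelengths = 40,
                                seed = 5))
  b <- generate_pair(synth_spec(n_samples = 20, n_wavelengths = 40,
                                seed = 5))
  expect_identical(a$pair$master$spectra, b$pair$master$spectra)
  expect_identical(a$pair$slave$spectra, b$pair$slave$spectra)
  expect_identical(a$truth, b$truth)
})

test_that("the null transformation leaves slave identical to master", {
  sp <- synth_spec(n_samples = 15, n_wavelengths = 30, slave_shift = 0,
                   slave_gain = 1, baseline_slave = numeric(),
                   unstable_bands = data.frame(start = 1L, end = 1L, sd = 0),
                   noise_sd = 0, y_noise_sd = 0, seed = 3)
  g <- generate_pair(sp)
  expect_identical(g$pair$master$spectra, g$pair$slave$spectra)
})

test_that("noiseless one-component spectra have the predicted rank bound", {
  sp <- synth_spec(n_samples = 25, n_wavelengths = 40, n_components = 1,
                   peaks = data.frame(component = 1, center = 1140,
                                      width = 12, amplitude = 1),
                   y_weights = 1, slave_shift = 0, slave_gain = 1,
                   baseline_master = c(0.1, 0.05),  # degree-1 baseline
                   baseline_slave = numeric(),
                   unstable_bands = data.frame(start = 1L, end = 1L, sd = 0),
                   noise_sd = 0, y_noise_sd = 0, seed = 4)
  g <- generate_pair(sp)
  # 1 component + constant baseline term (+ slope term) -> rank <= 2 here
  sv <- svd(g$pair$master$spectra)$d
  expect_lte(sum(sv > sv[1] * 1e-10), 1 + length(sp$baseline_master))
})

test_that("spec validation rejects impossible worlds", {
  expect_error(synth_spec(n_wavelengths = 30, slave_shift = 1e5),
               "spec error")
  expect_error(synth_spec(n_wavelengths = 30,
                          unstable_bands = data.frame(start = 1L, end = 99L,
                                                      sd = 0.1)))
  expect_error(synth_spec(y_weights = c(1, 2)))
})

test_that("identical instruments give the single-set closed form", {
  sp <- synth_spec(n_samples = 40, n_wavelengths = 30, slave_shift = 0,
                   slave_gain = 1, baseline_slave = numeric(),
                   unstable_bands = data.frame(start = 1L, end = 1L, sd = 0),
                   noise_sd = 0, seed = 6)
  g <- generate_pair(sp)
  # the pair is literally a = b, so |c_i| = mean(a_i)^2 / sd(a_i)^2
  prof <- stability_profile(g$pair, K = 15, rate = 0.8, seed = 2,
                            n_latent_master = 3, n_latent_slave = 3)
  plans <- monte_carlo_subsets(40, 0.8, 15, seed = 2)
  A <- sapply(plans, function(ix)
    fit_pls(g$pair$master$spectra[ix, ], g$pair$master$y[ix],
            3)$coefficients)
  expect_equal(prof$c_abs, rowMeans(A)^2 / apply(A, 1, stats::sd)^2,
               tolerance = 1e-10)
})

test_that("generate_outliers plants recoverable y-outliers", {
  s <- linear_set(n = 60, p = 15, noise = 0.1, seed = 12)
  same <- generate_outliers(s, 0)
  expect_identical(same$set$y, s$y)
  planted <- generate_outliers(s, 1, y_shift_sd = 10, seed = 3)
  kept <- screen_outliers(planted$set, 3)
  expect_false(planted$planted %in% kept)
  # several outliers: most are caught at the defaults
  hits <- vapply(1:10, function(sd) {
    s2 <- linear_set(n = 100, p = 15, noise = 0.1, seed = 100 + sd)
    pl <- generate_outliers(s2, 5, y_shift_sd = 10, seed = sd)
    kept <- screen_outliers(pl$set, 3)
    sum(!(pl$planted %in% kept))
  }, numeric(1))
  expect_gte(stats::median(hits), 4)
})
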