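test_that("stability index matches hand-evaluated cases", {
  # means 2 and 4, sds 1 and 2 -> 8 / 2 = 4
  pr <- stability_from_coefficients(matrix(c(1, 2, 3), 1),
                                    matrix(c(2, 4, 6), 1))
  expect_equal(pr$c_abs, 4, tolerance = 1e-15)
  # zero mean in one instrument kills the numerator
  pr0 <- stability_from_coefficients(matrix(c(1, -1), 1),
                                     matrix(c(5, 3), 1))
  expect_equal(pr0$c_abs, 0)
  # zero spread with nonzero mean product -> infinite stability
  A <- rbind(c(2, 2, 2), c(0, 0, 0))
  B <- rbind(c(3, 3, 3), c(0, 0, 0))
  prI <- stability_from_coefficients(A, B)
  expect_identical(prI$c_abs, c(Inf, 0))
})

test_that("stability_profile equals the naive double-loop oracle", {
  g <- small_demo_pair(seed = 31, n = 30, p = 20)
  cal <- subset_pair(g$pair, 1:24)
  K <- 10L
  prof <- stability_profile(cal, K = K, rate = 0.8, seed = 99,
                            n_latent_master = 3, n_latent_slave = 3)
  # rebuild the coefficient ensembles with the same sampling plan
  plans <- monte_carlo_subsets(24, 0.8, K = K, seed = 99)
  A <- sapply(plans, function(ix)
    fit_pls(cal$master$spectra[ix, ], cal$master$y[ix], 3)$coefficients)
  B <- sapply(plans, function(ix)
    fit_pls(cal$slave$spectra[ix, ], cal$slave$y[ix], 3)$coefficients)
  expect_lt(max(abs(prof$c_abs - naive_stability(A, B))), 1e-12)
  expect_equal(prof$c_min, min(prof$c_abs[is.finite(prof$c_abs)]))
  expect_equal(prof$c_max, max(prof$c_abs[is.finite(prof$c_abs)]))
})

test_that("identical instruments reduce the index to mean^2/sd^2", {
  set.seed(41)
  A <- matrix(rnorm(60, mean = 1), 6, 10)
  pr <- stability_from_coefficients(A, A)
  expect_equal(pr$c_abs, rowMeans(A)^2 / apply(A, 1, stats::sd)^2,
               tolerance = 1e-12)
})

test_that("select_by_threshold is a strict, monotone cut", {
  prof <- stability_from_coefficients(
    rbind(c(0.9, 1.1), c(4.9, 5.1), c(2.9, 3.1)),
    rbind(c(0.9, 1.1), c(4.9, 5.1), c(2.9, 3.1)))
  # c_abs here is (mean/sd)^2 per row; use a direct profile instead
  prof$c_abs <- c(1, 5, 3); prof$c_min <- 1; prof$c_max <- 5
  expect_identical(select_by_threshold(prof, 2.5), c(2L, 3L))
  expect_identical(select_by_threshold(prof, 0.5), 1:3)
  expect_identical(select_by_threshold(prof, 5), integer(0))
  # monotone: higher threshold selects a subset
  set.seed(5)
  prof$c_abs <- runif(200, 0, 10); prof$c_min <- min(prof$c_abs)
  prof$c_max <- max(prof$c_abs)
  ts <- sort(runif(10, 0, 10))
  sels <- lapply(ts, select_by_threshold, profile = prof)
  for (k in 2:10) expect_true(all(sels[[k]] %in% sels[[k - 1]]))
})

test_that("chromosomes decode to the documented endpoints and grid", {
  expect_equal(decode_threshold(rep(0L, 20), 1.5, 9.5), 1.5)
  expect_equal(decode_threshold(rep(1L, 20), 1.5, 9.5), 9.5)
  expect_equal(decode_threshold(c(rep(0L, 19), 1L), 0, 2^20 - 1), 1)
})

test_that("ga_config validates its fields", {
  expect_error(ga_config(pop_size = 51), "pop_size")
  expect_error(ga_config(p_mut = 1.2), "p_mut")
  expect_s3_class(ga_config(), "ga_config")
})

test_that("GA threshold search honours elitism and finds a usable cut", {
  g <- small_demo_pair(seed = 17)
  splits <- spxy_split(g$pair$master, 45, 15, 20)
  prof <- stability_profile(subset_pair(g$pair, splits$cal), K = 60,
                            rate = 0.8, seed = 3, max_latent = 6)
  cfg <- ga_config(pop_size = 16, max_gen = 15, stagnation = Inf, seed = 8)
  res <- ga_optimize_threshold(prof, g$pair, splits$cal, splits$val, "pds",
                               cfg, max_latent = 6)
  expect_true(all(diff(res$fitness_history) >= 0))
  expect_length(res$fitness_history, 15)
  expect_identical(res$selected,
                   select_by_threshold(prof, res$threshold_best))
  expect_gt(length(res$selected), 0)
  # final best beats (or ties) the direct fitness at the median stability
  med <- stats::median(prof$c_abs[is.finite(prof$c_abs)])
  sel_med <- select_by_threshold(prof, med)
  r <- nirct:::transfer_eval_core(g$pair, splits$cal, splits$val, sel_med,
                                  "pds", max_latent = 6,
                                  val_idx = splits$val)
  expect_gte(res$fitness_best + 1e-12, r$r2 / (1 + r$rmse))
})

test_that("safs_select is reproducible end to end", {
  g <- small_demo_pair(seed = 23, n = 50, p = 60)
  splits <- spxy_split(g$pair$master, 28, 10, 12)
  cfg <- ga_config(pop_size = 10, max_gen = 6, stagnation = Inf, seed = 5)
  r1 <- safs_select(g$pair, splits, "pds", cfg, K = 20, rate = 0.8,
                    seed = 2, max_latent = 5)
  r2 <- safs_select(g$pair, splits, "pds", cfg, K = 20, rate = 0.8,
                    seed = 2, max_latent = 5)
  expect_identical(r1$threshold_best, r2$threshold_best)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$fitness_history, r2$fitness_history)
})

test_that("an identical pair under PDS reproduces the master model", {
  g <- small_demo_pair(seed = 29, n = 50, p = 60)
  m <- g$pair$master
  pair_id <- paired_sets(m, m)
  splits <- spxy_split(m, 28, 10, 12)
  r <- nirct:::transfer_eval_core(pair_id, splits$cal, splits$pred, NULL,
                                  "pds", max_latent = 6,
                                  val_idx = splits$val,
                                  transfer_opts = list(n_latent_local = 9))
  mm <- fit_pls(m$spectra[splits$cal, ], m$y[splits$cal], r$n_latent)
  rm <- sqrt(mean((predict(mm, m$spectra[splits$pred, ]) -
                     m$y[splits$pred])^2))
  expect_lt(abs(r$rmse - rm), 1e-8)
})
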