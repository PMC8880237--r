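# Stability-analysis feature selection (SAFS).
#
# Wavelengths useful for calibration transfer are those whose PLS regression
# coefficient is simultaneously large and reproducible on BOTH instruments.
# K paired Monte-Carlo subsamples of the calibration set yield coefficient
# draws a_ij (master) and b_ij (slave) for wavelength i; the stability index
#
#   |c_i| = | mean_j(a_ij) * mean_j(b_ij) | / ( sd_j(a_ij) * sd_j(b_ij) )
#
# (sd with denominator K-1) scores each wavelength, and a genetic algorithm
# picks the threshold T maximizing the transfer fitness F = R^2/(1 + RMSEV)
# of a model rebuilt on the wavelengths with |c_i| > T.

#' Monte-Carlo stability profile of paired regression coefficients
#'
#' Fits master and slave PLS models on K paired random subsets of the
#' calibration samples (same subset indices for both instruments per draw)
#' and reduces the two coefficient ensembles to the per-wavelength stability
#' index described above. The latent-variable count is fixed once per
#' instrument (chosen by 10-fold cross-validation on the full calibration
#' set) so coefficient vectors stay comparable across draws.
#'
#' @param pair `paired_sets` restricted to calibration samples (already
#'   preprocessed).
#' @param K number of Monte-Carlo iterations (default 1000).
#' @param rate subsampling fraction (default 0.8).
#' @param seed RNG seed.
#' @param n_latent_master,n_latent_slave fixed component counts; `NULL`
#'   (default) selects them by cross-validation.
#' @param max_latent cap for that selection (default 15).
#' @param cv_scheme fold scheme for the selection, see [cv_rmse()].
#' @return object of class `stability_profile`: `c_abs` (one value per
#'   wavelength, `Inf` where a coefficient has zero spread but nonzero mean
#'   product), `c_min`/`c_max` (finite extremes, the threshold search range),
#'   plus `K`, `rate`, `seed` and the component counts used.
#' @export
stability_profile <- function(pair, K = 1000L, rate = 0.8, seed = 1L,
                              n_latent_master = NULL, n_latent_slave = NULL,
                              max_latent = 15L,
                              cv_scheme = "kfold_random") {
  stopifnot(inherits(pair, "paired_sets"))
  Xm <- pair$master$spectra; ym <- pair$master$y
  Xs <- pair$slave$spectra;  ys <- pair$slave$y
  n <- nrow(Xm); p <- ncol(Xm)
  if (is.null(n_latent_master))
    n_latent_master <- choose_n_latent(Xm, ym, max_latent, cv_scheme,
                                       seed = seed + 11L)
  if (is.null(n_latent_slave))
    n_latent_slave <- choose_n_latent(Xs, ys, max_latent, cv_scheme,
                                      seed = seed + 13L)
  subsets <- monte_carlo_subsets(n, rate, K, seed)
  A <- matrix(0, p, K); B <- matrix(0, p, K)
  for (j in seq_len(K)) {
    idx <- subsets[[j]]
    pm <- simpls_path(Xm[idx, , drop = FALSE], ym[idx], n_latent_master)
    ps <- simpls_path(Xs[idx, , drop = FALSE], ys[idx], n_latent_slave)
    A[, j] <- pm$betas[, pm$achieved]
    B[, j] <- ps$betas[, ps$achieved]
  }
  stability_from_coefficients(A, B, K = K, rate = rate, seed = seed,
                              n_latent_master = n_latent_master,
                              n_latent_slave = n_latent_slave)
}

#' Reduce paired coefficient ensembles to a stability profile
#'
#' Exposed separately so the index arithmetic can be verified directly on
#' hand-built coefficient matrices.
#'
#' @param A,B numeric matrices `n_wavelengths x K` of master and slave
#'   regression coefficients, one column per Monte-Carlo draw.
#' @param K,rate,seed,n_latent_master,n_latent_slave provenance metadata.
#' @return a `stability_profile`.
#' @export
stability_from_coefficients <- function(A, B, K = ncol(A), rate = NA_real_,
                                        seed = NA_integer_,
                                        n_latent_master = NA_integer_,
                                        n_latent_slave = NA_integer_) {
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)), ncol(A) >= 2)
  am <- rowMeans(A); bm <- rowMeans(B)
  asd <- sqrt(rowSums((A - am)^2) / (ncol(A) - 1))
  bsd <- sqrt(rowSums((B - bm)^2) / (ncol(B) - 1))
  num <- abs(am * bm)
  den <- asd * bsd
  c_abs <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  finite <- c_abs[is.finite(c_abs)]
  if (!length(finite)) stop("stability profile has no finite values")
  structure(list(c_abs = c_abs, K = as.integer(K), rate = rate,
                 seed = seed, c_min = min(finite), c_max = max(finite),
                 n_latent_master = n_latent_master,
                 n_latent_slave = n_latent_slave),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("<stability_profile> ", length(x$c_abs), " wavelengths, K = ", x$K,
      ", |c| in [", signif(x$c_min, 5), ", ", signif(x$c_max, 5), "]",
      if (any(is.infinite(x$c_abs))) " (+Inf entries)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Threshold a stability profile
#'
#' @param profile a `stability_profile`.
#' @param threshold finite cutoff T.
#' @return ascending indices of wavelengths with `|c_i| > T` (strict).
#' @export
select_by_threshold <- function(profile, threshold) {
  stopifnot(inherits(profile, "stability_profile"), is.finite(threshold))
  which(profile$c_abs > threshold)
}

#' Genetic-algorithm configuration for the threshold search
#'
#' Defaults follow the conventional small-GA setup used for this search:
#' population 50, 20-bit chromosomes, 100 generations, crossover probability
#' 0.8, mutation probability 0.1, elitism on. `mutation` chooses between
#' flipping one random bit per selected chromosome (`"per-chromosome"`,
#' default) and independent per-bit flips at rate `p_mut / chrom_bits`
#' (`"per-bit"`). `stagnation` adds an early stop after that many
#' generations without improvement (`Inf` disables it).
#'
#' @param pop_size even population size.
#' @param chrom_bits chromosome length in bits.
#' @param max_gen generation cap.
#' @param p_cross,p_mut crossover / mutation probabilities.
#' @param elitism keep the best individual each generation.
#' @param stagnation early-stop patience in generations.
#' @param mutation `"per-chromosome"` or `"per-bit"`.
#' @param seed RNG seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, chrom_bits = 20L, max_gen = 100L,
                      p_cross = 0.8, p_mut = 0.1, elitism = TRUE,
                      stagnation = 20L,
                      mutation = c("per-chromosome", "per-bit"), seed = 1L) {
  mutation <- match.arg(mutation)
  stopifnot(pop_size %% 2 == 0, pop_size >= 2, chrom_bits >= 1,
            max_gen >= 1, p_cross >= 0, p_cross <= 1, p_mut >= 0,
            p_mut <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 chrom_bits = as.integer(chrom_bits),
                 max_gen = as.integer(max_gen), p_cross = p_cross,
                 p_mut = p_mut, elitism = isTRUE(elitism),
                 stagnation = stagnation, mutation = mutation,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Decode a bit vector into a threshold
#'
#' `T = c_min + uint(bits) / (2^bits - 1) * (c_max - c_min)`: the all-zero
#' chromosome maps to `c_min`, the all-one chromosome to `c_max`.
#'
#' @param bits 0/1 integer vector (most significant bit first).
#' @param c_min,c_max threshold range.
#' @return numeric threshold.
#' @export
decode_threshold <- function(bits, c_min, c_max) {
  nb <- length(bits)
  u <- sum(bits * 2^((nb - 1):0))
  c_min + u / (2^nb - 1) * (c_max - c_min)
}

#' Transfer fitness of a threshold candidate
#'
#' `F = R^2 / (1 + RMSEV)`: large coefficients of determination and small
#' validation errors both push F up, so maximizing F balances the two.
#'
#' @param r2 coefficient of determination on the transferred validation set.
#' @param rmsev root mean square error of the same predictions.
#' @return the scalar fitness value.
#' @export
safs_fitness <- function(r2, rmsev) r2 / (1 + rmsev)

#' GA search for the optimal stability threshold
#'
#' Each 20-bit chromosome decodes to a threshold T inside the profile's
#' finite range. Its fitness rebuilds the whole transfer path on the
#' wavelengths with `|c_i| > T`: a master PLS model (latent variables chosen
#' by deterministic contiguous-block cross-validation), the named transfer
#' fitted on the calibration standards, the slave validation spectra
#' transferred and predicted, and `F = R^2 / (1 + RMSEV)`. Selection is
#' roulette-wheel on nonnegative fitness (uniform fallback when a generation
#' scores all zero), with one-point crossover, mutation, and elitism.
#'
#' @param profile a `stability_profile` for the calibration pair.
#' @param pair preprocessed `paired_sets` (full sample set).
#' @param cal,val integer indices of calibration and validation samples.
#' @param transfer_method `"sbc"`, `"pds"`, `"sst"` or `"osc"`.
#' @param cfg a [ga_config()].
#' @param max_latent latent-variable cap for the fitness models.
#' @param transfer_opts named list forwarded to the transfer fit (e.g.
#'   `window`, `n_osc`, `n_factors`).
#' @return object of class `safs_result`: `threshold_best`, `selected`,
#'   `fitness_history` (best F per generation), `fitness_best`, `profile`.
#' @export
ga_optimize_threshold <- function(profile, pair, cal, val, transfer_method,
                                  cfg = ga_config(), max_latent = 15L,
                                  transfer_opts = list()) {
  stopifnot(inherits(profile, "stability_profile"),
            inherits(pair, "paired_sets"), length(val) >= 1)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(bits) {
    T_ <- decode_threshold(bits, profile$c_min, profile$c_max)
    sel <- select_by_threshold(profile, T_)
    # many thresholds induce the same selection, so key the cache on it
    key <- paste(sel, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- if (!length(sel)) 0 else {
      res <- tryCatch(
        transfer_eval_core(pair, cal, val, sel, transfer_method,
                           max_latent = max_latent, val_idx = val,
                           transfer_opts = transfer_opts),
        error = function(e) NULL)
      if (is.null(res)) 0 else safs_fitness(res$r2, res$rmse)
    }
    cache[[key]] <- f
    f
  }

  nb <- cfg$chrom_bits
  history <- numeric(0)
  with_seed(cfg$seed, {
    pop <- matrix(stats::rbinom(cfg$pop_size * nb, 1, 0.5),
                  cfg$pop_size, nb)
    fit <- apply(pop, 1, fitness_of)
    best_bits <- pop[which.max(fit), ]
    best_fit <- max(fit)
    stale <- 0L
    for (gen in seq_len(cfg$max_gen)) {
      w <- pmax(fit, 0)
      prob <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
      parents <- sample.int(cfg$pop_size, cfg$pop_size, replace = TRUE,
                            prob = prob)
      newpop <- pop[parents, , drop = FALSE]
      for (i in seq(1, cfg$pop_size, by = 2)) {         # one-point crossover
        if (stats::runif(1) < cfg$p_cross && nb > 1) {
          cut <- sample.int(nb - 1, 1)
          tmp <- newpop[i, (cut + 1):nb]
          newpop[i, (cut + 1):nb] <- newpop[i + 1, (cut + 1):nb]
          newpop[i + 1, (cut + 1):nb] <- tmp
        }
      }
      if (cfg$mutation == "per-chromosome") {
        for (i in seq_len(cfg$pop_size)) {
          if (stats::runif(1) < cfg$p_mut) {
            b <- sample.int(nb, 1)
            newpop[i, b] <- 1L - newpop[i, b]
          }
        }
      } else {
        flips <- matrix(stats::runif(cfg$pop_size * nb) < cfg$p_mut / nb,
                        cfg$pop_size, nb)
        newpop[flips] <- 1L - newpop[flips]
      }
      if (cfg$elitism) newpop[1, ] <- best_bits
      pop <- newpop
      fit <- apply(pop, 1, fitness_of)
      gen_best <- max(fit)
      if (gen_best > best_fit) {
        best_fit <- gen_best
        best_bits <- pop[which.max(fit), ]
        stale <- 0L
      } else stale <- stale + 1L
      history <- c(history, if (cfg$elitism) best_fit else gen_best)
      if (is.finite(cfg$stagnation) && stale >= cfg$stagnation) break
    }
  })
  threshold_best <- decode_threshold(best_bits, profile$c_min, profile$c_max)
  selected <- select_by_threshold(profile, threshold_best)
  if (!length(selected))
    stop("empty selection at the optimized threshold ",
         signif(threshold_best, 6))
  structure(list(threshold_best = threshold_best, selected = selected,
                 fitness_history = history, fitness_best = best_fit,
                 profile = profile, transfer_method = transfer_method),
            class = "safs_result")
}

#' @export
print.safs_result <- function(x, ...) {
  cat("<safs_result> T_best = ", signif(x$threshold_best, 6), ", ",
      length(x$selected), " wavelengths selected, best F = ",
      signif(x$fitness_best, 5), "\n", sep = "")
  invisible(x)
}

#' Run the full SAFS selection
#'
#' Composes [stability_profile()] on the calibration subset of `pair` with
#' [ga_optimize_threshold()]. The transfer method is a required input because
#' the optimal threshold is transfer-specific: every transfer algorithm gets
#' its own GA run and its own `T_best`.
#'
#' @param pair preprocessed `paired_sets`.
#' @param splits list with `cal` and `val` index vectors (e.g. from
#'   [spxy_split()]).
#' @param transfer_method `"sbc"`, `"pds"`, `"sst"` or `"osc"`.
#' @param cfg a [ga_config()].
#' @param K,rate,seed Monte-Carlo settings, see [stability_profile()].
#' @param max_latent latent-variable cap used throughout.
#' @param transfer_opts options forwarded to the transfer fit.
#' @return a `safs_result`.
#' @export
safs_select <- function(pair, splits, transfer_method, cfg = ga_config(),
                        K = 1000L, rate = 0.8, seed = 1L, max_latent = 15L,
                        transfer_opts = list()) {
  prof <- stability_profile(subset_pair(pair, splits$cal), K = K,
                            rate = rate, seed = seed,
                            max_latent = max_latent)
  ga_optimize_threshold(prof, pair, splits$cal, splits$val, transfer_method,
                        cfg = cfg, max_latent = max_latent,
                        transfer_opts = transfer_opts)
}
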