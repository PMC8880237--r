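# Sample-set partitioning and screening.

# Full SPXY ranking of all samples: Kennard-Stone greedy selection on the
# joint distance d = d_x/max(d_x) + d_y/max(d_y). The first two ranked
# samples are the pair at maximal joint distance; each further sample
# maximizes its minimum joint distance to those already ranked.
spxy_rank <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(matrix(y, ncol = 1)))
  mx <- max(dx); my <- max(dy)
  if (mx == 0) mx <- 1
  if (my == 0) my <- 1
  d <- dx / mx + dy / my
  sel <- integer(n)
  first <- which(d == max(d), arr.ind = TRUE)[1, ]
  sel[1:2] <- sort(as.integer(first))
  remaining <- setdiff(seq_len(n), sel[1:2])
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  for (k in 3:n) {
    if (length(remaining) == 1L) {
      sel[k] <- remaining
      break
    }
    pick <- remaining[which.max(mind[remaining])]
    sel[k] <- pick
    remaining <- setdiff(remaining, pick)
    mind <- pmin(mind, d[, pick])
  }
  sel
}

#' Partition a dataset into calibration / validation / prediction sets
#'
#' SPXY ranking on joint spectral and property distances. The first `n_cal`
#' ranked samples form the calibration set; the ranking then continues among
#' the remaining samples (restarted SPXY on the leftover pool) to pick the
#' validation set, and what is left is the prediction set. The split is
#' deterministic; for a paired dataset the same index lists must be applied
#' to master and slave so the pairing survives.
#'
#' @param set a `spectra_set` (distances are computed on its spectra and y).
#' @param n_cal,n_val,n_pred set sizes; must sum to the sample count.
#' @return list of integer index vectors `cal`, `val`, `pred`.
#' @export
spxy_split <- function(set, n_cal, n_val, n_pred) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$spectra)
  if (n_cal < 2 || n_val < 1 || n_pred < 1)
    stop("partition error: each subset needs at least 1 sample (cal >= 2)")
  if (n_cal + n_val + n_pred != n)
    stop("partition error: sizes ", n_cal, "+", n_val, "+", n_pred,
         " do not sum to n = ", n)
  rank1 <- spxy_rank(set$spectra, set$y)
  cal <- sort(rank1[seq_len(n_cal)])
  rest <- setdiff(seq_len(n), cal)
  if (length(rest) > 2) {
    rank2 <- spxy_rank(set$spectra[rest, , drop = FALSE], set$y[rest])
    val <- sort(rest[rank2[seq_len(n_val)]])
  } else {
    val <- sort(rest[seq_len(n_val)])
  }
  pred <- sort(setdiff(rest, val))
  list(cal = cal, val = val, pred = pred)
}

#' Paired Monte-Carlo subsampling plans
#'
#' Draws `K` uniform random subsets (without replacement) of size
#' `round(rate * n_cal)` from the calibration indices. One list is produced
#' per iteration and, in paired mode, the same list is applied to both the
#' master and the slave calibration set so the two coefficient vectors of an
#' iteration see identical samples.
#'
#' @param n_cal calibration-set size.
#' @param rate sampling fraction in (0, 1); default 0.8.
#' @param K number of iterations; default 1000.
#' @param seed RNG seed (required, for reproducibility).
#' @return list of `K` integer vectors.
#' @export
monte_carlo_subsets <- function(n_cal, rate = 0.8, K = 1000L, seed) {
  if (rate <= 0 || rate >= 1) stop("sampling error: rate must be in (0,1)")
  if (K < 2) stop("sampling error: K must be >= 2")
  m <- round(rate * n_cal)
  if (m < 2) stop("sampling error: rate * n_cal < 2")
  with_seed(seed, lapply(seq_len(K), function(j) sort(sample.int(n_cal, m))))
}

# leverage + studentized-residual screening core for one dataset
flag_outliers <- function(X, y, n_components, leverage_mult, alpha) {
  n <- nrow(X)
  n_components <- min(n_components, n - 2L, ncol(X))
  path <- simpls_path(X, y, n_components)
  TT <- path$scores                      # orthonormal columns
  h <- 1 / n + rowSums(TT^2)
  resid <- y - (X %*% path$betas[, path$achieved] +
                  path$intercepts[path$achieved])
  dfree <- n - path$achieved - 1L
  s <- sqrt(sum(resid^2) / max(dfree, 1L))
  stud <- as.numeric(resid) / (s * sqrt(pmax(1 - h, 1e-12)))
  tcrit <- stats::qt(1 - alpha / 2, df = max(dfree, 1L))
  which(h > leverage_mult * mean(h) | abs(stud) > tcrit)
}

#' Screen outlying samples by leverage and studentized residuals
#'
#' Fits a PLS model on all samples and flags those whose leverage exceeds
#' `leverage_mult` times the mean leverage or whose studentized residual
#' exceeds the two-sided t critical value at `alpha`. Returns the indices of
#' the samples kept.
#'
#' @param set a `spectra_set`.
#' @param n_components PLS components for the screening model.
#' @param leverage_mult leverage cut multiplier (default 3).
#' @param alpha two-sided significance level of the residual t-test
#'   (default 0.05).
#' @return integer vector of kept sample indices.
#' @export
screen_outliers <- function(set, n_components = 5L, leverage_mult = 3,
                            alpha = 0.05) {
  stopifnot(inherits(set, "spectra_set"))
  flagged <- flag_outliers(set$spectra, set$y, n_components, leverage_mult,
                           alpha)
  if (length(flagged) >= nrow(set$spectra))
    stop("screening error: every sample was flagged")
  setdiff(seq_len(nrow(set$spectra)), flagged)
}

#' Outlier screening across condition groups with a merged removal list
#'
#' When the same physical samples are measured under several conditions
#' (e.g. moisture levels), each group is screened separately and the union
#' of flagged sample ids is removed from every group, keeping the groups
#' aligned sample-for-sample.
#'
#' @param sets named list of `spectra_set`s sharing sample ids.
#' @inheritParams screen_outliers
#' @return list with `kept_ids` and `sets` (each group reduced to kept ids).
#' @export
screen_outliers_groups <- function(sets, n_components = 5L,
                                   leverage_mult = 3, alpha = 0.05) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1),
                                          "spectra_set")))
  ids <- sets[[1]]$ids
  for (s in sets) if (!identical(s$ids, ids))
    stop("screening error: groups do not share the same sample ids")
  flagged_ids <- character(0)
  for (s in sets) {
    fl <- flag_outliers(s$spectra, s$y, n_components, leverage_mult, alpha)
    flagged_ids <- union(flagged_ids, ids[fl])
  }
  kept <- which(!(ids %in% flagged_ids))
  if (!length(kept)) stop("screening error: every sample was flagged")
  list(kept_ids = ids[kept],
       sets = lapply(sets, subset_samples, samples = kept))
}
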