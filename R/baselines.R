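# Baseline wavelength selectors used for comparison with SAFS.

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Runs `n_runs` Monte-Carlo iterations. In each, a random `rate` fraction of
#' the calibration rows is used to fit a PLS model; variables are then culled
#' in two stages: an enforced cut keeping the `ceil(r_i * p)` largest
#' absolute coefficients, where the exponentially decreasing function
#' `r_i = a * exp(-k i)` is pinned to keep all `p` variables at the first
#' iteration and 2 variables at the last (`a = (p/2)^(1/(N-1))`,
#' `k = log(p/2)/(N-1)`), followed by adaptive reweighted sampling: drawing
#' that many variables with replacement with probability proportional to
#' `|beta|` and keeping the distinct draws. The subset with the smallest
#' 10-fold cross-validated RMSE wins.
#'
#' @param X_cal,y_cal calibration data.
#' @param n_runs Monte-Carlo iterations (default 50).
#' @param rate row sampling fraction (default 0.8).
#' @param max_latent latent-variable cap (default 15).
#' @param seed RNG seed.
#' @param cv_scheme fold scheme for the per-subset RMSECV.
#' @return list of class `selection_result`: `selected` (ascending indices),
#'   `rmsecv` (winning value), `rmsecv_path`, `n_kept_path`, `method`.
#' @export
cars_select <- function(X_cal, y_cal, n_runs = 50L, rate = 0.8,
                        max_latent = 15L, seed = 1L,
                        cv_scheme = "kfold_random") {
  X <- as.matrix(X_cal); y <- as.numeric(y_cal)
  n <- nrow(X); p <- ncol(X)
  if (n_runs < 2) stop("n_runs must be >= 2")
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  keep <- seq_len(p)
  subsets <- vector("list", n_runs)
  rmsecv_path <- numeric(n_runs)
  n_kept_path <- integer(n_runs)
  with_seed(seed, {
    for (i in seq_len(n_runs)) {
      rows <- sample.int(n, max(2L, round(rate * n)))
      nlv <- min(max_latent, length(rows) - 1L, length(keep))
      path <- simpls_path(X[rows, keep, drop = FALSE], y[rows], nlv)
      beta <- abs(path$betas[, path$achieved])
      n_keep <- max(1L, min(length(keep), ceiling(a * exp(-k * i) * p)))
      ord <- order(beta, decreasing = TRUE)
      keep <- keep[ord[seq_len(n_keep)]]
      beta <- beta[ord[seq_len(n_keep)]]
      if (sum(beta) > 0 && length(keep) > 1) {   # adaptive reweighted sampling
        draw <- sample(seq_along(keep), n_keep, replace = TRUE,
                       prob = beta / sum(beta))
        keep <- sort(unique(keep[draw]))
      } else keep <- sort(keep)
      subsets[[i]] <- keep
      n_kept_path[i] <- length(keep)
      nlv_cv <- min(max_latent, length(keep))
      rmsecv_path[i] <- min(cv_rmse_path(X[, keep, drop = FALSE], y, nlv_cv,
                                         cv_scheme, seed = seed + i))
    }
  })
  best <- which.min(rmsecv_path)
  structure(list(selected = subsets[[best]], rmsecv = rmsecv_path[best],
                 rmsecv_path = rmsecv_path, n_kept_path = n_kept_path,
                 best_iteration = best, method = "cars"),
            class = "selection_result")
}

#' Synergy interval PLS (SiPLS)
#'
#' Splits the wavelength axis into `n_intervals` contiguous intervals (sizes
#' differing by at most one; by default the earlier intervals take the
#' remainder points) and exhaustively evaluates every combination of
#' `n_joint` intervals by cross-validated PLS, returning the combination
#' with the smallest RMSECV. Deterministic with the default contiguous-block
#' cross-validation.
#'
#' @param X_cal,y_cal calibration data.
#' @param n_intervals number of intervals (default 30).
#' @param n_joint intervals per combination (default 4).
#' @param max_latent latent-variable cap (default 15).
#' @param cv_scheme fold scheme (default deterministic contiguous blocks).
#' @param remainder `"first"` or `"last"`: which intervals receive the extra
#'   point when `p` is not divisible by `n_intervals`.
#' @param max_combinations guard against combinatorial blow-up.
#' @param seed seed for `"kfold_random"` folds.
#' @return `selection_result` with `selected`, `intervals` (winning interval
#'   ids), `rmsecv`, `interval_bounds`.
#' @export
sipls_select <- function(X_cal, y_cal, n_intervals = 30L, n_joint = 4L,
                         max_latent = 15L, cv_scheme = "contiguous_blocks",
                         remainder = c("first", "last"),
                         max_combinations = 50000L, seed = NULL) {
  remainder <- match.arg(remainder)
  X <- as.matrix(X_cal); y <- as.numeric(y_cal)
  n_intervals <- as.integer(n_intervals)
  n_joint <- as.integer(n_joint)
  p <- ncol(X)
  if (n_intervals > p) stop("n_intervals exceeds wavelength count")
  if (n_joint > n_intervals) stop("n_joint exceeds n_intervals")
  n_comb <- choose(n_intervals, n_joint)
  if (n_comb > max_combinations)
    stop("combination count ", n_comb, " exceeds cap ", max_combinations,
         "; reduce n_joint or n_intervals")
  sizes <- rep(p %/% n_intervals, n_intervals)
  extra <- p %% n_intervals
  if (extra > 0) {
    at <- if (remainder == "first") seq_len(extra)
          else (n_intervals - extra + 1L):n_intervals
    sizes[at] <- sizes[at] + 1L
  }
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  members <- lapply(seq_len(n_intervals), function(i) starts[i]:ends[i])
  combs <- utils::combn(n_intervals, n_joint)
  rmse <- apply(combs, 2, function(cc) {
    cols <- unlist(members[cc], use.names = FALSE)
    min(cv_rmse_path(X[, cols, drop = FALSE], y,
                     min(max_latent, length(cols)), cv_scheme, seed = seed))
  })
  best <- which.min(rmse)
  win <- combs[, best]
  structure(list(selected = unlist(members[win], use.names = FALSE),
                 intervals = win, rmsecv = rmse[best],
                 interval_bounds = data.frame(interval = seq_len(n_intervals),
                                              start = starts, end = ends),
                 method = "sipls"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$selected),
      " wavelengths, RMSECV = ", signif(x$rmsecv, 5), "\n", sep = "")
  invisible(x)
}
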