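# Partial least squares (single response) via SIMPLS. For one y, SIMPLS and
# NIPALS PLS1 give identical regression coefficients, so either serves as a
# cross-implementation reference for the other.

# Core decomposition: returns coefficient paths for 1..n_latent components on
# centered data plus the orthonormal score matrix (used for leverages).
simpls_path <- function(X, y, n_latent, tol = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, `-`)
  yc <- y - ym
  A <- min(n_latent, n - 1L, p)
  R <- matrix(0, p, A); TT <- matrix(0, n, A)
  V <- matrix(0, p, A); q <- numeric(A)
  s <- crossprod(Xc, yc)
  if (is.null(tol)) tol <- 1e-12 * max(1, sqrt(sum(Xc^2)))
  achieved <- 0L
  for (a in seq_len(A)) {
    r <- s
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (!is.finite(normt) || normt < tol) break
    t <- t / normt
    r <- r / normt
    pa <- crossprod(Xc, t)
    q[a] <- sum(yc * t)
    v <- pa
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, v)
      v <- v - Vp %*% crossprod(Vp, v)   # second pass against drift
    }
    nv <- sqrt(sum(v^2))
    if (nv < tol) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; TT[, a] <- t; V[, a] <- v
    achieved <- a
  }
  if (achieved == 0L) stop("rank error: X has no usable variance (rank 0)")
  R <- R[, seq_len(achieved), drop = FALSE]
  TT <- TT[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  # beta path: beta_a = sum_{k<=a} R[,k] q[k]
  betas <- apply(sweep(R, 2, q, `*`), 1, cumsum)
  betas <- if (achieved == 1L) matrix(betas, ncol = 1) else t(betas)
  intercepts <- ym - as.numeric(xm %*% betas)
  list(betas = betas, intercepts = intercepts, scores = TT,
       achieved = achieved, x_center = xm, y_center = ym)
}

#' Fit a PLS regression model
#'
#' Fits `y = X beta + e` by SIMPLS with `n_latent` components and returns the
#' coefficient vector in original (uncentered) units. X is mean-centered only
#' before decomposition: column autoscaling is deliberately off because SNV
#' pretreatment already row-normalizes and autoscaling would distort
#' derivative spectra.
#'
#' @param X numeric matrix (samples x variables).
#' @param y numeric response vector.
#' @param n_latent number of latent variables, `1 <= n_latent <=
#'   min(n-1, p)`.
#' @return object of class `pls_model`: coefficients, intercept, n_latent,
#'   centers, and training scores.
#' @export
fit_pls <- function(X, y, n_latent) {
  X <- as.matrix(X)
  n_latent <- as.integer(n_latent)
  if (n_latent < 1) stop("n_latent must be >= 1")
  if (n_latent > min(nrow(X) - 1L, ncol(X)))
    stop("n_latent exceeds min(n-1, p)")
  path <- simpls_path(X, y, n_latent)
  if (path$achieved < n_latent)
    stop("rank error: rank collapse after ", path$achieved,
         " components (requested ", n_latent, ")")
  structure(list(coefficients = path$betas[, n_latent],
                 intercept = path$intercepts[n_latent],
                 n_latent = n_latent,
                 x_center = path$x_center, y_center = path$y_center,
                 scores = path$scores),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("transform error: newdata has ", ncol(X), " columns, model expects ",
         length(object$coefficients))
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$coefficients), " variables, ", x$n_latent,
      " latent variable(s)\n", sep = "")
  invisible(x)
}

# fold assignment helpers ---------------------------------------------------

cv_folds <- function(n, folds, scheme = c("contiguous_blocks",
                                          "kfold_random"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (folds > n) stop("cv error: more folds than samples")
  if (scheme == "contiguous_blocks") {
    # deterministic: consecutive blocks with sizes differing by at most 1
    sizes <- rep(n %/% folds, folds)
    sizes[seq_len(n %% folds)] <- sizes[seq_len(n %% folds)] + 1L
    rep(seq_len(folds), times = sizes)
  } else {
    if (is.null(seed)) stop("kfold_random needs a seed")
    idx <- with_seed(seed, sample.int(n))
    out <- integer(n)
    out[idx] <- cv_folds(n, folds, "contiguous_blocks")
    out
  }
}

# run an expression with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cross-validated RMSE for every component count 1..max_latent in one pass.
cv_rmse_path <- function(X, y, max_latent, scheme = "contiguous_blocks",
                         folds = 10L, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fold_id <- cv_folds(n, folds, scheme, seed)
  A <- min(max_latent, n - max(table(fold_id)) - 1L, ncol(X))
  A <- max(A, 1L)
  press <- matrix(NA_real_, n, A)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    path <- simpls_path(X[!hold, , drop = FALSE], y[!hold], A)
    k <- path$achieved
    pred <- sweep(X[hold, , drop = FALSE] %*% path$betas, 2,
                  path$intercepts, `+`)
    press[hold, seq_len(k)] <- (pred[, seq_len(k), drop = FALSE] - y[hold])^2
    if (k < A) press[hold, (k + 1):A] <- press[hold, k]
  }
  sqrt(colMeans(press))
}

#' Cross-validated RMSE of a PLS model
#'
#' @param X,y training data.
#' @param n_latent component count to assess.
#' @param scheme `"contiguous_blocks"` (deterministic 10 consecutive blocks
#'   in sample order) or `"kfold_random"` (shuffled folds, needs `seed`).
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the random scheme.
#' @return root mean squared error over all held-out predictions.
#' @export
cv_rmse <- function(X, y, n_latent, scheme = "contiguous_blocks",
                    folds = 10L, seed = NULL) {
  path <- cv_rmse_path(X, y, n_latent, scheme, folds, seed)
  path[min(n_latent, length(path))]
}

#' Choose the number of latent variables by cross-validation
#'
#' Scans 1..`max_latent` and returns the count minimizing the CV RMSE; ties
#' break toward the smaller count. The conventional cap of 15 latent
#' variables bounds model complexity on full spectra.
#'
#' @inheritParams cv_rmse
#' @param max_latent upper bound on components (default 15).
#' @return integer component count.
#' @export
choose_n_latent <- function(X, y, max_latent = 15L,
                            scheme = "contiguous_blocks", folds = 10L,
                            seed = NULL) {
  path <- cv_rmse_path(X, y, max_latent, scheme, folds, seed)
  which.min(path)  # which.min returns the first (smallest) index on ties
}

#' Prediction metrics
#'
#' RMSE and coefficient of determination `R^2 = 1 - SSres/SStot` of a model
#' on an evaluation set. `r2_method = "pearson2"` instead returns the squared
#' Pearson correlation between predictions and reference values (a
#' sensitivity check; it ignores bias).
#'
#' @param model a `pls_model` (or anything with a `predict` method).
#' @param X,y evaluation data.
#' @param r2_method `"cod"` (default) or `"pearson2"`.
#' @return list with `rmse`, `r2`, `pred`.
#' @export
evaluate_model <- function(model, X, y, r2_method = c("cod", "pearson2")) {
  r2_method <- match.arg(r2_method)
  pred <- predict(model, X)
  metric_rmse_r2(pred, y, r2_method)
}

# shared by transfer paths that produce predictions directly
metric_rmse_r2 <- function(pred, y, r2_method = "cod") {
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("r2 undefined: constant reference values")
  resid <- y - pred
  rmse <- sqrt(mean(resid^2))
  r2 <- if (r2_method == "pearson2") {
    if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)^2
  } else {
    1 - sum(resid^2) / sum((y - mean(y))^2)
  }
  list(rmse = rmse, r2 = r2, pred = pred)
}
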