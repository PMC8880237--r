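# Calibration transfer algorithms. All of them fit on calibration/standard
# samples only; prediction-set rows never enter the fitted parameters.
#
# Three families:
#  * prediction-space correction (SBC): predict slave spectra with the master
#    model and linearly recalibrate the predictions;
#  * spectral-space mapping with standards (PDS, SST): learn a matrix sending
#    slave spectra into master space from paired standard measurements;
#  * standard-free projection (OSC): remove y-orthogonal structure from all
#    spectra before the master model sees them.

new_transfer_model <- function(method, params) {
  structure(c(list(method = method), params), class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat("<transfer_model> method =", x$method, "\n")
  invisible(x)
}

#' Slope/bias correction (SBC)
#'
#' Predicts the slave standards with the master model and fits the ordinary
#' least squares line `y = slope * y_hat + bias`; new slave predictions are
#' corrected by the same line.
#'
#' @param master_model a `pls_model` built on the master instrument.
#' @param slave_standards `spectra_set` of slave-measured standards carrying
#'   reference y values (column count must match the model).
#' @return `transfer_model` with `slope` and `bias`.
#' @export
fit_sbc <- function(master_model, slave_standards) {
  stopifnot(inherits(slave_standards, "spectra_set"))
  yhat <- predict(master_model, slave_standards$spectra)
  if (stats::sd(yhat) == 0)
    stop("fit error: zero variance in predicted standards")
  fit <- stats::lm.fit(cbind(1, yhat), slave_standards$y)
  new_transfer_model("sbc", list(bias = unname(fit$coefficients[1]),
                                 slope = unname(fit$coefficients[2])))
}

# local regression for one PDS window: PLS capped at the achievable rank;
# at full rank PLS coincides with minimum-norm least squares, which the SVD
# computes with better conditioning than a long SIMPLS recursion
local_regress <- function(Z, target, n_latent) {
  A <- min(n_latent, nrow(Z) - 1L, ncol(Z))
  if (A >= min(nrow(Z) - 1L, ncol(Z))) {
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    sv <- svd(Zc)
    pos <- sv$d > max(sv$d, 0) * 1e-12
    if (any(pos)) {
      b <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE],
                   target - mean(target)) / sv$d[pos])
      return(list(beta = as.numeric(b),
                  intercept = mean(target) - sum(mu * b)))
    }
  }
  path <- tryCatch(simpls_path(Z, target, A), error = function(e) NULL)
  if (is.null(path)) {
    # degenerate window (e.g. zero variance): ridge fallback
    Zc <- scale(Z, scale = FALSE)
    tc <- target - mean(target)
    G <- crossprod(Zc) + diag(1e-8, ncol(Z))
    b <- solve(G, crossprod(Zc, tc))
    return(list(beta = as.numeric(b),
                intercept = mean(target) - sum(colMeans(Z) * b)))
  }
  k <- path$achieved
  list(beta = path$betas[, k], intercept = path$intercepts[k])
}

#' Piecewise direct standardization (PDS)
#'
#' For each master wavelength i, the master absorbance column is regressed on
#' the slave columns inside a moving window centered at i (odd width, default
#' 9, truncated at the spectrum ends). The local regressions assemble a banded
#' transfer matrix F and intercept vector so that `transformed = slave %*% F +
#' intercept` lives in master space. The local regressor is PLS with up to
#' `n_latent_local` components (capped at the window's rank); with the window
#' spanning the full axis PDS coincides with global direct standardization.
#'
#' @param master_standards,slave_standards paired `spectra_set`s of transfer
#'   standards (same samples, same wavelength count).
#' @param window odd window width in points (default 9).
#' @param n_latent_local components for the local regressions (default
#'   `min(3, window)`).
#' @return `transfer_model` with transfer matrix `F` and `intercept`.
#' @export
fit_pds <- function(master_standards, slave_standards, window = 9L,
                    n_latent_local = NULL) {
  stopifnot(inherits(master_standards, "spectra_set"),
            inherits(slave_standards, "spectra_set"))
  Xm <- master_standards$spectra
  Xs <- slave_standards$spectra
  if (ncol(Xm) != ncol(Xs))
    stop("parameter error: master and slave wavelength counts differ")
  p <- ncol(Xm)
  window <- as.integer(window)
  if (window %% 2 == 0) stop("parameter error: window must be odd")
  if (window > 2L * p - 1L) stop("parameter error: window exceeds spectrum")
  if (is.null(n_latent_local)) n_latent_local <- min(3L, window)
  h <- (window - 1L) %/% 2L
  Fmat <- matrix(0, p, p)
  intercept <- numeric(p)
  for (i in seq_len(p)) {
    lo <- max(1L, i - h); hi <- min(p, i + h)
    fit <- local_regress(Xs[, lo:hi, drop = FALSE], Xm[, i], n_latent_local)
    Fmat[lo:hi, i] <- fit$beta
    intercept[i] <- fit$intercept
  }
  new_transfer_model("pds", list(F = Fmat, intercept = intercept,
                                 window = window))
}

#' Spectral space transformation (SST)
#'
#' The paired standards are concatenated column-wise `[master | slave]` and
#' factored by SVD; the leading `n_factors` right singular vectors split into
#' master loadings P1 and slave loadings P2 sharing one score space. A new
#' slave spectrum x is mapped by estimating its scores against P2 and adding
#' the loading difference: `x_master = x + t (P1 - P2)'` (on centered data).
#' `n_factors = "auto"` scans 1..cap and keeps the count minimizing the RMSE
#' of the transferred validation set under the supplied master model.
#'
#' @param master_standards,slave_standards paired standards.
#' @param n_factors integer, or `"auto"`.
#' @param cap upper bound for the auto scan (default `min(15, rank)`).
#' @param master_model,val_pair needed for `"auto"`: a fitted master
#'   `pls_model` and a `paired_sets` of validation samples.
#' @return `transfer_model` with centers, loadings and `n_factors`.
#' @export
fit_sst <- function(master_standards, slave_standards, n_factors = "auto",
                    cap = NULL, master_model = NULL, val_pair = NULL) {
  stopifnot(inherits(master_standards, "spectra_set"),
            inherits(slave_standards, "spectra_set"))
  Xm <- master_standards$spectra
  Xs <- slave_standards$spectra
  if (nrow(Xm) != nrow(Xs))
    stop("parameter error: standard sets must be paired row-for-row")
  p <- ncol(Xm)
  mum <- colMeans(Xm); mus <- colMeans(Xs)
  comb <- cbind(sweep(Xm, 2, mum), sweep(Xs, 2, mus))
  sv <- svd(comb)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (is.null(cap)) cap <- min(15L, rank)
  build <- function(f) {
    V <- sv$v[, seq_len(f), drop = FALSE]
    P1 <- V[seq_len(p), , drop = FALSE] *
      rep(sv$d[seq_len(f)], each = p)          # master loadings (scaled)
    P2 <- V[p + seq_len(p), , drop = FALSE] *
      rep(sv$d[seq_len(f)], each = p)          # slave loadings
    new_transfer_model("sst", list(P1 = P1, P2 = P2, mu_master = mum,
                                   mu_slave = mus, n_factors = f))
  }
  if (identical(n_factors, "auto")) {
    if (is.null(master_model) || is.null(val_pair))
      stop("auto factor choice needs master_model and val_pair")
    rmse_at <- vapply(seq_len(cap), function(f) {
      mdl <- build(f)
      Xt <- apply_transfer(mdl, val_pair$slave$spectra)
      sqrt(mean((predict(master_model, Xt) - val_pair$slave$y)^2))
    }, numeric(1))
    best <- which.min(rmse_at)
    mdl <- build(best)
    mdl$rmsev_scan <- rmse_at
    return(mdl)
  }
  n_factors <- as.integer(n_factors)
  if (n_factors < 1 || n_factors > rank)
    stop("rank error: n_factors must be in 1..", rank)
  build(n_factors)
}

#' Orthogonal signal correction (OSC)
#'
#' Extracts components of X that are exactly orthogonal to y: each component
#' maximizes explained X-variance subject to the linear constraint
#' `t(y) %*% X %*% w = 0`, giving scores with zero correlation to y by
#' construction. The stored weights/loadings deflate any new spectra the same
#' way, so OSC acts as a standard-free transfer pretreatment applied to both
#' instruments' spectra before the master model.
#'
#' @param X_cal calibration spectra matrix (typically master calibration, or
#'   pooled master+slave standards).
#' @param y_cal reference values for `X_cal`.
#' @param n_osc number of orthogonal components to remove (default 1).
#' @return `transfer_model` with weight matrix `W`, loading matrix `P`, and
#'   the centering vector.
#' @export
fit_osc <- function(X_cal, y_cal, n_osc = 1L) {
  X <- as.matrix(X_cal)
  y <- as.numeric(y_cal)
  n_osc <- as.integer(n_osc)
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  yc <- y - mean(y)
  W <- matrix(0, p, n_osc); P <- matrix(0, p, n_osc)
  if (n_osc > 0) {
    for (k in seq_len(n_osc)) {
      v <- crossprod(Xc, yc)                 # constraint direction in w-space
      nv <- sqrt(sum(v^2))
      # maximize ||Xc w||^2 s.t. v'w = 0: top eigenvector of the projected
      # cross-product matrix
      M <- crossprod(Xc)
      if (nv > 0) {
        vv <- v / nv
        M <- M - vv %*% crossprod(vv, M)
        M <- M - (M %*% vv) %*% t(vv)
      }
      eig <- eigen(M, symmetric = TRUE)
      w <- eig$vectors[, 1]
      if (nv > 0) w <- w - as.numeric(crossprod(w, v / nv)) * v / nv
      nw <- sqrt(sum(w^2))
      if (eig$values[1] <= 1e-12 * sum(Xc^2) || nw < 1e-12)
        stop("extraction error: no y-orthogonal variance left at component ",
             k)
      w <- w / nw
      t_k <- Xc %*% w
      p_k <- crossprod(Xc, t_k) / sum(t_k^2)
      Xc <- Xc - t_k %*% t(p_k)
      W[, k] <- w; P[, k] <- p_k
    }
  }
  new_transfer_model("osc", list(W = W, P = P, center = mu, n_osc = n_osc))
}

#' Scores of fitted OSC components on (new) spectra
#' @param model an OSC `transfer_model`.
#' @param spectra matrix of spectra.
#' @return score matrix, one column per removed component.
#' @export
osc_scores <- function(model, spectra) {
  stopifnot(model$method == "osc")
  Xc <- sweep(as.matrix(spectra), 2, model$center)
  S <- matrix(0, nrow(Xc), model$n_osc)
  for (k in seq_len(model$n_osc)) {
    t_k <- Xc %*% model$W[, k]
    S[, k] <- t_k
    Xc <- Xc - t_k %*% t(model$P[, k])
  }
  S
}

#' Apply a fitted transfer model
#'
#' PDS, SST and OSC map slave spectra into the space the master model
#' expects; SBC instead corrects predictions, so its input here is a vector
#' of master-model predictions of slave spectra.
#'
#' @param model a `transfer_model`.
#' @param x spectra matrix (pds/sst/osc) or prediction vector (sbc).
#' @return transformed spectra matrix, or corrected predictions for sbc.
#' @export
apply_transfer <- function(model, x) {
  stopifnot(inherits(model, "transfer_model"))
  switch(model$method,
    sbc = model$slope * as.numeric(x) + model$bias,
    pds = {
      X <- as.matrix(x)
      if (ncol(X) != nrow(model$F))
        stop("transform error: column count mismatch")
      sweep(X %*% model$F, 2, model$intercept, `+`)
    },
    sst = {
      X <- as.matrix(x)
      if (ncol(X) != length(model$mu_slave))
        stop("transform error: column count mismatch")
      Xc <- sweep(X, 2, model$mu_slave)
      # scores by least squares against the slave loadings
      G <- crossprod(model$P2)
      TT <- t(solve(G + diag(1e-12 * max(diag(G)), ncol(G)),
                    t(Xc %*% model$P2)))
      sweep(Xc + TT %*% t(model$P1 - model$P2), 2, model$mu_master, `+`)
    },
    osc = {
      X <- as.matrix(x)
      Xc <- sweep(X, 2, model$center)
      for (k in seq_len(model$n_osc)) {
        t_k <- Xc %*% model$W[, k]
        Xc <- Xc - t_k %*% t(model$P[, k])
      }
      sweep(Xc, 2, model$center, `+`)
    },
    stop("unknown transfer method ", model$method)
  )
}
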