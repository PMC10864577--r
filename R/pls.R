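# Compact single-response partial least squares (SIMPLS, de Jong 1993),
# used only inside CARS for its coefficient weights and RMSECV; the
# downstream regression model of every pipeline remains OLS. Mean-centered,
# unscaled. Kept internal: chemometrics users interact with CARS, not with
# this engine.

# Fit up to `ncomp` components; returns per-component cumulative
# coefficients so cross-validation over component counts costs one fit.
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1)
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean

  R <- matrix(0, p, ncomp) # x-weights mapping Xc to scores
  V <- matrix(0, p, ncomp) # orthonormal basis for deflating the covariance
  q <- numeric(ncomp)      # y-loadings
  S <- crossprod(Xc, yc)   # p x 1 covariance
  a <- 0
  for (k in seq_len(ncomp)) {
    r <- S
    t_raw <- Xc %*% r
    tn <- sqrt(sum(t_raw^2))
    if (!is.finite(tn) || tn < 1e-12) break
    r <- r / tn
    t_k <- t_raw / tn
    p_k <- crossprod(Xc, t_k)
    q_k <- sum(yc * t_k)
    v <- p_k
    if (k > 1) {
      Vk <- V[, seq_len(k - 1), drop = FALSE]
      v <- v - Vk %*% crossprod(Vk, p_k)
    }
    vn <- sqrt(sum(v^2))
    if (vn < 1e-12) break
    v <- v / vn
    S <- S - v %*% crossprod(v, S)
    R[, k] <- r
    V[, k] <- v
    q[k] <- q_k
    a <- k
  }
  if (a == 0) {
    # no extractable covariance: intercept-only model
    coefs <- matrix(0, p, 1)
  } else {
    R <- R[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    # cumulative coefficients: column k gives the k-component solution
    coefs <- sapply(seq_len(a), function(k) {
      R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]
    })
    coefs <- matrix(coefs, nrow = p)
  }
  list(coefs = coefs, x_means = x_means, y_mean = y_mean,
       ncomp = ncol(coefs))
}

# Predictions for every component count: returns m x ncomp matrix.
pls_predict_all <- function(fit, X) {
  Xc <- sweep(as.matrix(X), 2, fit$x_means)
  Xc %*% fit$coefs + fit$y_mean
}

# Coefficients of the `k`-component model (length-p vector).
pls_coef <- function(fit, k = fit$ncomp) {
  fit$coefs[, min(k, fit$ncomp)]
}

# Seeded k-fold RMSECV over component counts 1..max_comp; returns the
# minimizing component count and its RMSECV.
pls_cv <- function(X, y, max_comp, folds = 5, seed = 0L) {
  n <- nrow(X)
  folds <- min(folds, n)
  max_comp <- max(1, min(max_comp, ncol(X), n - ceiling(n / folds) - 1))
  fold_id <- assign_folds(n, folds, seed)
  sse <- numeric(max_comp)
  cnt <- numeric(max_comp)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], max_comp)
    if (fit$ncomp == 0) next
    pred <- pls_predict_all(fit, X[!tr, , drop = FALSE])
    k_avail <- seq_len(fit$ncomp)
    err <- (pred[, k_avail, drop = FALSE] - y[!tr])^2
    sse[k_avail] <- sse[k_avail] + colSums(err)
    cnt[k_avail] <- cnt[k_avail] + sum(!tr)
  }
  ok <- cnt > 0
  if (!any(ok)) return(list(ncomp = 1L, rmsecv = Inf))
  rmse <- sqrt(sse[ok] / cnt[ok])
  best <- which.min(rmse)
  list(ncomp = which(ok)[best], rmsecv = rmse[best])
}
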