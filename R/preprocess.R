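# Spectral pre-processing. SNV, detrend correction (DC) and Savitzky-Golay
# (SG) smoothing are per-spectrum transforms with no fitted state; direct
# orthogonal signal correction (DOSC) learns from the calibration spectra
# and response and must be applied to new spectra with the fitted
# parameters (dosc_fit / dosc_apply).

#' Standard normal variate transform
#'
#' Standardizes each spectrum (row) to mean 0 and sample SD 1 (denominator
#' n - 1), removing per-sample multiplicative scatter and additive offset:
#' `snv(a * x + b) = snv(x)` for any scalars `a > 0`, `b`.
#'
#' @param X n x p matrix of spectra (rows are samples).
#' @return An n x p matrix with row means 0 and row sample SDs 1.
#' @export
#' @examples
#' snv(matrix(c(1, 2, 3), nrow = 1))
snv <- function(X) {
  X <- check_matrix(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, sd)
  if (any(sdv == 0)) {
    abort(sprintf(
      "Degenerate constant spectrum in row(s) %s: SNV undefined.",
      paste(which(sdv == 0), collapse = ", ")
    ))
  }
  (X - mu) / sdv
}

#' Detrend correction
#'
#' Fits a least-squares polynomial of the given degree in wavelength to each
#' spectrum and subtracts it, removing baseline drift. The residual of each
#' row is orthogonal to the polynomial basis, so the transform is idempotent
#' and exactly annihilates planted polynomial drift up to `degree`.
#'
#' @param X n x p matrix of spectra.
#' @param wavelengths Length-p wavelength grid (nm).
#' @param degree Polynomial degree (default 1, a trend line).
#' @return The n x p matrix of detrended spectra.
#' @export
detrend <- function(X, wavelengths, degree = 1) {
  X <- check_matrix(X)
  p <- ncol(X)
  if (length(wavelengths) != p) abort("`wavelengths` must have length ncol(X).")
  if (degree < 0) abort("`degree` must be non-negative.")
  if (degree >= p) abort("`degree` must be smaller than the number of wavelengths.")
  # orthonormal polynomial basis in wavelength, shared by all rows
  B <- cbind(1 / sqrt(p), stats::poly(wavelengths, degree = degree))
  Q <- qr.Q(qr(B))
  X - (X %*% Q) %*% t(Q)
}

#' Savitzky-Golay convolution smoothing
#'
#' Smooths each spectrum with a moving-window polynomial fit; window edges
#' are handled by the boundary rows of the Savitzky-Golay projection matrix
#' (a polynomial fit over the first/last window evaluated at the edge
#' points), so the output has the same shape as the input.
#'
#' @param X n x p matrix of spectra.
#' @param window Odd window length (default 11 points).
#' @param polyorder Polynomial order, `< window` (default 2).
#' @return The n x p matrix of smoothed spectra.
#' @export
sg_smooth <- function(X, window = 11, polyorder = 2) {
  X <- check_matrix(X)
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (polyorder >= window) abort("`polyorder` must be smaller than `window`.")
  if (window > ncol(X)) abort("`window` must not exceed the number of wavelengths.")
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window))
}

#' Fit a direct orthogonal signal correction model
#'
#' Removes the spectral variation orthogonal to the response: (1) column-
#' center X and center y; (2) anti-project the centered spectra on the
#' centered response; (3) take the leading principal-component score
#' vectors of the anti-projected matrix; (4) compute deflation loadings
#' `p_k = X_c' t_k / (t_k' t_k)`; (5) solve minimum-norm weights
#' `w_k` with `X_c w_k ~ t_k` so new spectra can be corrected without the
#' response. Components are extracted sequentially with deflation; the
#' stored weights map the *original* centered spectra to all scores so that
#' correction of new data is a single linear operation.
#'
#' @param X n x p calibration spectra.
#' @param y Length-n response (SSC).
#' @param n_osc Number of orthogonal components to remove (default 1).
#' @return A list of class `dosc_model` with fields `n_osc`,
#'   `column_means`, `y_mean`, `weights` (p x n_osc) and `loadings`
#'   (p x n_osc). Training scores `X_c %*% weights` are orthogonal to the
#'   centered response.
#' @export
dosc_fit <- function(X, y, n_osc = 1) {
  X <- check_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n_osc < 1) abort("`n_osc` must be at least 1.")
  if (n <= n_osc + 1) abort("Need more than `n_osc` + 1 samples.")
  if (length(y) != n) abort("`y` must have length nrow(X).")
  if (sd(y) == 0) abort("`y` is constant: DOSC undefined.")

  column_means <- colMeans(X)
  y_mean <- mean(y)
  Xc0 <- sweep(X, 2, column_means)
  yc <- y - y_mean

  Xc <- Xc0
  Tm <- matrix(0, n, n_osc)
  P <- matrix(0, p, n_osc)
  for (k in seq_len(n_osc)) {
    # variation in Xc with the response direction removed
    Z <- Xc - yc %*% (crossprod(yc, Xc) / sum(yc^2))
    sv <- svd(Z, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12 * max(1, sqrt(sum(Xc0^2)))) {
      # nothing orthogonal to the response remains: null component
      break
    }
    t_k <- sv$u[, 1] * sv$d[1]
    P[, k] <- crossprod(Xc, t_k) / sum(t_k^2)
    Tm[, k] <- t_k
    Xc <- Xc - tcrossprod(t_k, P[, k])
  }
  # minimum-norm map from original centered spectra to all scores
  W <- apply(Tm, 2, function(tk) pinv_solve(Xc0, tk))
  W <- matrix(W, nrow = p)

  structure(
    list(n_osc = as.integer(n_osc), column_means = column_means,
         y_mean = y_mean, weights = W, loadings = P),
    class = "dosc_model"
  )
}

#' Apply a fitted DOSC correction to spectra
#'
#' Centers with the calibration column means, computes scores against the
#' fitted weights, deflates with the fitted loadings, and restores the
#' column means: `X_c - (X_c W) P' + means`. Applying to the calibration
#' matrix reproduces the corrected calibration spectra.
#'
#' @param model A `dosc_model` from [dosc_fit()].
#' @param X m x p matrix with the calibration wavelength count.
#' @return The corrected m x p matrix.
#' @export
dosc_apply <- function(model, X) {
  stopifnot(inherits(model, "dosc_model"))
  X <- check_matrix(X)
  if (ncol(X) != length(model$column_means)) {
    abort("Column count does not match the fitted DOSC model.")
  }
  Xc <- sweep(X, 2, model$column_means)
  scores <- Xc %*% model$weights
  sweep(Xc - tcrossprod(scores, model$loadings), 2, model$column_means, `+`)
}

# ---------------------------------------------------------------------------
# Pre-processor registry used by pipelines. "none", "snv", "dc" and "sg" are
# stateless per-row transforms; "dosc" is supervised and must be fitted on
# calibration rows only.

preprocess_methods <- function() c("none", "snv", "dosc", "dc", "sg")

preprocess_is_supervised <- function(method) identical(method, "dosc")

# Returns list(apply = function(X) ...) fitted on the training data.
preprocess_fit <- function(method, X, y, wavelengths, params = list()) {
  method <- match.arg(method, preprocess_methods())
  switch(method,
    none = list(apply = identity),
    snv = list(apply = snv),
    dc = {
      degree <- params$degree %||% 1
      list(apply = function(M) detrend(M, wavelengths, degree = degree))
    },
    sg = {
      window <- params$window %||% 11
      polyorder <- params$polyorder %||% 2
      list(apply = function(M) sg_smooth(M, window = window, polyorder = polyorder))
    },
    dosc = {
      model <- dosc_fit(X, y, n_osc = params$n_osc %||% 1)
      list(apply = function(M) dosc_apply(model, M), model = model)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
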