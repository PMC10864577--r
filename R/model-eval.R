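# Downstream modeling and evaluation: SPXY sample partitioning, ordinary
# least squares (minimum-norm, so wide "no-selection" designs never crash),
# and the RMSE / MAPE / RPD metric triple.

#' SPXY sample-set partitioning
#'
#' Kennard-Stone-style selection on the joint predictor-response distance
#' `d(i, j) = d_x(i, j) / max(d_x) + d_y(i, j) / max(d_y)` with Euclidean
#' `d_x` and absolute-difference `d_y`: the pair at maximal joint distance
#' seeds the calibration set, then the sample maximizing its minimum joint
#' distance to the selected set is added until the calibration size
#' `round(n * a / (a + b))` for ratio `"a:b"` is reached. Fully
#' deterministic; for 116 samples at 3:1 the split is 87 / 29.
#'
#' @param data A `spectral_dataset` tibble (or a plain matrix of spectra,
#'   in which case `y` must be given).
#' @param ratio Split ratio string, calibration:prediction (default
#'   `"3:1"`).
#' @param y Response vector, only when `data` is a matrix.
#' @return A list of class `spxy_split` with sorted integer vectors
#'   `cal_idx` and `pred_idx` partitioning `1:n`.
#' @export
#' @examples
#' ds <- generate_spectra(generator_config(n_samples = 16, seed = 1))
#' spxy_split(ds, "3:1")
spxy_split <- function(data, ratio = "3:1", y = NULL) {
  if (is.matrix(data)) {
    X <- data
    if (is.null(y)) abort("`y` is required when `data` is a matrix.")
  } else {
    X <- spectra_matrix(data)
    y <- spectra_ssc(data)
  }
  X <- check_matrix(X)
  n <- nrow(X)
  if (n < 4) abort("SPXY needs at least 4 samples.")
  parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts) || any(parts <= 0)) {
    abort("`ratio` must look like \"3:1\".")
  }
  n_cal <- round(n * parts[1] / sum(parts))
  if (n_cal < 2 || n_cal >= n) abort("Split ratio leaves too few samples in a set.")

  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  if (max(dx) == 0 || max(dy) == 0) {
    abort("All samples identical in X or y: SPXY distances degenerate.")
  }
  d <- dx / max(dx) + dy / max(dy)

  # seed with the maximal-distance pair (ties: lowest flat index)
  pair <- arrayInd(which.max(d), dim(d))
  sel <- sort(pair[1, ])
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  structure(
    list(cal_idx = sort(sel), pred_idx = sort(setdiff(seq_len(n), sel))),
    class = "spxy_split"
  )
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split: %d calibration / %d prediction samples>\n",
              length(x$cal_idx), length(x$pred_idx)))
  invisible(x)
}

#' Ordinary least squares with minimum-norm fallback
#'
#' Fits `y ~ intercept + F` by least squares. Rank-deficient or
#' underdetermined designs (`q > n`, as in no-selection pipelines on full
#' spectra) are solved by the minimum-norm solution via the SVD
#' pseudoinverse, which reproduces the training responses exactly when the
#' design spans them.
#'
#' @param features n x q feature matrix (`q = 0` gives an intercept-only model
#'   predicting `mean(y)`).
#' @param y Length-n response.
#' @return A list of class `ols_model` with `intercept` and
#'   `coefficients`.
#' @export
ols_fit <- function(features, y) {
  F <- as.matrix(features)
  if (!all(is.finite(F)) || !all(is.finite(y))) {
    abort("Non-finite values in the OLS inputs.")
  }
  if (length(y) != nrow(F)) abort("`y` must have length nrow(features).")
  if (length(y) < 2) abort("Need at least 2 samples.")
  if (ncol(F) == 0) {
    b <- c(mean(y))
    return(structure(list(intercept = b[1], coefficients = numeric(0)),
                     class = "ols_model"))
  }
  A <- cbind(1, F)
  beta <- NULL
  if (nrow(A) >= ncol(A)) {
    # QR fast path for full-column-rank designs; the pseudoinverse route
    # below is only needed for rank-deficient or wide designs
    qf <- qr(A)
    if (qf$rank == ncol(A)) beta <- qr.coef(qf, y)
  }
  if (is.null(beta)) beta <- pinv_solve(A, y)
  structure(
    list(intercept = beta[1], coefficients = as.vector(beta[-1])),
    class = "ols_model"
  )
}

#' @rdname ols_fit
#' @param model An `ols_model`.
#' @export
ols_predict <- function(model, features) {
  stopifnot(inherits(model, "ols_model"))
  F <- as.matrix(features)
  if (ncol(F) != length(model$coefficients)) {
    abort("Feature count does not match the fitted model.")
  }
  if (length(model$coefficients) == 0) {
    return(rep(model$intercept, nrow(F)))
  }
  as.vector(model$intercept + F %*% model$coefficients)
}

#' @export
print.ols_model <- function(x, ...) {
  cat(sprintf("<ols_model: intercept + %d coefficient(s)>\n",
              length(x$coefficients)))
  invisible(x)
}

#' RMSE, MAPE and RPD of predictions
#'
#' `rmse = sqrt(mean((y - yhat)^2))` (% Brix); `mape` is the mean absolute
#' percentage error as a fraction, `mean(|y - yhat| / y)`; `rpd` is the
#' residual prediction deviation, the sample SD (denominator N - 1) of the
#' measured values divided by the RMSE, so `rpd * rmse` always recovers
#' that SD. A perfect prediction yields `rpd = Inf` with a warning.
#'
#' @param y_true Measured values, strictly positive (% Brix).
#' @param y_pred Predicted values.
#' @return A one-row tibble with columns `rmse`, `mape`, `rpd`.
#' @export
#' @examples
#' compute_metrics(c(10, 12, 14), c(11, 11, 15))
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Input lengths differ.")
  if (length(y_true) < 2) abort("Need at least 2 values.")
  if (any(y_true <= 0)) abort("MAPE undefined: `y_true` must be strictly positive.")
  if (!all(is.finite(y_pred))) abort("Non-finite predictions.")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  mape <- mean(abs(y_true - y_pred) / y_true)
  if (rmse == 0) {
    warn("RMSE is 0: RPD reported as Inf.")
    rpd <- Inf
  } else {
    rpd <- sd(y_true) / rmse
  }
  tibble::tibble(rmse = rmse, mape = mape, rpd = rpd)
}
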