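# Wavelength selection under one fit/apply contract. Three families:
# projections (PCA, KPCA, SVD) transform spectra onto fitted components;
# rankers (F-test, Pearson correlation, mutual information) score each
# wavelength against SSC and keep the top n; iterative searchers (RFE, SPA,
# CARS, in selectors-iterative.R) decide a subset by repeated model fits.
# Every fitted selector is a `spectral_selector` applicable to new spectra
# without refitting.

selector_methods <- function() {
  c("none", "pca", "kpca", "svd", "f_test", "ppmcc", "mi", "rfe", "spa", "cars")
}

projection_methods <- function() c("pca", "kpca", "svd")
ranker_methods <- function() c("f_test", "ppmcc", "mi")

new_selector <- function(method, n_features, state, p, fit_seed = NA_integer_) {
  structure(
    list(method = method, n_features = as.integer(n_features),
         state = state, p = as.integer(p), fit_seed = fit_seed),
    class = "spectral_selector"
  )
}

#' @export
print.spectral_selector <- function(x, ...) {
  cat(sprintf("<spectral_selector: %s, %d feature(s) from %d wavelengths>\n",
              x$method, x$n_features, x$p))
  invisible(x)
}

#' Fit a projection-based selector (PCA, SVD or KPCA)
#'
#' PCA centers the columns and projects onto the top-n eigenvectors of the
#' covariance; SVD projects onto the top-n right singular vectors of the
#' uncentered matrix; KPCA builds a centered RBF kernel matrix and projects
#' onto its top-n eigenvectors, with out-of-sample extension through the
#' kernel against the training samples.
#'
#' @param method `"pca"`, `"svd"` or `"kpca"`.
#' @param X n x p calibration spectra.
#' @param n Number of components, `1 <= n <= min(n_samples, p)` (KPCA:
#'   `n < n_samples`).
#' @param kernel KPCA kernel: `"rbf"` (default, inverse length-scale
#'   `gamma`) or `"linear"` (provided so that KPCA can be checked against
#'   PCA).
#' @param gamma RBF inverse length-scale; defaults to `1/p`.
#' @return A `spectral_selector`; apply it with [apply_selector()].
#' @export
fit_projection <- function(method, X, n, kernel = c("rbf", "linear"),
                           gamma = NULL) {
  method <- match.arg(method, projection_methods())
  kernel <- match.arg(kernel)
  X <- check_matrix(X)
  p <- ncol(X)
  ns <- nrow(X)
  max_n <- if (method == "kpca") ns - 1 else min(ns, p)
  if (n < 1 || n > max_n) {
    abort(sprintf("`n` = %d out of range [1, %d] for %s.", n, max_n, method))
  }
  state <- switch(method,
    pca = {
      ctr <- colMeans(X)
      sv <- svd(sweep(X, 2, ctr), nu = 0, nv = n)
      list(center = ctr, rotation = sv$v,
           sdev = sv$d / sqrt(max(1, ns - 1)))
    },
    svd = list(v = svd(X, nu = 0, nv = n)$v),
    kpca = {
      kfun <- if (kernel == "rbf") {
        kernlab::rbfdot(sigma = gamma %||% 1 / p)
      } else {
        kernlab::vanilladot()
      }
      # kernlab warns when the centered kernel matrix has fewer eigenvalues
      # above threshold than requested; the achieved count is checked below
      kp <- suppressWarnings(kernlab::kpca(X, kernel = kfun, features = n))
      achieved <- ncol(kernlab::rotated(kp))
      if (achieved < n) {
        abort(sprintf(
          "KPCA kernel matrix supports only %d of the %d requested components.",
          achieved, n
        ))
      }
      list(kp = kp)
    }
  )
  new_selector(method, n, state, p)
}

# Like fit_projection() but tolerates a KPCA kernel matrix that supports
# fewer components than requested: the achieved count is kept in
# `n_features`.
fit_projection_upto <- function(method, X, n, kernel = "rbf", gamma = NULL) {
  if (method != "kpca") {
    return(fit_projection(method, X, n, kernel = kernel, gamma = gamma))
  }
  X <- check_matrix(X)
  p <- ncol(X)
  n <- min(n, nrow(X) - 1)
  kfun <- if (kernel == "rbf") {
    kernlab::rbfdot(sigma = gamma %||% 1 / p)
  } else {
    kernlab::vanilladot()
  }
  kp <- suppressWarnings(kernlab::kpca(X, kernel = kfun, features = n))
  new_selector("kpca", ncol(kernlab::rotated(kp)), list(kp = kp), p)
}

#' Score every wavelength against the response
#'
#' `f_test` computes the univariate regression F statistic
#' `F = (n - 2) r^2 / (1 - r^2)` per column; `ppmcc` the absolute Pearson
#' correlation; `mi` a k-nearest-neighbour mutual-information estimate
#' (k = 3), which also detects non-linear dependence. Higher scores mean
#' more relevant; constant columns score 0 with a warning.
#'
#' @param method `"f_test"`, `"ppmcc"` or `"mi"`.
#' @param X n x p matrix.
#' @param y Length-n response.
#' @param seed Seed for the MI estimator's duplicate-breaking jitter.
#' @return Length-p numeric vector of non-negative scores.
#' @export
rank_features <- function(method, X, y, seed = 0L) {
  method <- match.arg(method, ranker_methods())
  X <- check_matrix(X)
  n <- nrow(X)
  if (n < 3) abort("Need at least 3 samples to rank features.")
  if (sd(y) == 0) abort("`y` is constant: ranking undefined.")
  csd <- apply(X, 2, sd)
  const <- csd == 0
  if (any(const)) {
    warn(sprintf("%d constant column(s) scored 0.", sum(const)))
  }
  scores <- numeric(ncol(X))
  live <- !const
  if (method %in% c("f_test", "ppmcc")) {
    r <- as.vector(cor(X[, live, drop = FALSE], y))
    scores[live] <- if (method == "ppmcc") {
      abs(r)
    } else {
      r2 <- pmin(r^2, 1 - 1e-15)
      (n - 2) * r2 / (1 - r2)
    }
  } else {
    scores[live] <- apply(X[, live, drop = FALSE], 2, knn_mi, y = y,
                          k = 3L, seed = seed)
  }
  scores
}

# Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information between a
# single feature and y, k nearest neighbours in the max-norm. Duplicated
# values are broken with a tiny seeded jitter so neighbour counts are
# well-defined. Clamped at 0.
knn_mi <- function(x, y, k = 3L, seed = 0L) {
  n <- length(x)
  jitter_dup <- function(v, s) {
    if (anyDuplicated(v)) {
      scale <- max(sd(v), .Machine$double.eps) * 1e-10
      v + with_seed(s, rnorm(n, 0, scale))
    } else v
  }
  x <- jitter_dup(x, fanout_seed(seed, "mi_x"))
  y <- jitter_dup(y, fanout_seed(seed, "mi_y"))
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  # distance to the k-th neighbour (self-distance 0 occupies rank 1)
  eps <- apply(dz, 1, function(row) sort.int(row, partial = k + 1)[k + 1])
  nx <- rowSums(dx < eps) - 1
  ny <- rowSums(dy < eps) - 1
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(mi, 0)
}

# Indices of the n largest scores; ties broken toward the lower wavelength
# index. Returned sorted ascending.
top_n_indices <- function(scores, n) {
  if (n < 1 || n > length(scores)) abort("`n` out of range for top-n selection.")
  sort(order(-scores, seq_along(scores))[seq_len(n)])
}

#' Fit a ranker-based selector
#'
#' Scores all wavelengths with [rank_features()] and keeps the top `n`.
#'
#' @inheritParams rank_features
#' @param n Number of wavelengths to keep.
#' @return A `spectral_selector` holding sorted column indices.
#' @export
fit_ranker <- function(method, X, y, n, seed = 0L) {
  scores <- rank_features(method, X, y, seed = seed)
  new_selector(method, n, list(indices = top_n_indices(scores, n),
                               scores = scores),
               ncol(as.matrix(X)), fit_seed = seed)
}

#' Apply a fitted selector to spectra
#'
#' Projection selectors transform; index selectors subset columns. No
#' refitting occurs, so the same selector applied to the training matrix
#' always reproduces the training features.
#'
#' @param selector A `spectral_selector`.
#' @param X m x p matrix with the fitted wavelength count.
#' @return An m x `n_features` matrix.
#' @export
apply_selector <- function(selector, X) {
  stopifnot(inherits(selector, "spectral_selector"))
  X <- check_matrix(X)
  if (ncol(X) != selector$p) {
    abort(sprintf("Selector was fitted on %d wavelengths but X has %d columns.",
                  selector$p, ncol(X)))
  }
  st <- selector$state
  out <- switch(selector$method,
    pca = sweep(X, 2, st$center) %*% st$rotation,
    svd = X %*% st$v,
    kpca = kernlab::predict(st$kp, X),
    X[, st$indices, drop = FALSE]
  )
  unname(as.matrix(out))
}

# Selected column indices of an index-based selector (NULL for projections).
selector_indices <- function(selector) selector$state$indices
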