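# Iterative wavelength searchers: recursive feature elimination (RFE),
# the successive projections algorithm (SPA) and competitive adaptive
# reweighted sampling (CARS). RFE and SPA are deterministic; CARS is
# Monte-Carlo and fully seeded.

#' Recursive feature elimination
#'
#' Standardizes all columns to unit variance, then repeatedly fits an OLS
#' model (minimum-norm when the design is wide) and removes the single
#' column with the smallest absolute coefficient until `n` remain.
#' Deterministic; coefficient ties are broken by the lower wavelength
#' index.
#'
#' @param X n x p matrix.
#' @param y Length-n response.
#' @param n Number of wavelengths to keep, `1 <= n < p`.
#' @return A `spectral_selector` holding sorted column indices. The full
#'   elimination order is kept in the state, so nested subsets for any
#'   `m >= n` can be recovered without refitting.
#' @export
rfe_select <- function(X, y, n) {
  X <- check_matrix(X)
  p <- ncol(X)
  if (n < 1 || n >= p) abort("`n` must satisfy 1 <= n < p for RFE.")
  order_removed <- rfe_elimination_order(X, y)
  keep <- sort(setdiff(seq_len(p), order_removed[seq_len(p - n)]))
  new_selector("rfe", n, list(indices = keep, removal_order = order_removed), p)
}

# Column indices in the order they are eliminated (first removed first);
# the final surviving column is last.
rfe_elimination_order <- function(X, y) {
  p <- ncol(X)
  csd <- apply(X, 2, sd)
  Xs <- sweep(X, 2, ifelse(csd > 0, csd, 1), "/")
  active <- seq_len(p)
  removed <- integer(0)
  while (length(active) > 1) {
    b <- pinv_solve(cbind(1, Xs[, active, drop = FALSE]), y)[-1]
    worst <- active[order(abs(b), seq_along(active))[1]]
    removed <- c(removed, worst)
    active <- setdiff(active, worst)
  }
  c(removed, active)
}

#' Successive projections algorithm
#'
#' For every candidate start wavelength, grows a chain by repeatedly adding
#' the wavelength with the largest residual norm after orthogonal
#' projection onto the span of the chain so far (minimizing collinearity).
#' Every (start, chain-length) candidate with length in
#' `[n_min, n_max]` is scored by the mean fold RMSE of an OLS model under
#' seeded internal 5-fold cross-validation; the candidate with minimal CV
#' RMSE wins. Deterministic given the fold seed.
#'
#' @param X n x p matrix; must contain no all-zero column.
#' @param y Length-n response.
#' @param n_min,n_max Candidate subset-size range,
#'   `1 <= n_min <= n_max <= min(p, n - 2)`.
#' @param folds Internal CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @return A `spectral_selector` holding sorted column indices.
#' @export
spa_select <- function(X, y, n_min = 1, n_max = NULL, folds = 5, seed = 0L) {
  X <- check_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(n_max)) n_max <- min(30, p, n - 2)
  if (n_min < 1 || n_min > n_max || n_max > min(p, n - 2)) {
    abort("Require 1 <= n_min <= n_max <= min(p, n - 2) for SPA.")
  }
  norms0 <- colSums(X^2)
  if (any(norms0 == 0)) abort("SPA cannot run with all-zero columns present.")

  fold_id <- assign_folds(n, folds, seed)
  best <- list(rmse = Inf, subset = NULL, start = NA_integer_)
  for (start in seq_len(p)) {
    chain <- spa_chain(X, start, n_max)
    for (len in n_min:n_max) {
      subset <- chain[seq_len(len)]
      rmse <- cv_ols_rmse(X[, subset, drop = FALSE], y, fold_id)
      if (rmse < best$rmse) {
        best <- list(rmse = rmse, subset = subset, start = start)
      }
    }
  }
  new_selector("spa", length(best$subset),
               list(indices = sort(best$subset), start = best$start,
                    cv_rmse = best$rmse),
               p, fit_seed = seed)
}

# Chain of column indices grown by successive orthogonal projection.
spa_chain <- function(X, start, len) {
  R <- X
  chain <- integer(len)
  chain[1] <- as.integer(start)
  for (step in seq_len(len - 1)) {
    v <- R[, chain[step]]
    R <- R - v %*% (crossprod(v, R) / sum(v^2))
    norms <- colSums(R^2)
    norms[chain[seq_len(step)]] <- -Inf
    chain[step + 1] <- which.max(norms)
  }
  chain
}

# Mean fold RMSE of an intercept OLS model over a fixed fold assignment.
cv_ols_rmse <- function(Fm, y, fold_id) {
  rmse <- numeric(max(fold_id))
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    if (sum(tr) < ncol(Fm) + 2) return(Inf)
    fit <- ols_fit(Fm[tr, , drop = FALSE], y[tr])
    pred <- ols_predict(fit, Fm[!tr, , drop = FALSE])
    if (!all(is.finite(pred))) return(Inf)
    rmse[f] <- sqrt(mean((y[!tr] - pred)^2))
  }
  mean(rmse)
}

#' Competitive adaptive reweighted sampling
#'
#' Runs `runs` Monte-Carlo iterations. In iteration i, a random
#' `mc_ratio` fraction of samples fits a PLS model on the currently
#' retained wavelengths (components chosen by internal 5-fold
#' cross-validation, capped at `max_pls_components`); wavelengths are
#' weighted by normalized absolute PLS coefficients; an exponential decay
#' function forces the retained count down to
#' `ceiling(r_i * p)` with `r_i = a * exp(-k * i)`,
#' `a = (p/2)^(1/(runs-1))` and `k = log(p/2)/(runs-1)` (so `r_1 = 1` and
#' `r_runs = 2/p`); adaptive reweighted sampling then draws that many
#' wavelengths with replacement proportionally to weight and retains the
#' unique draws. Each iteration's retained set is scored by 5-fold PLS
#' RMSECV on all samples, and the set with minimal RMSECV wins. Fully
#' seeded.
#'
#' @param X n x p matrix.
#' @param y Length-n response.
#' @param runs Number of Monte-Carlo iterations (default 50).
#' @param mc_ratio Calibration fraction per iteration (default 0.8).
#' @param max_pls_components Cap on PLS components (default 10).
#' @param folds Internal CV folds (default 5).
#' @param seed Master seed for all draws.
#' @return A `spectral_selector` holding sorted column indices; the state
#'   records the per-iteration RMSECV trace and retained counts.
#' @export
cars_select <- function(X, y, runs = 50, mc_ratio = 0.8,
                        max_pls_components = 10, folds = 5, seed = 0L) {
  X <- check_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (runs < 2) abort("`runs` must be at least 2.")
  if (mc_ratio <= 0 || mc_ratio >= 1) abort("`mc_ratio` must be in (0, 1).")
  if (n < 2 * folds) abort("Too few samples for CARS internal cross-validation.")

  decay_a <- (p / 2)^(1 / (runs - 1))
  decay_k <- log(p / 2) / (runs - 1)
  n_cal <- ceiling(mc_ratio * n)

  retained <- seq_len(p)
  sets <- vector("list", runs)
  rmsecv <- rep(Inf, runs)
  counts <- integer(runs)
  with_seed(seed, {
    for (i in seq_len(runs)) {
      sub_seed <- sample.int(2147483646L, 2)
      cal <- sample.int(n, n_cal)
      Xr <- X[cal, retained, drop = FALSE]
      cap <- min(max_pls_components, length(retained), n_cal - 2)
      cv <- pls_cv(Xr, y[cal], max_comp = cap, folds = folds,
                   seed = sub_seed[1])
      fit <- pls_fit(Xr, y[cal], cv$ncomp)
      w <- abs(pls_coef(fit))
      if (sum(w) == 0) {
        # no usable coefficients: record a failed run, keep the set as-is
        sets[[i]] <- retained
        counts[i] <- length(retained)
        next
      }
      w <- w / sum(w)
      keep_count <- min(ceiling(decay_a * exp(-decay_k * i) * p),
                        length(retained))
      counts[i] <- keep_count
      ord <- order(-w, seq_along(w))[seq_len(keep_count)]
      forced <- retained[ord]
      fw <- w[ord]
      draws <- forced[sample.int(keep_count, keep_count, replace = TRUE,
                                 prob = fw)]
      retained <- sort(unique(draws))
      sets[[i]] <- retained
      if (length(retained) == 0) next
      cap2 <- min(max_pls_components, length(retained),
                  n - ceiling(n / folds) - 1)
      rmsecv[i] <- pls_cv(X[, retained, drop = FALSE], y, max_comp = cap2,
                          folds = folds, seed = sub_seed[2])$rmsecv
    }
  })
  best <- which.min(rmsecv)
  if (!is.finite(rmsecv[best])) {
    abort("Every CARS iteration collapsed; no retained wavelength set.")
  }
  new_selector("cars", length(sets[[best]]),
               list(indices = sets[[best]], rmsecv = rmsecv,
                    keep_counts = counts, best_run = best),
               p, fit_seed = seed)
}

#' Exponential decay function keep-ratio used by CARS
#'
#' `cars_keep_ratio(i, p, runs)` returns `r_i = a * exp(-k * i)` with
#' `a = (p/2)^(1/(runs-1))` and `k = log(p/2)/(runs-1)`, so that
#' `r_1 = 1` (all wavelengths eligible on the first iteration) and
#' `r_runs = 2/p` (two wavelengths on the last).
#'
#' @param i Iteration number(s).
#' @param p Total wavelength count.
#' @param runs Total iterations.
#' @return Keep ratio(s) in `(0, 1]`.
#' @export
cars_keep_ratio <- function(i, p, runs) {
  a <- (p / 2)^(1 / (runs - 1))
  k <- log(p / 2) / (runs - 1)
  a * exp(-k * i)
}
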