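# Oracle checks for the iterative searchers: each implementation is
# compared against an independent brute-force or hand-rolled reimplementation
# on small instances.

test_that("rfe keeps the dominant feature and matches a hand-rolled elimination loop", {
  set.seed(21)
  n <- 40
  X <- rand_matrix(n, 6, seed = 21)
  y <- X[, 1]
  expect_identical(tidy(rfe_select(X, y, 1))$index, 1L)

  # independent oracle: same rule, separately coded with lm()
  y2 <- X %*% c(2, -1.5, 1, 0.5, 0.2, 0.05) + rnorm(n, 0, 0.3)
  oracle_rfe <- function(X, y, n_keep) {
    Xs <- scale(X, center = FALSE, scale = apply(X, 2, sd))
    act <- seq_len(ncol(X))
    while (length(act) > n_keep) {
      cf <- coef(lm(y ~ Xs[, act]))[-1]
      act <- act[-which.min(abs(cf))]
    }
    sort(act)
  }
  for (k in c(1, 2, 3, 5)) {
    expect_identical(tidy(rfe_select(X, y2, k))$index,
                     as.integer(oracle_rfe(X, y2, k)))
  }

  # a single elimination step removes exactly the smallest-|coef| column
  cf1 <- coef(lm(y2 ~ scale(X, center = FALSE, scale = apply(X, 2, sd))))[-1]
  kept <- tidy(rfe_select(X, y2, 5))$index
  expect_identical(setdiff(1:6, kept), unname(which.min(abs(cf1))))
  expect_error(rfe_select(X, y2, 6), "1 <= n < p")
})

test_that("spa chains follow descending residual norms on orthogonal columns and never repeat a duplicated column", {
  # orthogonal columns with distinct norms
  Q <- qr.Q(qr(rand_matrix(20, 5, seed = 22)))
  X <- Q %*% diag(c(5, 3, 9, 1, 7))
  chain <- specstack:::spa_chain(X, start = 3, len = 5)
  expect_identical(chain, c(3L, 5L, 1L, 2L, 4L)) # norms 9,7,5,3,1

  # duplicated column has zero residual once its twin is chosen
  X2 <- cbind(X, X[, 3])
  chain2 <- specstack:::spa_chain(X2, start = 3, len = 5)
  expect_false(6 %in% chain2)
})

test_that("spa matches an exhaustive oracle over all (start, length) candidates", {
  ds <- generate_spectra(tiny_config(n_samples = 30, p_step = 100))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  p <- ncol(X)
  expect_lte(p, 6)

  seed <- 5
  sel <- spa_select(X, y, n_min = 1, n_max = 3, folds = 5, seed = seed)

  # oracle: same chains, every candidate scored by the same fold split
  fold_id <- specstack:::assign_folds(nrow(X), 5, seed)
  score <- function(subset) {
    rs <- vapply(1:5, function(f) {
      tr <- fold_id != f
      fit <- lm(y[tr] ~ X[tr, subset, drop = FALSE])
      pred <- cbind(1, X[!tr, subset, drop = FALSE]) %*% coef(fit)
      sqrt(mean((y[!tr] - pred)^2))
    }, numeric(1))
    mean(rs)
  }
  best <- list(rmse = Inf, subset = NULL)
  for (start in seq_len(p)) {
    chain <- specstack:::spa_chain(X, start, 3)
    for (len in 1:3) {
      r <- score(chain[seq_len(len)])
      if (r < best$rmse) best <- list(rmse = r, subset = sort(chain[seq_len(len)]))
    }
  }
  expect_identical(tidy(sel)$index, as.integer(best$subset))
  expect_equal(sel$state$cv_rmse, best$rmse)
})

test_that("cars keep-ratio endpoints follow the exponential decay closed form", {
  expect_equal(cars_keep_ratio(1, p = 100, runs = 50), 1)
  expect_equal(cars_keep_ratio(50, p = 100, runs = 50), 2 / 100)
  expect_equal(cars_keep_ratio(1, p = 221, runs = 50), 1)
  expect_equal(cars_keep_ratio(50, p = 221, runs = 50), 2 / 221)
  # monotone decreasing
  r <- cars_keep_ratio(1:50, p = 221, runs = 50)
  expect_true(all(diff(r) < 0))
})

test_that("cars forced retention counts are non-increasing and runs are seeded", {
  ds <- generate_spectra(noisy_config(n_samples = 50, seed = 77))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  s1 <- cars_select(X, y, runs = 30, seed = 99)
  s2 <- cars_select(X, y, runs = 30, seed = 99)
  expect_identical(s1, s2)
  counts <- s1$state$keep_counts
  expect_true(all(diff(counts) <= 0))
  idx <- tidy(s1)$index
  expect_identical(idx, sort(idx))
  expect_true(all(idx >= 1 & idx <= ncol(X)))
})

test_that("cars recovers planted informative bands on clean data", {
  ds <- generate_spectra(clean_config(n_samples = 80, seed = 55))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  truth <- spectra_truth(ds)
  wl <- spectra_wavelengths(ds)
  sel <- cars_select(X, y, seed = 13)
  picked_wl <- wl[tidy(sel)$index]
  hits <- vapply(truth$informative_centers, function(cc) {
    any(abs(picked_wl - cc) <= 2 * truth$config$band_widths[
      which(truth$config$band_centers == cc)])
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("internal simpls agrees with an independent pls oracle", {
  skip_if_not_installed("mixOmics")
  set.seed(30)
  n <- 25; p <- 8
  X <- rand_matrix(n, p, seed = 30)
  colnames(X) <- paste0("V", 1:p)
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(n, 0, 0.2)
  fit <- specstack:::pls_fit(X, y, 3)
  pred <- specstack:::pls_predict_all(fit, X)

  om <- suppressMessages(mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                                       scale = FALSE))
  po <- predict(om, X)$predict
  for (k in 1:3) {
    expect_equal(unname(pred[, k]), unname(po[, 1, k]), tolerance = 1e-6)
  }
})
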