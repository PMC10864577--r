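test_that("pca with a single direction of variance explains everything", {
  set.seed(11)
  dir <- rnorm(10)
  X <- outer(rnorm(40), dir)
  sel <- fit_projection("pca", X, 1)
  share <- sel$state$sdev[1]^2 / sum(sel$state$sdev^2)
  expect_equal(share, 1, tolerance = 1e-8)
})

test_that("pca scores equal svd-of-centered scores up to sign", {
  X <- rand_matrix(25, 12, seed = 12)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  s_pca <- apply_selector(fit_projection("pca", X, 4), X)
  s_svd <- apply_selector(fit_projection("svd", Xc, 4), Xc)
  for (k in 1:4) {
    expect_equal(abs(s_pca[, k]), abs(s_svd[, k]), tolerance = 1e-8)
  }
})

test_that("linear-kernel kpca matches pca scores up to sign and scale", {
  X <- rand_matrix(20, 10, seed = 13)
  s_pca <- apply_selector(fit_projection("pca", X, 3), X)
  s_kpca <- apply_selector(fit_projection("kpca", X, 3, kernel = "linear"), X)
  for (k in 1:3) {
    a <- s_kpca[, k]; b <- s_pca[, k]
    expect_gt(abs(cor(a, b)), 1 - 1e-6)
  }
})

test_that("projection selectors reject out-of-range component counts", {
  X <- rand_matrix(10, 6, seed = 14)
  expect_error(fit_projection("pca", X, 0), "out of range")
  expect_error(fit_projection("pca", X, 7), "out of range")
  expect_error(fit_projection("kpca", X, 10), "out of range")
})

test_that("rankers score relevance as documented", {
  set.seed(15)
  n <- 12
  X <- rand_matrix(n, 5, seed = 15)
  y <- X[, 3]
  expect_equal(rank_features("ppmcc", X, y)[3], 1)

  # closed form: r = 0.5, n = 12 gives F = 10/3
  r_target <- 0.5
  f_formula <- (n - 2) * r_target^2 / (1 - r_target^2)
  expect_equal(f_formula, 10 / 3)
  # and the implementation reproduces it on data engineered to r = 0.5
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x)); e <- e / sd(e)
  xs <- (x - mean(x)) / sd(x)
  y2 <- r_target * xs + sqrt(1 - r_target^2) * e
  F_imp <- rank_features("f_test", matrix(x, ncol = 1), y2)
  expect_equal(F_imp, 10 / 3, tolerance = 1e-8)

  expect_warning(
    s <- rank_features("ppmcc", cbind(X, 1), y),
    "constant"
  )
  expect_equal(s[6], 0)
})

test_that("mutual information detects a quadratic dependence invisible to correlation", {
  set.seed(16)
  n <- 200
  x <- rnorm(n)
  y <- x^2
  expect_lt(abs(cor(x, y)), 0.2)
  mi_signal <- rank_features("mi", matrix(x, ncol = 1), y, seed = 1)
  noise_scores <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    rank_features("mi", matrix(rnorm(n), ncol = 1), y, seed = i)
  }, numeric(1))
  expect_gt(mi_signal, quantile(noise_scores, 0.95))
})

test_that("top-n ranker sets are nested with deterministic tie-breaks", {
  ds <- generate_spectra(tiny_config(n_samples = 40))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  for (m in c("f_test", "ppmcc", "mi")) {
    prev <- integer(0)
    for (n in 1:6) {
      sel <- fit_ranker(m, X, y, n, seed = 2)
      idx <- tidy(sel)$index
      expect_true(all(prev %in% idx))
      prev <- idx
    }
  }
})

test_that("apply_selector subsets, transforms, and checks shapes", {
  X <- rand_matrix(15, 8, seed = 17)
  y <- X[, 2] + rnorm(15, 0, 0.1)
  sel <- fit_ranker("ppmcc", X, y, 8)
  expect_identical(apply_selector(sel, X), X)
  expect_identical(apply_selector(sel, X), apply_selector(sel, X))

  psel <- fit_projection("pca", X, 3)
  scores <- apply_selector(psel, X)
  expect_equal(apply_selector(psel, X[5, , drop = FALSE]),
               scores[5, , drop = FALSE])

  expect_error(apply_selector(sel, X[, 1:3]), "fitted on")
})

test_that("selectors are invariant to row order", {
  ds <- generate_spectra(tiny_config(n_samples = 30))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  perm <- sample(nrow(X))
  for (m in c("f_test", "ppmcc")) {
    s1 <- tidy(fit_ranker(m, X, y, 3))$index
    s2 <- tidy(fit_ranker(m, X[perm, ], y[perm], 3))$index
    expect_identical(s1, s2)
  }
  expect_identical(
    tidy(rfe_select(X, y, 3))$index,
    tidy(rfe_select(X[perm, ], y[perm], 3))$index
  )
})
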