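test_that("snv standardizes rows and is affine-invariant and idempotent", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))

  X <- rand_matrix(10, 50, seed = 3)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)

  a <- runif(10, 0.5, 2)
  b <- rnorm(10)
  expect_equal(snv(a * X + b), snv(X), tolerance = 1e-12)
  expect_equal(snv(snv(X)), snv(X), tolerance = 1e-10)

  expect_error(snv(matrix(1, 2, 4)), "row")
})

test_that("detrend annihilates polynomial drift and is idempotent", {
  wl <- seq(450, 1000, by = 10)
  p <- length(wl)

  # a perfectly linear row vanishes
  lin <- matrix(2 + 0.01 * wl, 1)
  expect_lt(max(abs(detrend(lin, wl))), 1e-10)

  # adding per-sample offset and slope changes nothing
  X <- rand_matrix(6, p, seed = 4)
  a <- rnorm(6); b <- rnorm(6)
  drift <- outer(a, rep(1, p)) + outer(b, wl)
  expect_equal(detrend(X + drift, wl), detrend(X, wl), tolerance = 1e-9)
  expect_equal(detrend(detrend(X, wl), wl), detrend(X, wl), tolerance = 1e-10)

  # degree-1 residual of a quadratic row is orthogonal to [1, wl]
  quad <- matrix(wl^2, 1)
  res <- detrend(quad, wl, degree = 1)
  expect_lt(abs(sum(res)), 1e-8 * sqrt(sum(quad^2)))
  expect_lt(abs(sum(res * wl)) / sqrt(sum(quad^2)) / sqrt(sum(wl^2)), 1e-8)

  expect_error(detrend(X, wl, degree = -1), "non-negative")
  expect_error(detrend(X, wl, degree = p), "smaller")
})

test_that("savitzky-golay smoothing: interpolating order is identity, constants survive, noise shrinks", {
  X <- rand_matrix(4, 80, seed = 5)
  expect_equal(sg_smooth(X, window = 5, polyorder = 4), X, tolerance = 1e-10)

  const <- matrix(3.7, 2, 40)
  expect_equal(sg_smooth(const, 11, 2), const, tolerance = 1e-10)

  set.seed(6)
  t <- seq(0, 4 * pi, length.out = 200)
  clean <- sin(t)
  noisy <- clean + rnorm(200, 0, 0.1)
  sm <- sg_smooth(matrix(noisy, 1), 11, 2)
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))

  expect_error(sg_smooth(X, window = 4), "odd")
  expect_error(sg_smooth(X, window = 5, polyorder = 5), "smaller")
})

test_that("dosc training scores are orthogonal to the centered response", {
  ds <- generate_spectra(noisy_config(n_samples = 40, seed = 31))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  m <- dosc_fit(X, y, n_osc = 2)
  Tm <- sweep(X, 2, m$column_means) %*% m$weights
  yc <- y - mean(y)
  for (k in seq_len(ncol(Tm))) {
    rel <- abs(sum(Tm[, k] * yc)) / (sqrt(sum(Tm[, k]^2)) * sqrt(sum(yc^2)))
    expect_lt(rel, 1e-6)
  }
})

test_that("dosc removes a response-independent rank-1 artifact", {
  set.seed(8)
  n <- 40; p <- 60
  y <- rnorm(n)
  signal_dir <- rnorm(p); signal_dir <- signal_dir / sqrt(sum(signal_dir^2))
  artifact_dir <- rnorm(p)
  artifact_dir <- artifact_dir - signal_dir * sum(artifact_dir * signal_dir)
  artifact_dir <- artifact_dir / sqrt(sum(artifact_dir^2))
  artifact_load <- rnorm(n, 0, 2)
  X <- outer(y, signal_dir) + outer(artifact_load, artifact_dir) +
    matrix(rnorm(n * p, 0, 0.01), n, p)

  m <- dosc_fit(X, y, n_osc = 1)
  corrected <- dosc_apply(m, X)
  energy <- function(M) sum((scale(M, scale = FALSE) %*% artifact_dir)^2)
  expect_lt(energy(corrected), 0.1 * energy(X))
})

test_that("dosc on rank-1 data fully correlated with y removes nothing", {
  set.seed(9)
  y <- rnorm(30)
  dir <- rnorm(20)
  X <- outer(y, dir)
  m <- dosc_fit(X, y, n_osc = 1)
  Tm <- sweep(X, 2, m$column_means) %*% m$weights
  expect_lt(sqrt(sum(Tm^2)), 1e-6 * sqrt(sum(X^2)))
})

test_that("dosc_apply matches its definition and handles edge cases", {
  ds <- generate_spectra(noisy_config(n_samples = 30, seed = 33))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  m <- dosc_fit(X, y)

  # one-shot formula
  Xc <- sweep(X, 2, m$column_means)
  manual <- sweep(Xc - (Xc %*% m$weights) %*% t(m$loadings), 2,
                  m$column_means, `+`)
  expect_equal(dosc_apply(m, X), manual)

  # a new spectrum equal to a training spectrum corrects identically
  expect_equal(dosc_apply(m, X[3, , drop = FALSE]),
               dosc_apply(m, X)[3, , drop = FALSE])

  # zero weights means identity
  m0 <- m
  m0$weights <- m$weights * 0
  expect_equal(dosc_apply(m0, X), X)

  expect_error(dosc_apply(m, X[, 1:5]), "Column count")
  expect_error(dosc_fit(X, rep(1, nrow(X))), "constant")
  expect_error(dosc_fit(X, y, n_osc = 0), "at least 1")
})

test_that("all pre-processors preserve matrix shape and 'none' is the identity", {
  ds <- generate_spectra(noisy_config(n_samples = 25, seed = 35))
  X <- spectra_matrix(ds); y <- spectra_ssc(ds)
  wl <- spectra_wavelengths(ds)
  for (m in c("none", "snv", "dc", "sg", "dosc")) {
    pre <- specstack:::preprocess_fit(m, X, y, wl)
    out <- pre$apply(X)
    expect_identical(dim(out), dim(X))
  }
  expect_identical(specstack:::preprocess_fit("none", X, y, wl)$apply(X), X)
})
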