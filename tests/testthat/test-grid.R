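test_that("a restricted grid has the right cardinality and is reproducible", {
  ds <- generate_spectra(noisy_config(n_samples = 40, seed = 81))
  g1 <- run_grid(ds, preprocess = "none", select = c("none", "f_test"),
                 seed = 10)
  expect_identical(nrow(g1), 2L)
  expect_identical(g1$select, c("none", "f_test"))
  g2 <- run_grid(ds, preprocess = "none", select = c("none", "f_test"),
                 seed = 10)
  expect_equal(tibble::as_tibble(g1), tibble::as_tibble(g2))
})

test_that("best_frequency tallies a hand-built table correctly", {
  tab <- tibble::tibble(
    preprocess = rep(c("none", "snv"), each = 2),
    select = rep(c("pca", "cars"), 2),
    n = 2L,
    rmse_c = c(1.0, 0.5, 0.7, 0.9),
    mape_c = c(0.10, 0.05, 0.07, 0.09),
    rpd_c = c(1.0, 2.0, 1.5, 1.1),
    rmse_p = c(0.8, 0.9, 0.6, 0.7),
    mape_p = c(0.08, 0.09, 0.06, 0.07),
    rpd_p = c(1.2, 1.1, 1.7, 1.4),
    failed = FALSE, reason = NA_character_
  )
  bf <- best_frequency(tab)
  # group "none": cars wins the 3 calibration metrics, pca the 3 prediction
  expect_identical(bf$cars[bf$preprocess == "none"], 3L)
  expect_identical(bf$pca[bf$preprocess == "none"], 3L)
  # group "snv": pca wins everything
  expect_identical(bf$pca[bf$preprocess == "snv"], 6L)
  expect_identical(bf$sum, c(6L, 6L))
  expect_identical(unname(attr(bf, "column_sums")["pca"]), 9L)
})

test_that("a method that is best everywhere collects the full column sum", {
  tab <- tidyr::expand_grid(
    preprocess = c("none", "snv", "dc"),
    select = c("none", "mi", "cars")
  )
  tab$n <- 1L
  base <- ifelse(tab$select == "cars", 0.5, 1)
  tab$rmse_c <- base; tab$mape_c <- base / 10; tab$rpd_c <- 1 / base
  tab$rmse_p <- base; tab$mape_p <- base / 10; tab$rpd_p <- 1 / base
  tab$failed <- FALSE; tab$reason <- NA_character_
  bf <- best_frequency(tab)
  expect_identical(unname(attr(bf, "column_sums")["cars"]),
                   as.integer(6 * 3))
  expect_identical(sum(bf$sum), 18L)
})

test_that("failed rows never win and ties warn with canonical-order break", {
  tab <- tibble::tibble(
    preprocess = "none",
    select = c("none", "pca", "cars"),
    n = 1L,
    rmse_c = c(0.1, 0.5, 0.5), mape_c = c(0.01, 0.05, 0.06),
    rpd_c = c(9, 3, 2),
    rmse_p = c(0.1, 0.5, 0.6), mape_p = c(0.01, 0.05, 0.06),
    rpd_p = c(9, 3, 2),
    failed = c(TRUE, FALSE, FALSE), reason = c("x", NA, NA)
  )
  # the failed "none" row has the best raw numbers but cannot win; pca and
  # cars tie on rmse_c and the canonical order awards it to pca
  expect_warning(bf <- best_frequency(tab), "Tie")
  expect_identical(bf$none, 0L)
  expect_identical(bf$pca, 6L)
})

test_that("selection_helps flags selectors beating the baseline on both RMSEs", {
  tab <- tibble::tibble(
    preprocess = "none",
    select = c("none", "pca", "mi"),
    n = 1L,
    rmse_c = c(1.0, 0.8, 1.2), mape_c = 0.05, rpd_c = 1,
    rmse_p = c(0.9, 0.7, 0.8), mape_p = 0.05, rpd_p = 1,
    failed = FALSE, reason = NA_character_
  )
  h <- selection_helps(tab)
  expect_identical(h$helps[h$select == "pca"], TRUE)
  expect_identical(h$helps[h$select == "mi"], FALSE)
})

test_that("spectra CSV round-trips losslessly and validates its header", {
  ds <- generate_spectra(noisy_config(n_samples = 10, seed = 83))
  csv <- tempfile(fileext = ".csv")
  truth <- tempfile(fileext = ".json")
  write_spectra_csv(ds, csv, truth_path = truth)
  back <- read_spectra_csv(csv, truth_path = truth)
  expect_lt(max(abs(spectra_matrix(back) - spectra_matrix(ds))), 1e-12)
  expect_equal(spectra_ssc(back), spectra_ssc(ds))
  expect_equal(spectra_truth(back)$informative_centers,
               spectra_truth(ds)$informative_centers)

  # unsorted wavelength columns are rejected
  df <- utils::read.csv(csv, check.names = FALSE)
  bad <- df[, c(1, 2, ncol(df), 4:(ncol(df) - 1), 3)]
  bad_csv <- tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_csv, row.names = FALSE)
  expect_error(read_spectra_csv(bad_csv), "ascending")

  no_ssc <- df[, -2]
  no_ssc_csv <- tempfile(fileext = ".csv")
  utils::write.csv(no_ssc, no_ssc_csv, row.names = FALSE)
  expect_error(read_spectra_csv(no_ssc_csv), "ssc")
})

test_that("result tables round-trip through disk and tallies agree", {
  ds <- generate_spectra(noisy_config(n_samples = 40, seed = 85))
  g <- run_grid(ds, preprocess = c("none", "snv"),
                select = c("none", "pca", "f_test"), seed = 12)
  dir <- tempfile()
  write_results(g, dir)
  back <- read_results(dir)
  expect_equal(tibble::as_tibble(back)[names(g)], tibble::as_tibble(g),
               tolerance = 1e-12)
  expect_equal(
    tibble::as_tibble(best_frequency(back)),
    tibble::as_tibble(best_frequency(g))
  )
  expect_identical(attr(back, "seed"), attr(g, "seed"))
})

test_that("run configurations load from json and yaml", {
  cfg <- list(split = list(ratio = "3:1"), cv = list(folds = 5, seed = 1))
  jp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  yp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yp)
  expect_equal(read_run_config(jp)$split$ratio, "3:1")
  expect_equal(read_run_config(yp)$cv$folds, 5)
  expect_error(read_run_config(tempfile(fileext = ".txt")), "json")
})
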