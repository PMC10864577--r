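# Pipeline recipes and their evaluation protocol: a pipeline is one
# (pre-processor, selector) grid cell, evaluated by seeded 5-fold
# cross-validation on the calibration set (choosing the feature count n for
# rankers, projections and RFE) plus a single-shot fit on the full
# calibration set scored on the held-out prediction set. Supervised steps
# (DOSC, every selector) are refitted inside each fold so no held-out
# information leaks into them.

#' Define a feature-engineering pipeline
#'
#' @param preprocess One of `"none"`, `"snv"`, `"dosc"`, `"dc"`, `"sg"`.
#' @param select One of `"none"`, `"pca"`, `"kpca"`, `"svd"`, `"f_test"`,
#'   `"ppmcc"`, `"mi"`, `"rfe"`, `"spa"`, `"cars"`.
#' @param n Feature-count policy: `"cv"` (default) searches
#'   `1..min(30, fold size - 2)` by cross-validation for rankers,
#'   projections and RFE; a fixed integer pins it. SPA and CARS determine
#'   their subset size internally and ignore this.
#' @param preprocess_params,select_params Named lists of method options
#'   (e.g. `list(window = 11, polyorder = 2)` for SG;
#'   `list(runs = 50, mc_ratio = 0.8)` for CARS; `list(degree = 1)` for
#'   detrend; `list(n_osc = 1)` for DOSC; `list(kernel = "rbf")` for KPCA).
#' @return A list of class `pipeline_spec`.
#' @export
#' @examples
#' pipeline_spec("sg", "cars")
pipeline_spec <- function(preprocess = "none", select = "none", n = "cv",
                          preprocess_params = list(), select_params = list()) {
  preprocess <- match.arg(preprocess, preprocess_methods())
  select <- match.arg(select, selector_methods())
  if (!(identical(n, "cv") || (is.numeric(n) && length(n) == 1 && n >= 1))) {
    abort("`n` must be \"cv\" or a positive integer.")
  }
  structure(
    list(preprocess = preprocess, select = select, n = n,
         preprocess_params = preprocess_params,
         select_params = select_params),
    class = "pipeline_spec"
  )
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf("<pipeline_spec: %s + %s (n = %s) + ols>\n",
              x$preprocess, x$select,
              if (identical(x$n, "cv")) "cv" else x$n))
  invisible(x)
}

selector_family <- function(method) {
  if (method == "none") return("none")
  if (method %in% projection_methods()) return("projection")
  if (method %in% ranker_methods()) return("ranker")
  if (method == "rfe") return("rfe")
  "search" # spa, cars
}

# Fit the selector of `spec` on training data; `n` is used by nested-n
# families only.
fit_selector_final <- function(spec, X, y, n, seed) {
  sp <- spec$select_params
  switch(selector_family(spec$select),
    none = NULL,
    projection = fit_projection(spec$select, X, n,
                                kernel = sp$kernel %||% "rbf",
                                gamma = sp$gamma),
    ranker = fit_ranker(spec$select, X, y, n, seed = seed),
    rfe = rfe_select(X, y, n),
    search = if (spec$select == "spa") {
      spa_select(X, y,
                 n_min = sp$n_min %||% 1,
                 n_max = sp$n_max %||% min(30, ncol(X), nrow(X) - 2),
                 seed = seed)
    } else {
      cars_select(X, y,
                  runs = sp$runs %||% 50,
                  mc_ratio = sp$mc_ratio %||% 0.8,
                  max_pls_components = sp$max_components %||% 10,
                  seed = seed)
    }
  )
}

# Nested candidate-subset machinery for families whose n is chosen by CV.
# Returns `get(n)` giving train/test feature matrices for the leading n
# features of a single fitted ordering, plus the largest n available in
# this fold (a near-singular KPCA kernel can yield fewer components than
# requested).
nested_features <- function(spec, X_tr, y_tr, X_te, n_max, seed) {
  fam <- selector_family(spec$select)
  sp <- spec$select_params
  if (fam == "ranker") {
    scores <- rank_features(spec$select, X_tr, y_tr, seed = seed)
    ordering <- order(-scores, seq_along(scores))
    get <- function(n) {
      idx <- sort(ordering[seq_len(n)])
      list(tr = X_tr[, idx, drop = FALSE], te = X_te[, idx, drop = FALSE])
    }
    list(get = get, n_avail = n_max)
  } else if (fam == "rfe") {
    elim <- rfe_elimination_order(X_tr, y_tr)
    p <- ncol(X_tr)
    get <- function(n) {
      idx <- sort(elim[seq(p - n + 1, p)])
      list(tr = X_tr[, idx, drop = FALSE], te = X_te[, idx, drop = FALSE])
    }
    list(get = get, n_avail = n_max)
  } else { # projection: leading components of one n_max-component fit
    sel <- fit_projection_upto(spec$select, X_tr, n_max,
                               kernel = sp$kernel %||% "rbf", gamma = sp$gamma)
    S_tr <- apply_selector(sel, X_tr)
    S_te <- apply_selector(sel, X_te)
    get <- function(n) {
      list(tr = S_tr[, seq_len(n), drop = FALSE],
           te = S_te[, seq_len(n), drop = FALSE])
    }
    list(get = get, n_avail = sel$n_features)
  }
}

#' Cross-validate a pipeline on the calibration set
#'
#' Assigns the calibration rows to seeded folds; within each fold the
#' response-dependent pre-processor (DOSC) and the selector are fitted on
#' the training folds only and applied to the held-out fold, whose RMSE /
#' MAPE / RPD triple (RPD using that fold's sample SD) is recorded. For
#' rankers, projections and RFE the feature count minimizing the mean fold
#' RMSE over `1..min(30, fold size - 2)` is chosen; SPA and CARS pick their
#' subsets internally per fold. Reported metrics are means across folds.
#'
#' @param spec A [pipeline_spec()].
#' @param X_cal,y_cal Calibration spectra and response.
#' @param wavelengths Wavelength grid (nm).
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and stochastic selectors.
#' @param leaky If `TRUE`, fit the pre-processor and selector once on the
#'   whole calibration set before cross-validating the regression only
#'   (provided for comparison studies; default `FALSE`).
#' @return A list with `metrics` (one-row tibble `rmse_c`, `mape_c`,
#'   `rpd_c`), `n` (chosen feature count, `NA` for none/SPA/CARS), and
#'   `fold_id`.
#' @export
cv_evaluate <- function(spec, X_cal, y_cal, wavelengths, folds = 5,
                        seed = 0L, leaky = FALSE) {
  stopifnot(inherits(spec, "pipeline_spec"))
  X_cal <- check_matrix(X_cal, "X_cal")
  n_cal <- nrow(X_cal)
  if (n_cal < 2 * folds) abort("Calibration set too small for the fold count.")
  fold_id <- assign_folds(n_cal, folds, fanout_seed(seed, "cv_folds"))
  fam <- selector_family(spec$select)

  leaky_state <- NULL
  if (leaky) {
    pre <- preprocess_fit(spec$preprocess, X_cal, y_cal, wavelengths,
                          spec$preprocess_params)
    Xp <- pre$apply(X_cal)
    n_fixed <- if (is.numeric(spec$n)) spec$n else {
      min(30, ncol(Xp), n_cal - 2)
    }
    sel <- fit_selector_final(spec, Xp, y_cal, n_fixed,
                              fanout_seed(seed, "leaky_selector"))
    leaky_state <- list(Xf = if (is.null(sel)) Xp else apply_selector(sel, Xp),
                        n = if (fam %in% c("none")) NA_integer_ else
                          if (is.null(sel)) NA_integer_ else sel$n_features)
  }

  min_train <- n_cal - max(tabulate(fold_id, folds))
  per_fold <- vector("list", folds)

  if (leaky) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- ols_fit(leaky_state$Xf[tr, , drop = FALSE], y_cal[tr])
      pred <- ols_predict(fit, leaky_state$Xf[!tr, , drop = FALSE])
      per_fold[[f]] <- compute_metrics(y_cal[!tr], pred)
    }
    mm <- dplyr::bind_rows(per_fold)
    return(list(
      metrics = tibble::tibble(rmse_c = mean(mm$rmse), mape_c = mean(mm$mape),
                               rpd_c = mean(mm$rpd)),
      n = leaky_state$n, fold_id = fold_id
    ))
  }

  if (fam %in% c("none", "search")) {
    ns <- integer(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      pre <- preprocess_fit(spec$preprocess, X_cal[tr, , drop = FALSE],
                            y_cal[tr], wavelengths, spec$preprocess_params)
      X_tr <- pre$apply(X_cal[tr, , drop = FALSE])
      X_te <- pre$apply(X_cal[!tr, , drop = FALSE])
      sel <- fit_selector_final(spec, X_tr, y_cal[tr], NA,
                                fanout_seed(seed, paste0("fold", f)))
      F_tr <- if (is.null(sel)) X_tr else apply_selector(sel, X_tr)
      F_te <- if (is.null(sel)) X_te else apply_selector(sel, X_te)
      fit <- ols_fit(F_tr, y_cal[tr])
      pred <- ols_predict(fit, F_te)
      per_fold[[f]] <- compute_metrics(y_cal[!tr], pred)
      ns[f] <- if (is.null(sel)) NA_integer_ else sel$n_features
    }
    mm <- dplyr::bind_rows(per_fold)
    return(list(
      metrics = tibble::tibble(rmse_c = mean(mm$rmse), mape_c = mean(mm$mape),
                               rpd_c = mean(mm$rpd)),
      n = NA_integer_, fold_id = fold_id
    ))
  }

  # nested-n families: rankers, projections, rfe
  n_cap <- min(30, ncol(X_cal), min_train - 2)
  if (selector_family(spec$select) == "projection" &&
      spec$select == "kpca") {
    n_cap <- min(n_cap, min_train - 1)
  }
  candidates <- if (is.numeric(spec$n)) {
    if (spec$n > n_cap) abort(sprintf("Requested n = %d exceeds fold capacity %d.",
                                      spec$n, n_cap))
    as.integer(spec$n)
  } else {
    seq_len(n_cap)
  }

  rmse_fn <- mape_fn <- rpd_fn <- matrix(NA_real_, folds, length(candidates))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    pre <- preprocess_fit(spec$preprocess, X_cal[tr, , drop = FALSE],
                          y_cal[tr], wavelengths, spec$preprocess_params)
    X_tr <- pre$apply(X_cal[tr, , drop = FALSE])
    X_te <- pre$apply(X_cal[!tr, , drop = FALSE])
    feats <- nested_features(spec, X_tr, y_cal[tr], X_te, max(candidates),
                             fanout_seed(seed, paste0("fold", f)))
    for (j in seq_along(candidates)) {
      if (candidates[j] > feats$n_avail) next
      Fs <- feats$get(candidates[j])
      fit <- ols_fit(Fs$tr, y_cal[tr])
      m <- compute_metrics(y_cal[!tr], ols_predict(fit, Fs$te))
      rmse_fn[f, j] <- m$rmse
      mape_fn[f, j] <- m$mape
      rpd_fn[f, j] <- m$rpd
    }
  }
  # candidates unavailable in some fold are excluded from the search
  mean_rmse <- colMeans(rmse_fn)
  if (all(is.na(mean_rmse))) abort("No feature count evaluable in every fold.")
  j_best <- which.min(mean_rmse) # ties resolve to the smaller n
  list(
    metrics = tibble::tibble(rmse_c = mean_rmse[j_best],
                             mape_c = mean(mape_fn[, j_best]),
                             rpd_c = mean(rpd_fn[, j_best])),
    n = candidates[j_best], fold_id = fold_id
  )
}

# Fit the full pipeline on training rows; returns a predictor closure.
# `n` must already be resolved for nested-n families.
fit_pipeline <- function(spec, X_tr, y_tr, wavelengths, n, seed) {
  pre <- preprocess_fit(spec$preprocess, X_tr, y_tr, wavelengths,
                        spec$preprocess_params)
  Xp <- pre$apply(X_tr)
  sel <- fit_selector_final(spec, Xp, y_tr, n, seed)
  Ftr <- if (is.null(sel)) Xp else apply_selector(sel, Xp)
  fit <- ols_fit(Ftr, y_tr)
  list(
    predict = function(X_new) {
      Xn <- pre$apply(check_matrix(X_new))
      Fn <- if (is.null(sel)) Xn else apply_selector(sel, Xn)
      ols_predict(fit, Fn)
    },
    selector = sel, ols = fit,
    n_used = if (is.null(sel)) NA_integer_ else sel$n_features
  )
}

#' Evaluate a pipeline against a calibration/prediction split
#'
#' Produces the six-metric result row of one experiment-grid cell: the
#' cross-validated calibration triple (`rmse_c`, `mape_c`, `rpd_c`) from
#' [cv_evaluate()] and the single-shot prediction triple (`rmse_p`,
#' `mape_p`, `rpd_p`) from a full-calibration fit applied to the held-out
#' prediction set. Any numerical failure is captured: the row comes back
#' with `failed = TRUE`, `NA` metrics and a reason instead of an error.
#'
#' @param data A `spectral_dataset` tibble.
#' @param spec A [pipeline_spec()].
#' @param split An [spxy_split()] of the dataset.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for folds and stochastic selectors.
#' @param leaky Passed to [cv_evaluate()].
#' @return A one-row tibble: `preprocess`, `select`, `n`, `rmse_c`,
#'   `mape_c`, `rpd_c`, `rmse_p`, `mape_p`, `rpd_p`, `failed`, `reason`.
#' @export
#' @examples
#' ds <- generate_spectra(generator_config(n_samples = 40, seed = 2))
#' sp <- spxy_split(ds)
#' evaluate_pipeline(ds, pipeline_spec("none", "f_test"), sp, seed = 1)
evaluate_pipeline <- function(data, spec, split, folds = 5, seed = 0L,
                              leaky = FALSE) {
  stopifnot(inherits(spec, "pipeline_spec"), inherits(split, "spxy_split"))
  X <- spectra_matrix(data)
  y <- spectra_ssc(data)
  wl <- spectra_wavelengths(data)
  row_shell <- tibble::tibble(
    preprocess = spec$preprocess, select = spec$select, n = NA_integer_,
    rmse_c = NA_real_, mape_c = NA_real_, rpd_c = NA_real_,
    rmse_p = NA_real_, mape_p = NA_real_, rpd_p = NA_real_,
    failed = TRUE, reason = NA_character_
  )
  out <- tryCatch({
    X_cal <- X[split$cal_idx, , drop = FALSE]
    y_cal <- y[split$cal_idx]
    X_pred <- X[split$pred_idx, , drop = FALSE]
    y_pred <- y[split$pred_idx]

    cv <- cv_evaluate(spec, X_cal, y_cal, wl, folds = folds, seed = seed,
                      leaky = leaky)
    fam <- selector_family(spec$select)
    n_final <- if (fam %in% c("ranker", "projection", "rfe")) cv$n else NA
    fit <- fit_pipeline(spec, X_cal, y_cal, wl, n_final,
                        fanout_seed(seed, "final_fit"))
    pred <- fit$predict(X_pred)
    if (!all(is.finite(pred))) abort("Non-finite prediction-set predictions.")
    mp <- compute_metrics(y_pred, pred)

    n_rep <- if (fam %in% c("ranker", "projection", "rfe")) {
      as.integer(cv$n)
    } else if (fam == "search") {
      fit$n_used
    } else {
      NA_integer_
    }
    tibble::tibble(
      preprocess = spec$preprocess, select = spec$select, n = n_rep,
      rmse_c = cv$metrics$rmse_c, mape_c = cv$metrics$mape_c,
      rpd_c = cv$metrics$rpd_c,
      rmse_p = mp$rmse, mape_p = mp$mape, rpd_p = mp$rpd,
      failed = FALSE, reason = NA_character_
    )
  }, error = function(e) {
    row_shell$reason <- conditionMessage(e)
    row_shell
  })
  out
}
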