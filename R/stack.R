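# Two-base stacked generalization: base pipelines are trained on the
# calibration set; their out-of-fold predictions (shared seeded fold
# partition) form the meta-features of an OLS meta-model, which avoids the
# refitting bias of training the meta-model on in-fold predictions. The
# default bases pair the detrend+CARS pipeline (strong calibration fit)
# with the Savitzky-Golay+CARS pipeline (strong generalization).

#' Default base pipelines for stacking
#'
#' @return A named list of two [pipeline_spec()]s: `dc_cars` and `sg_cars`.
#' @export
default_stack_bases <- function() {
  list(dc_cars = pipeline_spec("dc", "cars"),
       sg_cars = pipeline_spec("sg", "cars"))
}

#' Fit a stacked generalization model
#'
#' For each base pipeline, out-of-fold predictions on every calibration row
#' are produced under one shared seeded fold partition; the OLS meta-model
#' is fitted on the resulting n_cal x 2 prediction matrix against the
#' calibration response (minimum-norm, so identical bases do not break it);
#' the base pipelines are then refitted on the full calibration set.
#'
#' @param data A `spectral_dataset` tibble.
#' @param split An [spxy_split()]; bases only ever see calibration rows.
#' @param base_specs List of two (or more) [pipeline_spec()]s; default
#'   [default_stack_bases()].
#' @param folds Out-of-fold partition size (default 5).
#' @param seed Seed shared by the fold partition and the bases.
#' @return A list of class `stack_model` with `base_specs`, `base_fits`,
#'   `meta` (an `ols_model`), `oof` (the meta training matrix) and
#'   `fold_id`.
#' @export
stack_fit <- function(data, split, base_specs = default_stack_bases(),
                      folds = 5, seed = 0L) {
  stopifnot(inherits(split, "spxy_split"))
  if (length(base_specs) < 2) abort("Stacking needs at least 2 base pipelines.")
  base_names <- names(base_specs) %||% paste0("base", seq_along(base_specs))
  X <- spectra_matrix(data)
  y <- spectra_ssc(data)
  wl <- spectra_wavelengths(data)
  X_cal <- X[split$cal_idx, , drop = FALSE]
  y_cal <- y[split$cal_idx]
  n_cal <- length(y_cal)
  fold_id <- assign_folds(n_cal, folds, fanout_seed(seed, "stack_folds"))

  oof <- matrix(NA_real_, n_cal, length(base_specs),
                dimnames = list(NULL, base_names))
  for (b in seq_along(base_specs)) {
    spec <- base_specs[[b]]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- tryCatch(
        fit_base(spec, X_cal[tr, , drop = FALSE], y_cal[tr], wl,
                 fanout_seed(seed, paste(base_names[b], "fold", f))),
        error = function(e) {
          abort(sprintf("Base '%s' failed on fold %d: %s",
                        base_names[b], f, conditionMessage(e)))
        }
      )
      oof[!tr, b] <- fit$predict(X_cal[!tr, , drop = FALSE])
    }
  }
  if (!all(is.finite(oof))) abort("Non-finite out-of-fold base predictions.")
  meta <- ols_fit(oof, y_cal)

  base_fits <- lapply(seq_along(base_specs), function(b) {
    fit_base(base_specs[[b]], X_cal, y_cal, wl,
             fanout_seed(seed, paste(base_names[b], "full")))
  })
  names(base_fits) <- base_names

  structure(
    list(base_specs = base_specs, base_fits = base_fits, meta = meta,
         oof = oof, fold_id = fold_id, seed = seed),
    class = "stack_model"
  )
}

# Fit one base pipeline on training rows, resolving a "cv" n policy by an
# internal cross-validation on those rows.
fit_base <- function(spec, X_tr, y_tr, wl, seed) {
  fam <- selector_family(spec$select)
  n_final <- NA
  if (fam %in% c("ranker", "projection", "rfe")) {
    n_final <- if (is.numeric(spec$n)) spec$n else {
      cv_evaluate(spec, X_tr, y_tr, wl, seed = seed)$n
    }
  }
  fit_pipeline(spec, X_tr, y_tr, wl, n_final, seed)
}

#' Predict from a stacked model
#'
#' Each refitted base produces predictions for the new spectra; the OLS
#' meta-model combines them.
#'
#' @param model A `stack_model`.
#' @param X_new m x p matrix (or `spectral_dataset`) with the calibration
#'   wavelength count.
#' @return Length-m numeric vector of predicted SSC.
#' @export
stack_predict <- function(model, X_new) {
  stopifnot(inherits(model, "stack_model"))
  if (!is.matrix(X_new)) X_new <- spectra_matrix(X_new)
  base_pred <- vapply(model$base_fits, function(f) f$predict(X_new),
                      numeric(nrow(X_new)))
  base_pred <- matrix(base_pred, nrow = nrow(X_new))
  ols_predict(model$meta, base_pred)
}

#' @export
print.stack_model <- function(x, ...) {
  cat(sprintf("<stack_model: %d bases (%s) + ols meta>\n",
              length(x$base_fits), paste(names(x$base_fits), collapse = ", ")))
  invisible(x)
}

#' Evaluate base pipelines and their stack side by side
#'
#' Returns one result row per base pipeline (via [evaluate_pipeline()])
#' plus a row for the stacked model. The stack's prediction triple comes
#' from the fitted stack applied to the prediction set; its calibration
#' triple is computed by an outer cross-validation around the whole
#' stacking procedure (each outer fold refits both bases and the
#' meta-model without the held-out rows), which is the honest analogue of
#' the per-pipeline cross-validated triple. Set
#' `calibration = "none"` to skip the outer CV and report `NA`s there.
#'
#' @inheritParams stack_fit
#' @param calibration `"outer_cv"` (default) or `"none"`.
#' @return A tibble shaped like a `result_table` with a `model` column,
#'   and the fitted `stack_model` in the `stack` attribute.
#' @export
stack_evaluate <- function(data, split, base_specs = default_stack_bases(),
                           folds = 5, seed = 0L,
                           calibration = c("outer_cv", "none")) {
  calibration <- match.arg(calibration)
  base_names <- names(base_specs) %||% paste0("base", seq_along(base_specs))
  X <- spectra_matrix(data)
  y <- spectra_ssc(data)
  y_pred_true <- y[split$pred_idx]

  base_rows <- purrr::imap(
    setNames(base_specs, base_names),
    function(spec, nm) {
      row <- evaluate_pipeline(data, spec, split, folds = folds,
                               seed = fanout_seed(seed, nm))
      dplyr::bind_cols(tibble::tibble(model = nm), row)
    }
  )

  model <- stack_fit(data, split, base_specs, folds = folds, seed = seed)
  pred <- stack_predict(model, X[split$pred_idx, , drop = FALSE])
  mp <- compute_metrics(y_pred_true, pred)

  cal_triple <- tibble::tibble(rmse_c = NA_real_, mape_c = NA_real_,
                               rpd_c = NA_real_)
  if (calibration == "outer_cv") {
    X_cal <- X[split$cal_idx, , drop = FALSE]
    y_cal <- y[split$cal_idx]
    wl <- spectra_wavelengths(data)
    outer_id <- assign_folds(length(y_cal), folds,
                             fanout_seed(seed, "stack_outer"))
    triples <- purrr::map(seq_len(folds), function(f) {
      tr <- outer_id != f
      sub <- new_spectral_dataset(
        sample_ids = data$sample_id[split$cal_idx][tr],
        wavelengths = wl, reflectance = X_cal[tr, , drop = FALSE],
        ssc = y_cal[tr]
      )
      inner_split <- structure(
        list(cal_idx = seq_len(sum(tr)), pred_idx = integer(0)),
        class = "spxy_split"
      )
      m <- stack_fit(sub, inner_split, base_specs, folds = folds,
                     seed = fanout_seed(seed, paste0("stack_outer", f)))
      compute_metrics(y_cal[!tr],
                      stack_predict(m, X_cal[!tr, , drop = FALSE]))
    })
    mm <- dplyr::bind_rows(triples)
    cal_triple <- tibble::tibble(rmse_c = mean(mm$rmse),
                                 mape_c = mean(mm$mape),
                                 rpd_c = mean(mm$rpd))
  }

  stack_row <- dplyr::bind_cols(
    tibble::tibble(model = "stack", preprocess = NA_character_,
                   select = NA_character_, n = NA_integer_),
    cal_triple,
    tibble::tibble(rmse_p = mp$rmse, mape_p = mp$mape, rpd_p = mp$rpd,
                   failed = FALSE, reason = NA_character_)
  )
  out <- dplyr::bind_rows(c(base_rows, list(stack_row)))
  attr(out, "stack") <- model
  out
}
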