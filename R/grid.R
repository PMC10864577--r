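# The orthogonal experiment: every pre-processor crossed with every
# selector (5 x 10 = 50 pipelines, each option set including "none"),
# all evaluated against one shared SPXY split and fold seed, then tallied
# into a best-frequency table (one best selection method per metric within
# each pre-processing group).

grid_metrics <- function() {
  c("rmse_c", "mape_c", "rpd_c", "rmse_p", "mape_p", "rpd_p")
}

#' Run the pre-processor-by-selector experiment grid
#'
#' Performs one SPXY split of the dataset, then evaluates every
#' (pre-processor, selector) pipeline against that same split with a
#' shared cross-validation fold seed. The master seed fans out to
#' per-pipeline seeds by stable name hashing, so results are reproducible
#' and adding a method never perturbs the others.
#'
#' @param data A `spectral_dataset` tibble.
#' @param preprocess,select Character vectors of methods to cross
#'   (defaults: all five pre-processors, all ten selection options).
#' @param ratio SPXY split ratio (default `"3:1"`).
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed.
#' @param select_params,preprocess_params Named lists of per-method option
#'   lists, e.g. `select_params = list(cars = list(runs = 50))`.
#' @return A tibble of class `result_table` with one row per grid cell
#'   (columns as in [evaluate_pipeline()]); the split, seed and dataset
#'   fingerprint are attached as attributes.
#' @export
run_grid <- function(data,
                     preprocess = preprocess_methods(),
                     select = selector_methods(),
                     ratio = "3:1", folds = 5, seed = 0L,
                     select_params = list(), preprocess_params = list()) {
  preprocess <- match.arg(preprocess, preprocess_methods(), several.ok = TRUE)
  select <- match.arg(select, selector_methods(), several.ok = TRUE)
  split <- spxy_split(data, ratio)
  cells <- tidyr::expand_grid(preprocess = preprocess, select = select)
  rows <- purrr::pmap(cells, function(preprocess, select) {
    spec <- pipeline_spec(
      preprocess, select,
      preprocess_params = preprocess_params[[preprocess]] %||% list(),
      select_params = select_params[[select]] %||% list()
    )
    evaluate_pipeline(data, spec, split, folds = folds,
                      seed = fanout_seed(seed, paste(preprocess, select)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "split") <- split
  attr(out, "seed") <- as.integer(seed)
  attr(out, "dataset_fingerprint") <- dataset_fingerprint(data)
  class(out) <- c("result_table", class(out))
  out
}

# Cheap content fingerprint for provenance metadata (sum-based, not
# cryptographic).
dataset_fingerprint <- function(data) {
  m <- spectra_matrix(data)
  sprintf("%dx%d/%.10g/%.10g", nrow(m), ncol(m), sum(m), sum(spectra_ssc(data)))
}

#' Best-frequency tally of a result table
#'
#' Within each pre-processing group and for each of the six metrics
#' (`rmse_c`, `mape_c`, `rpd_c` lower/lower/higher-is-better, and the
#' prediction-set triple likewise), the best selection method receives one
#' count. Metric values are compared at full floating precision; exact ties
#' are broken by the canonical method order (none, pca, kpca, svd, f_test,
#' ppmcc, mi, rfe, spa, cars) with a warning. Failed (`NA`) rows never win;
#' a group with no successful row gets a zero row with a warning. On a
#' complete tie-free grid every group row sums to 6 and the grand total is
#' 30.
#'
#' @param table A `result_table` from [run_grid()] (or any tibble with the
#'   same columns).
#' @return A tibble of class `frequency_tally`: one row per pre-processing
#'   group, one count column per selection method, plus `sum`. Column sums
#'   are attached as the `column_sums` attribute.
#' @export
best_frequency <- function(table) {
  methods <- selector_methods()
  methods <- methods[methods %in% unique(table$select)]
  groups <- unique(table$preprocess)
  higher_better <- c(rmse_c = FALSE, mape_c = FALSE, rpd_c = TRUE,
                     rmse_p = FALSE, mape_p = FALSE, rpd_p = TRUE)

  counts <- matrix(0L, length(groups), length(methods),
                   dimnames = list(groups, methods))
  for (g in groups) {
    sub <- table[table$preprocess == g & !table$failed, , drop = FALSE]
    if (nrow(sub) == 0) {
      warn(sprintf("All pipelines failed in group '%s'; zero tally row.", g))
      next
    }
    for (metric in grid_metrics()) {
      v <- sub[[metric]]
      best_val <- if (higher_better[metric]) max(v) else min(v)
      winners <- sub$select[v == best_val]
      if (length(winners) > 1) {
        warn(sprintf("Tie on %s in group '%s' between: %s.", metric, g,
                     paste(winners, collapse = ", ")))
      }
      win <- methods[methods %in% winners][1] # canonical-order tie-break
      counts[g, win] <- counts[g, win] + 1L
    }
  }
  out <- tibble::as_tibble(as.data.frame(counts), rownames = "preprocess")
  out$sum <- as.integer(rowSums(counts))
  attr(out, "column_sums") <- setNames(as.integer(colSums(counts)),
                                       colnames(counts))
  class(out) <- c("frequency_tally", class(out))
  out
}

#' Which selectors beat the no-selection baseline?
#'
#' Mirrors the reporting convention of flagging results against the
#' baseline without any selection: within each pre-processing group, a
#' selector "helps" when it beats the (same group, no-selection) row on
#' both the calibration and prediction RMSE.
#'
#' @param table A `result_table` containing `select == "none"` rows.
#' @return A tibble with `preprocess`, `select` and logical `helps`.
#' @export
selection_helps <- function(table) {
  base <- table[table$select == "none",
                c("preprocess", "rmse_c", "rmse_p")]
  names(base) <- c("preprocess", "base_rmse_c", "base_rmse_p")
  out <- dplyr::left_join(
    table[table$select != "none", , drop = FALSE], base, by = "preprocess"
  )
  dplyr::transmute(
    out, .data$preprocess, .data$select,
    helps = !.data$failed & !is.na(.data$base_rmse_c) &
      .data$rmse_c < .data$base_rmse_c & .data$rmse_p < .data$base_rmse_p
  )
}
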