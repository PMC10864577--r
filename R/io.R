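# File interfaces: wide-format spectra CSV (sample_id, ssc, one column per
# wavelength in nm), a ground-truth sidecar JSON for synthetic data,
# result-table CSV/JSON emission, and JSON/YAML run configurations.

#' Write / read a spectral dataset as wide CSV
#'
#' The header is `sample_id,ssc,<wl1>,<wl2>,...` with wavelengths in nm as
#' column names; the round trip is lossless to full double precision. When
#' the dataset carries planted-band ground truth and `truth_path` is given,
#' a sidecar JSON (informative band centers, nearest grid indices, seed and
#' config echo) is written alongside.
#'
#' @param data A `spectral_dataset` tibble.
#' @param path Output CSV path.
#' @param truth_path Optional path for the ground-truth sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(data, path, truth_path = NULL) {
  df <- as.data.frame(data)
  readr::write_csv(df, path)
  truth <- spectra_truth(data)
  if (!is.null(truth_path)) {
    if (is.null(truth)) abort("Dataset carries no ground truth to write.")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param truth_path For the reader: optional sidecar JSON to re-attach as
#'   the `truth` attribute.
#' @export
read_spectra_csv <- function(path, truth_path = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "ssc") %in% names(df))) {
    abort("Spectra CSV must have `sample_id` and `ssc` columns.")
  }
  if (anyDuplicated(df$sample_id)) abort("Duplicated sample ids in spectra CSV.")
  wl_cols <- setdiff(names(df), c("sample_id", "ssc"))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) abort("Wavelength columns must be numeric nm values.")
  if (any(diff(wl) <= 0)) {
    abort("Wavelength columns must be in strictly ascending order.")
  }
  truth <- if (!is.null(truth_path)) jsonlite::read_json(truth_path,
                                                         simplifyVector = TRUE)
  new_spectral_dataset(
    sample_ids = as.character(df$sample_id), wavelengths = wl,
    reflectance = as.matrix(df[wl_cols]), ssc = df$ssc, truth = truth
  )
}

#' Write / read an experiment result table
#'
#' `write_results()` emits `results.csv` (one row per grid cell) and
#' `results.json` (the same rows plus run metadata: master seed, split
#' indices and dataset fingerprint) into `dir`. `read_results()` restores
#' the table from either file.
#'
#' @param table A `result_table` from [run_grid()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_results <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(as.data.frame(table), file.path(dir, "results.csv"))
  meta <- list(
    seed = attr(table, "seed"),
    dataset_fingerprint = attr(table, "dataset_fingerprint"),
    split = {
      s <- attr(table, "split")
      if (!is.null(s)) list(cal_idx = s$cal_idx, pred_idx = s$pred_idx)
    }
  )
  jsonlite::write_json(
    list(rows = as.data.frame(table), metadata = meta),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_results
#' @export
read_results <- function(dir) {
  path <- file.path(dir, "results.csv")
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           preprocess = "c", select = "c", n = "i",
                           failed = "l", reason = "c", .default = "d"
                         ))
  json_path <- file.path(dir, "results.json")
  if (file.exists(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)$metadata
    attr(out, "seed") <- meta$seed
    attr(out, "dataset_fingerprint") <- meta$dataset_fingerprint
    if (!is.null(meta$split)) {
      attr(out, "split") <- structure(
        list(cal_idx = meta$split$cal_idx, pred_idx = meta$split$pred_idx),
        class = "spxy_split"
      )
    }
  }
  class(out) <- c("result_table", class(out))
  out
}

#' Read a run configuration from JSON or YAML
#'
#' Configuration keys mirror the function arguments, grouped per stage,
#' e.g. `preprocess.method`, `preprocess.sg.window`, `select.method`,
#' `select.n`, `select.cars.runs`, `split.ratio`, `cv.folds`, `cv.seed`,
#' `stack.bases`.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A nested named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("Config must be a .json, .yaml or .yml file.")
  }
}

#' Build a pipeline spec from a configuration list
#'
#' @param config A list as returned by [read_run_config()], with at least
#'   `preprocess$method` and `select$method`.
#' @return A [pipeline_spec()].
#' @export
pipeline_from_config <- function(config) {
  pre <- config$preprocess %||% list(method = "none")
  sel <- config$select %||% list(method = "none")
  pre_method <- pre$method %||% "none"
  sel_method <- sel$method %||% "none"
  pipeline_spec(
    preprocess = pre_method,
    select = sel_method,
    n = sel$n %||% "cv",
    preprocess_params = pre[[pre_method]] %||% list(),
    select_params = sel[[sel_method]] %||% list()
  )
}
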