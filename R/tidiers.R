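# broom-style tidiers for the package's fitted objects.

#' Tidy an OLS model
#'
#' @param x An `ols_model`.
#' @param ... Unused.
#' @return A tibble with one row per term (`"(Intercept)"` first).
#' @export
tidy.ols_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)",
             if (length(x$coefficients)) paste0("f", seq_along(x$coefficients))),
    estimate = c(x$intercept, x$coefficients)
  )
}

#' @rdname tidy.ols_model
#' @export
glance.ols_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$coefficients))
}

#' Tidy a fitted selector
#'
#' For index-based selectors, one row per kept wavelength index (with its
#' score where the method produces one); for projections, one row per
#' component.
#'
#' @param x A `spectral_selector`.
#' @param wavelengths Optional wavelength grid to translate indices to nm.
#' @param ... Unused.
#' @export
tidy.spectral_selector <- function(x, wavelengths = NULL, ...) {
  idx <- selector_indices(x)
  if (is.null(idx)) {
    return(tibble::tibble(component = seq_len(x$n_features),
                          method = x$method))
  }
  out <- tibble::tibble(index = idx, method = x$method)
  if (!is.null(x$state$scores)) out$score <- x$state$scores[idx]
  if (!is.null(wavelengths)) out$wavelength <- wavelengths[idx]
  out
}

#' @rdname tidy.ols_model
#' @export
glance.spectral_selector <- function(x, ...) {
  tibble::tibble(method = x$method, n_features = x$n_features,
                 p = x$p)
}

#' Tidy a stacked model
#'
#' @param x A `stack_model`.
#' @param ... Unused.
#' @return Meta-model terms: intercept plus one weight per base pipeline.
#' @export
tidy.stack_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$base_fits)),
    estimate = c(x$meta$intercept, x$meta$coefficients)
  )
}

#' @rdname tidy.stack_model
#' @export
glance.stack_model <- function(x, ...) {
  tibble::tibble(n_bases = length(x$base_fits),
                 n_cal = nrow(x$oof), seed = x$seed)
}

#' Long-format view of a frequency tally
#'
#' @param x A `frequency_tally`.
#' @param ... Unused.
#' @return A tibble with `preprocess`, `select` and `count`.
#' @export
tidy.frequency_tally <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), -dplyr::any_of("sum")),
    -"preprocess", names_to = "select", values_to = "count"
  )
}
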