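#' Filter time estimates exceeding three times the target
#'
#' Excludes possible resting periods: only estimates strictly less than
#' three times the target interval are retained, in order. The number
#' removed is stored in the `n_removed` attribute.
#'
#' @param series A [time_estimate_series()].
#' @return A filtered [time_estimate_series()] (possibly empty) with
#'   attribute `n_removed`.
#' @export
filter_time_estimates <- function(series) {
  stopifnot(inherits(series, "time_estimate_series"))
  keep <- series$estimates < 3 * series$target
  out <- structure(list(estimates = series$estimates[keep],
                        target = series$target),
                   class = "time_estimate_series")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Absolute successive changes of a series
#'
#' The n-1 absolute first differences `|x_{i+1} - x_i|`, the quantity
#' whose distribution is tested for heavy tails in the time-estimation
#' task.
#'
#' @param x Numeric series of length at least 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
successive_changes <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values to form successive changes")
  abs(diff(x))
}

#' Classify a series as 1/f noise and/or heavy-tailed
#'
#' Applies the classification ranges used throughout: spectral exponents
#' `alpha` in `[0.5, 1.5]` count as 1/f scaling, and tail exponents `mu`
#' in `(1, 3]` count as heavy tails. Both boundaries follow the interval
#' notation literally (closed on alpha; half-open on mu).
#'
#' @param alpha Spectral exponent estimate.
#' @param mu Tail exponent estimate.
#' @return An object of class `"noise_classification"`: list with
#'   `is_one_over_f`, `is_heavy_tailed`, `alpha`, `mu`.
#' @export
classify_noise <- function(alpha, mu) {
  stopifnot(is.finite(alpha), is.finite(mu))
  structure(list(is_one_over_f = alpha >= 0.5 && alpha <= 1.5,
                 is_heavy_tailed = mu > 1 && mu <= 3,
                 alpha = alpha, mu = mu),
            class = "noise_classification")
}

#' @export
print.noise_classification <- function(x, ...) {
  cat(sprintf("alpha = %.3f -> 1/f: %s;  mu = %.3f -> heavy-tailed: %s\n",
              x$alpha, if (x$is_one_over_f) "yes" else "no",
              x$mu, if (x$is_heavy_tailed) "yes" else "no"))
  invisible(x)
}

#' Full noise analysis of a behavioral series
#'
#' Composes the analysis pipeline for one participant series. For time
#' estimation: apply the three-times-target filter, fit alpha on the
#' estimate sequence and mu on the absolute successive changes. For
#' animal naming: fit alpha on the IRI sequence (indexed by response
#' number) and mu on the raw IRIs; `tail_on = "changes"` switches the mu
#' fit to absolute successive changes instead.
#'
#' @param series A [time_estimate_series()] or [iri_series()].
#' @param tail_on For IRI series, fit the tail on `"raw"` IRIs (default,
#'   matching the histograms the readout model is compared against) or
#'   on absolute successive `"changes"`.
#' @param f_max,n_bins Passed to [fit_spectral_exponent()].
#' @param window_len,overlap Passed to [power_spectrum()].
#' @param compare_tails If `TRUE`, also run [tail_model_comparison()] at
#'   the fitted `xmin`.
#' @return An object of class `"noise_analysis"`: list with
#'   `spectral_fit`, `tail_fit`, `classification`, optional
#'   `tail_comparison`, and `n_removed` (timing filter count).
#' @examples
#' x <- gen_fgn(1024, alpha = 1, seed = 1)
#' a <- analyze_series(time_estimate_series(exp(0.05 * x), target = 1))
#' a$classification
#' @export
analyze_series <- function(series, tail_on = c("raw", "changes"),
                           f_max = 0.1, n_bins = 12L,
                           window_len = NULL, overlap = 0.5,
                           compare_tails = FALSE) {
  tail_on <- match.arg(tail_on)
  n_removed <- 0L
  if (inherits(series, "time_estimate_series")) {
    series <- filter_time_estimates(series)
    n_removed <- attr(series, "n_removed")
    values <- series$estimates
    tail_values <- if (length(values) >= 2L) successive_changes(values) else numeric(0)
  } else if (inherits(series, "iri_series")) {
    values <- series$iris
    tail_values <- if (tail_on == "raw") values
                   else if (length(values) >= 2L) successive_changes(values)
                   else numeric(0)
  } else stop("`series` must be a time_estimate_series or iri_series")
  if (length(values) < 2L) stop("series too short to analyze")
  spec <- power_spectrum(values, window_len = window_len, overlap = overlap)
  sfit <- fit_spectral_exponent(spec, f_max = f_max, n_bins = n_bins)
  tfit <- fit_tail_exponent(tail_values[tail_values > 0])
  out <- list(spectral_fit = sfit, tail_fit = tfit,
              classification = classify_noise(sfit$alpha, tfit$mu),
              n_removed = n_removed)
  if (compare_tails)
    out$tail_comparison <- tail_model_comparison(tail_values[tail_values > 0],
                                                 tfit$xmin)
  structure(out, class = "noise_analysis")
}

#' @export
print.noise_analysis <- function(x, ...) {
  print(x$spectral_fit)
  print(x$tail_fit)
  print(x$classification)
  if (!is.null(x$tail_comparison))
    cat(sprintf("Power-law vs exponential tail: lr_stat = %.3f, p = %.3g\n",
                x$tail_comparison$lr_stat, x$tail_comparison$lr_p))
  if (x$n_removed > 0)
    cat(sprintf("(%d estimate(s) removed by the 3x-target filter)\n",
                x$n_removed))
  invisible(x)
}
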