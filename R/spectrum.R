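#' Welch-style averaged power spectrum
#'
#' Splits the series into overlapping windows, removes each window's
#' mean, and averages the per-window periodograms. No taper is applied.
#' Frequencies are in cycles per sample; power is normalized so that the
#' one-sided spectrum sums to (approximately) the series variance.
#'
#' @param series Numeric series, length at least `window_len`.
#' @param window_len Window length; default `min(512, floor(n/2))`, at
#'   least 16.
#' @param overlap Fractional window overlap in `[0, 1)`.
#' @return An object of class `"power_spectrum"`: list with `freqs`
#'   (strictly increasing, `0 < f <= 0.5`), `power` and `n_windows`.
#' @export
power_spectrum <- function(series, window_len = NULL, overlap = 0.5) {
  series <- as.numeric(series)
  n <- length(series)
  if (is.null(window_len)) window_len <- max(16L, min(512L, floor(n / 2)))
  window_len <- as.integer(window_len)
  if (window_len < 16L) stop("`window_len` must be at least 16")
  if (n < window_len) stop("series is shorter than one window")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, n - window_len + 1L, by = step)
  L <- window_len
  half <- L %/% 2
  acc <- numeric(half)
  for (s in starts) {
    w <- series[s:(s + L - 1L)]
    w <- w - mean(w)
    X <- fft(w)
    p <- Mod(X[2:(half + 1L)])^2 / L^2
    # one-sided: double every bin except the Nyquist bin of an even window
    p <- 2 * p
    if (L %% 2L == 0L) p[half] <- p[half] / 2
    acc <- acc + p
  }
  structure(list(freqs = (1:half) / L, power = acc / length(starts),
                 n_windows = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d frequencies, %d window(s) averaged\n",
              length(x$freqs), x$n_windows))
  invisible(x)
}

#' Estimate the spectral exponent alpha of 1/f scaling
#'
#' Fits the scaling law `S(f) ~ 1/f^alpha` by ordinary least squares of
#' log-binned log10 power on log10 frequency, restricted to low
#' frequencies `f < f_max` (default 0.1). Power is averaged in
#' logarithmically spaced frequency bins before the line fit; empty bins
#' are dropped.
#'
#' @param spectrum A [power_spectrum()].
#' @param f_max High-frequency cutoff of the fit, cycles/sample.
#' @param n_bins Number of logarithmic bins between the lowest
#'   resolvable frequency and `f_max`.
#' @return An object of class `"spectral_fit"`: list with `alpha`
#'   (estimated exponent, `-slope`), `intercept`, `f_max`, `n_bins`
#'   (nonempty bins used, at least 3) and `r_squared`.
#' @export
fit_spectral_exponent <- function(spectrum, f_max = 0.1, n_bins = 12L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$freqs < f_max & spectrum$power > 0
  f <- spectrum$freqs[keep]
  p <- spectrum$power[keep]
  if (length(f) < 3L) stop("too few positive-power frequencies below `f_max`")
  edges <- 10^seq(log10(min(f)) - 1e-9, log10(f_max), length.out = n_bins + 1L)
  bin <- cut(f, edges, labels = FALSE, include.lowest = TRUE)
  lf <- tapply(log10(f), bin, mean)
  lp <- tapply(log10(p), bin, mean)
  ok <- is.finite(lf) & is.finite(lp)
  lf <- lf[ok]; lp <- lp[ok]
  if (length(lf) < 3L) stop("fewer than 3 nonempty log-frequency bins below `f_max`")
  lf <- as.numeric(lf); lp <- as.numeric(lp)
  slope <- sum((lf - mean(lf)) * (lp - mean(lp))) / sum((lf - mean(lf))^2)
  intercept <- mean(lp) - slope * mean(lf)
  r2 <- if (sd(lp) == 0) 1 else cor(lf, lp)^2
  structure(list(alpha = -slope, intercept = intercept,
                 f_max = f_max, n_bins = length(lf),
                 r_squared = r2),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit: alpha = %.3f (f < %g, %d bins, R^2 = %.3f)\n",
              x$alpha, x$f_max, x$n_bins, x$r_squared))
  invisible(x)
}
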