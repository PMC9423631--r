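#' Fit a power-law tail exponent mu
#'
#' Fits `P(l) ~ l^-mu` to the upper tail of a positive sample by
#' continuous maximum likelihood, `mu = 1 + n_tail / sum(log(x/xmin))`,
#' with the lower cutoff `xmin` chosen to minimize the Kolmogorov-Smirnov
#' distance between the empirical tail and the fitted power law.
#' Candidate cutoffs are the unique data values, thinned to a quantile
#' grid of at most `max_candidates`; candidates leaving fewer than
#' `min_tail` points are skipped.
#'
#' @param values Positive numeric sample, at least `min_tail` values.
#' @param min_tail Minimum tail size for a reported fit.
#' @param max_candidates Cap on the number of xmin candidates.
#' @return An object of class `"tail_fit"`: list with `mu`, `xmin`,
#'   `n_tail`, `ks` (minimized KS distance) and `proper` (`TRUE` when
#'   `mu > 1`, i.e. the fitted tail is normalizable).
#' @export
fit_tail_exponent <- function(values, min_tail = 10L, max_candidates = 200L) {
  x <- as.numeric(values)
  x <- x[is.finite(x)]
  if (any(x <= 0)) stop("tail fitting requires strictly positive values")
  n <- length(x)
  if (n < min_tail) stop("need at least ", min_tail, " positive values")
  x <- sort(x)
  cand <- unique(x[seq_len(n - min_tail + 1L)])
  if (length(cand) < 1L)
    stop("no candidate xmin leaves at least ", min_tail, " tail points")
  if (length(cand) > max_candidates)
    cand <- unique(quantile(cand, probs = seq(0, 1, length.out = max_candidates),
                            names = FALSE, type = 1))
  best <- cpp_tail_fit(x, cand, as.integer(min_tail))
  if (!is.finite(best$ks))
    stop("no candidate xmin admits a power-law fit with at least ",
         min_tail, " tail points")
  structure(c(best, list(proper = best$mu > 1)), class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("Tail fit: mu = %.3f (xmin = %.4g, n_tail = %d, KS = %.4f%s)\n",
              x$mu, x$xmin, x$n_tail, x$ks,
              if (x$proper) "" else "; improper, mu <= 1"))
  invisible(x)
}

# Vuong-style normalized log-likelihood ratio from per-point
# log-likelihood vectors; positive favors the first model.
vuong_lr <- function(ll1, ll2) {
  d <- ll1 - ll2
  n <- length(d)
  s <- sd(d)
  if (!is.finite(s) || s == 0) {
    if (all(d == 0)) return(list(lr_stat = 0, lr_p = 1))
    stop("degenerate likelihood-ratio comparison (zero variance)")
  }
  stat <- sum(d) / (s * sqrt(n))
  list(lr_stat = stat, lr_p = 2 * pnorm(-abs(stat)))
}

#' Compare a power-law tail against an exponential tail
#'
#' The stricter heavy-tail test: both a power law and an exponential are
#' fitted by maximum likelihood to the tail `x >= xmin`, and a
#' Vuong-style normalized log-likelihood ratio compares them pointwise.
#' A positive `lr_stat` favors the power law (heavy tail); `lr_p` is its
#' two-sided significance from the normal approximation.
#'
#' @param values Positive numeric sample.
#' @param xmin Lower cutoff defining the tail; typically the `xmin` of
#'   [fit_tail_exponent()].
#' @param min_tail Minimum number of tail points.
#' @return List with `lr_stat` and `lr_p`.
#' @export
tail_model_comparison <- function(values, xmin, min_tail = 10L) {
  x <- as.numeric(values)
  x <- x[is.finite(x) & x >= xmin]
  n <- length(x)
  if (n < min_tail) stop("need at least ", min_tail, " tail points")
  if (length(unique(x)) == 1L) stop("degenerate tail: all values equal")
  mu <- 1 + n / sum(log(x / xmin))
  ll_pl <- log(mu - 1) - log(xmin) - mu * log(x / xmin)
  lambda <- 1 / (mean(x) - xmin)
  ll_exp <- log(lambda) - lambda * (x - xmin)
  vuong_lr(ll_pl, ll_exp)
}
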