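test_that("the 3x-target filter behaves exactly as printed", {
  s <- time_estimate_series(c(0.9, 2.9, 3.1), target = 1)
  f <- filter_time_estimates(s)
  expect_equal(f$estimates, c(0.9, 2.9))
  expect_equal(attr(f, "n_removed"), 1L)
  # boundary: exactly 3x the target is removed (strictly less than)
  f2 <- filter_time_estimates(time_estimate_series(c(1, 3), target = 1))
  expect_equal(f2$estimates, 1)
  all_below <- time_estimate_series(c(0.5, 1, 2.5), target = 1)
  expect_equal(filter_time_estimates(all_below)$estimates, c(0.5, 1, 2.5))
})

test_that("successive changes are absolute first differences", {
  expect_equal(successive_changes(c(1, 3, 2)), c(2, 1))
  expect_equal(successive_changes(rep(4, 6)), rep(0, 5))
  set.seed(1)
  x <- rnorm(50)
  manual <- vapply(1:49, function(i) abs(x[i + 1] - x[i]), numeric(1))
  expect_equal(successive_changes(x), manual)
  expect_error(successive_changes(3), "at least 2")
})

test_that("Welch spectrum conserves power and finds a sinusoid", {
  set.seed(2)
  x <- rnorm(1024)
  ps <- power_spectrum(x, window_len = 1024)
  expect_equal(sum(ps$power), var(x) * 1023 / 1024, tolerance = 0.01)
  expect_true(all(diff(ps$freqs) > 0))
  expect_lte(max(ps$freqs), 0.5)
  y <- sin(2 * pi * 0.25 * seq_len(512))
  psy <- power_spectrum(y, window_len = 128)
  expect_equal(psy$freqs[which.max(psy$power)], 0.25, tolerance = 1 / 128)
})

test_that("single full-length window equals the naive DFT periodogram", {
  set.seed(3)
  x <- rnorm(128)
  ps <- power_spectrum(x, window_len = 128)
  oracle <- naive_periodogram(x)
  expect_equal(ps$freqs, oracle$freqs)
  expect_equal(ps$power, oracle$power, tolerance = 1e-10)
  expect_error(power_spectrum(rnorm(8)), "shorter|at least 16")
  expect_error(power_spectrum(rnorm(100), window_len = 128), "shorter")
})

test_that("an exact power-law spectrum is fit to machine precision", {
  f <- (1:256) / 512
  ps <- structure(list(freqs = f, power = f^(-1.3), n_windows = 1),
                  class = "power_spectrum")
  fit <- fit_spectral_exponent(ps)
  expect_equal(fit$alpha, 1.3, tolerance = 1e-6)
  expect_gte(fit$n_bins, 3)
  # slope is invariant to the log base used in the fit
  ps2 <- structure(list(freqs = f, power = 7 * f^(-0.8), n_windows = 1),
                   class = "power_spectrum")
  expect_equal(fit_spectral_exponent(ps2)$alpha, 0.8, tolerance = 1e-6)
})

test_that("only frequencies below f_max enter the spectral fit", {
  # spectrum with slope -1 below 0.1 and slope 0 above: the fit must see
  # only the low-frequency part
  f <- (1:500) / 1000
  p <- ifelse(f < 0.1, 1 / f, 10)
  ps <- structure(list(freqs = f, power = p, n_windows = 1),
                  class = "power_spectrum")
  expect_equal(fit_spectral_exponent(ps, f_max = 0.1)$alpha, 1,
               tolerance = 1e-6)
})

test_that("white noise yields a near-zero exponent, fGn recovers alpha = 1", {
  white <- vapply(1:20, function(s)
    fit_spectral_exponent(power_spectrum(gen_fgn(1024, 0, s)))$alpha,
    numeric(1))
  expect_lt(abs(mean(white)), 0.2)
  pink <- vapply(1:20, function(s)
    fit_spectral_exponent(power_spectrum(gen_fgn(1024, 1, s)))$alpha,
    numeric(1))
  expect_gt(mean(pink), 0.85)
  expect_lt(mean(pink), 1.15)
})

test_that("tail exponent recovery on Pareto samples", {
  for (mu in c(2, 2.5)) {
    est <- vapply(1:20, function(s)
      fit_tail_exponent(gen_pareto(5000, mu, 1, s))$mu, numeric(1))
    expect_lt(abs(mean(est) - mu), 0.15)
  }
})

test_that("the reported mu satisfies the Hill closed form at its xmin", {
  x <- gen_pareto(2000, 2, 1, seed = 3)
  fit <- fit_tail_exponent(x)
  tail <- x[x >= fit$xmin]
  expect_equal(fit$n_tail, length(tail))
  expect_equal(fit$mu, 1 + length(tail) / sum(log(tail / fit$xmin)),
               tolerance = 1e-12)
  expect_true(fit$proper)
  expect_error(fit_tail_exponent(c(1, 2, -1, rep(2, 10))), "positive")
  expect_error(fit_tail_exponent(rep(1, 5)), "at least 10")
})

test_that("estimator bias shrinks with sample size", {
  # spectral estimator: absolute bias at n = 4096 below bias at n = 256
  b <- vapply(c(256, 1024, 4096), function(n) {
    est <- vapply(1:10, function(s)
      fit_spectral_exponent(power_spectrum(gen_fgn(n, 1, s + n)))$alpha,
      numeric(1))
    abs(mean(est) - 1)
  }, numeric(1))
  expect_lt(b[3], b[1] + 0.05)
  # tail estimator
  bt <- vapply(c(500, 5000), function(n) {
    est <- vapply(1:10, function(s)
      fit_tail_exponent(gen_pareto(n, 2, 1, s + n))$mu, numeric(1))
    abs(mean(est) - 2)
  }, numeric(1))
  expect_lt(bt[2], bt[1] + 0.05)
})

test_that("tail comparison favors the true model", {
  pl_wins <- vapply(1:20, function(s) {
    x <- gen_pareto(2000, 2, 1, s)
    r <- tail_model_comparison(x, 1)
    r$lr_stat > 0 && r$lr_p < 0.05
  }, logical(1))
  expect_gte(sum(pl_wins), 18)
  exp_wins <- vapply(1:20, function(s) {
    set.seed(s)
    x <- 1 + rexp(2000)
    tail_model_comparison(x, 1)$lr_stat < 0
  }, logical(1))
  expect_gte(sum(exp_wins), 18)
})

test_that("identical per-point likelihoods give a zero statistic", {
  expect_equal(cognoise:::vuong_lr(rep(-1.3, 50), rep(-1.3, 50))$lr_stat, 0)
  expect_error(tail_model_comparison(rep(2, 20), 1), "degenerate")
})

test_that("classification boundaries follow the printed intervals", {
  c1 <- classify_noise(0.68, 1.80)
  expect_true(c1$is_one_over_f && c1$is_heavy_tailed)
  expect_false(classify_noise(0.38, 2)$is_one_over_f)
  expect_false(classify_noise(1, 1.0)$is_heavy_tailed)
  expect_true(classify_noise(1, 3.0)$is_heavy_tailed)
  expect_true(classify_noise(0.5, 2)$is_one_over_f)
  expect_true(classify_noise(1.5, 2)$is_one_over_f)
  expect_false(classify_noise(1.51, 2)$is_one_over_f)
  expect_false(classify_noise(1, 3.01)$is_heavy_tailed)
})

test_that("analyze_series equals its composed stages for timing data", {
  set.seed(4)
  x <- exp(0.1 * gen_fgn(600, 1, 4))
  s <- time_estimate_series(x, target = 1)
  a <- analyze_series(s)
  f <- filter_time_estimates(s)
  sf <- fit_spectral_exponent(power_spectrum(f$estimates))
  ch <- successive_changes(f$estimates)
  tf <- fit_tail_exponent(ch[ch > 0])
  expect_equal(a$spectral_fit$alpha, sf$alpha)
  expect_equal(a$tail_fit$mu, tf$mu)
  expect_identical(a$classification$is_one_over_f,
                   sf$alpha >= 0.5 && sf$alpha <= 1.5)
  expect_error(analyze_series(time_estimate_series(1, 1)), "too short")
})

test_that("naming analysis fits the tail on raw IRIs by default", {
  set.seed(5)
  iris <- gen_pareto(800, 2, 0.5, 5)
  s <- iri_series(iris)
  a_raw <- analyze_series(s)
  expect_equal(a_raw$tail_fit$mu, fit_tail_exponent(iris)$mu)
  a_chg <- analyze_series(s, tail_on = "changes")
  ch <- successive_changes(iris)
  expect_equal(a_chg$tail_fit$mu, fit_tail_exponent(ch[ch > 0])$mu)
})

test_that("fBm-style and Levy-flight series classify as the field expects", {
  # integrated fGn: Gaussian successive changes -> not heavy-tailed
  heavy <- vapply(1:20, function(s) {
    x <- cumsum(gen_fgn(1024, 1, s))
    ch <- successive_changes(x)
    fit_tail_exponent(ch[ch > 0])$mu <= 3
  }, logical(1))
  expect_lte(sum(heavy), 2)
  # Levy flight steps: heavy-tailed but uncorrelated
  res <- vapply(1:20, function(s) {
    lf <- gen_levy_flight(2048, 2, s)
    al <- fit_spectral_exponent(power_spectrum(lf$steps))$alpha
    mu <- fit_tail_exponent(lf$steps)$mu
    c(al, mu)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])), 0.2)
  expect_gte(sum(res[2, ] > 1 & res[2, ] <= 3), 18)
})
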