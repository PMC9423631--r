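test_that("Gaussian target log-density and gradient match closed forms", {
  tg <- gaussian_target(0, 1)
  expect_equal(log_density(tg, 0), log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  for (x in c(-2.5, -0.3, 0, 1.7)) {
    expect_equal(log_density(tg, x), dnorm(x, log = TRUE))
    expect_equal(grad_log_density(tg, x), -x)
  }
  tg2 <- gaussian_target(1, 0.25)
  expect_equal(grad_log_density(tg2, 1.5), -(1.5 - 1) / 0.25^2)
  expect_error(gaussian_target(0, 0), "positive")
  expect_error(log_density(tg, c(1, 2)), "one-dimensional")
})

test_that("Gaussian density integrates to 1 by quadrature", {
  tg <- gaussian_target(2, 0.5)
  gr <- seq(2 - 8 * 0.5, 2 + 8 * 0.5, length.out = 20001)
  dx <- gr[2] - gr[1]
  total <- sum(exp(vapply(gr, function(x) log_density(tg, x), numeric(1)))) * dx
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("mixture log-density equals brute-force component summation", {
  S1 <- matrix(c(1, 0.3, 0.3, 2), 2)
  S2 <- matrix(c(0.5, 0, 0, 0.5), 2)
  mx <- mixture_target(c(0.4, 0.6), rbind(c(-1, 0), c(2, 1)), list(S1, S2))
  dens2 <- function(x, mu, S) {
    d <- x - mu
    exp(-0.5 * drop(d %*% solve(S) %*% d)) / (2 * pi * sqrt(det(S)))
  }
  set.seed(1)
  for (i in 1:25) {
    p <- rnorm(2, 0, 3)
    direct <- 0.4 * dens2(p, c(-1, 0), S1) + 0.6 * dens2(p, c(2, 1), S2)
    expect_equal(log_density(mx, p), log(direct), tolerance = 1e-10)
  }
  # symmetric equal-weight mixture evaluated at the origin
  sym <- mixture_target(c(0.5, 0.5), rbind(c(-3, 0), c(3, 0)),
                        list(diag(2), diag(2)))
  direct <- 0.5 * dens2(c(0, 0), c(-3, 0), diag(2)) +
    0.5 * dens2(c(0, 0), c(3, 0), diag(2))
  expect_equal(log_density(sym, c(0, 0)), log(direct), tolerance = 1e-12)
})

test_that("degenerate one-component mixture equals its component density", {
  S <- matrix(c(1.5, 0.2, 0.2, 0.8), 2)
  mx <- mixture_target(1, matrix(c(1, -1), 1), list(S))
  d <- function(x) {
    v <- x - c(1, -1)
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(v %*% solve(S) %*% v)
  }
  for (p in list(c(0, 0), c(1, -1), c(3, 2)))
    expect_equal(log_density(mx, p), d(p), tolerance = 1e-12)
})

test_that("gradients match central finite differences", {
  mx <- mixture_target(c(0.3, 0.7), rbind(c(-2, 1), c(3, -1)),
                       list(matrix(c(1, 0.4, 0.4, 1.2), 2), diag(0.6, 2)))
  set.seed(7)
  for (i in 1:20) {
    p <- rnorm(2, 0, 2)
    expect_equal(grad_log_density(mx, p), fd_grad(mx, p), tolerance = 1e-5)
  }
  tg <- gaussian_target(0.5, 0.3)
  for (x in c(-1, 0.5, 2))
    expect_equal(grad_log_density(tg, x), fd_grad(tg, x), tolerance = 1e-5)
  # gradient vanishes at the mode of a symmetric mixture component
  sym <- mixture_target(c(0.5, 0.5), rbind(c(-5, 0), c(5, 0)),
                        list(diag(2), diag(2)))
  expect_lt(sqrt(sum(grad_log_density(sym, c(5, 0))^2)), 1e-6)
})

test_that("1-D mixtures are supported with correct density and gradient", {
  mx <- bimodal_1d()
  direct <- 0.5 * dnorm(0.7, -5, 1) + 0.5 * dnorm(0.7, 5, 1)
  expect_equal(log_density(mx, 0.7), log(direct), tolerance = 1e-12)
  expect_equal(grad_log_density(mx, 4.2), fd_grad(mx, 4.2), tolerance = 1e-5)
})

test_that("mixture density integrates to 1 on a 2-D quadrature grid", {
  mx <- mixture_target(c(0.5, 0.5), rbind(c(-2, 0), c(2, 1)),
                       list(diag(0.5, 2), matrix(c(1, 0.3, 0.3, 1), 2)))
  g <- seq(-10, 11, by = 0.05)
  gx <- rep(g, times = length(g)); gy <- rep(g, each = length(g))
  lp <- vapply(seq_along(gx), function(i) log_density(mx, c(gx[i], gy[i])),
               numeric(1))
  expect_equal(sum(exp(lp)) * 0.05^2, 1, tolerance = 1e-4)
})

test_that("invalid mixtures are rejected", {
  expect_error(mixture_target(c(0.5, 0.6), rbind(c(0, 0), c(1, 1)),
                              list(diag(2), diag(2))), "sum to 1")
  expect_error(mixture_target(1, matrix(c(0, 0), 1),
                              list(matrix(c(1, 2, 2, 1), 2))),
               "positive-definite")
})

test_that("nearest_name minimizes distance with lowest-index tie-breaking", {
  sp <- semantic_space(letters[1:6],
                       cbind(c(0, 1, 2, 3, 4, 2), c(0, 0, 1, 0, 0, -1)))
  expect_equal(nearest_name(sp, c(1, 0)), "b")
  # (2, 0) ties among indices 2, 3, 4, 6 -> lowest index wins
  expect_equal(nearest_name(sp, c(2, 0)), "b")
  # controlled two-way tie
  sp_tie <- semantic_space(c("p", "q"), rbind(c(0, 1), c(0, -1)))
  expect_equal(nearest_name(sp_tie, c(0, 0)), "p")
  # brute-force oracle on random configurations
  set.seed(3)
  coords <- matrix(rnorm(40), 20, 2)
  sp2 <- semantic_space(sprintf("n%02d", 1:20), coords)
  for (i in 1:100) {
    p <- rnorm(2, 0, 2)
    d <- sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2)
    expect_equal(nearest_name(sp2, p), sp2$names[which.min(d)])
  }
  expect_error(nearest_name(semantic_space(character(), matrix(0, 0, 2)),
                            c(0, 0)), "empty")
})

test_that("fit_mixture K=1 gives the closed-form MLE", {
  set.seed(11)
  pts <- matrix(rnorm(200), 100, 2)
  fit <- fit_mixture(pts, K = 1)
  expect_equal(fit$means[1, ], colMeans(pts), tolerance = 1e-8,
               ignore_attr = TRUE)
  mle_cov <- crossprod(sweep(pts, 2, colMeans(pts))) / 100
  expect_equal(fit$covariances[[1]], mle_cov, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("fit_mixture recovers well-separated clusters", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
               matrix(rnorm(100, 20, 1), 50, 2))
  fit <- fit_mixture(pts, K = 2, seed = 9)
  mu <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(mu[1, ] - colMeans(pts[1:50, ]))), 0.5)
  expect_lt(max(abs(mu[2, ] - colMeans(pts[51:100, ]))), 0.5)
  expect_equal(sort(fit$weights), c(0.5, 0.5), tolerance = 0.05)
})

test_that("EM log-likelihood trace is monotone nondecreasing and seeded", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
               matrix(rnorm(60, 4, 1.5), 30, 2),
               matrix(rnorm(60, -5, 0.8), 30, 2))
  fit <- fit_mixture(pts, K = 3, seed = 4)
  ll <- attr(fit, "loglik")
  expect_gte(min(diff(ll)), -1e-7)
  fit2 <- fit_mixture(pts, K = 3, seed = 4)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$weights, fit2$weights)
  expect_error(fit_mixture(pts, K = 0), "K")
  expect_error(fit_mixture(pts[1:2, ], K = 3), "K")
})

test_that("fit_mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(8)
  pts <- rbind(matrix(rnorm(120, -3, 1), 60, 2),
               matrix(rnorm(120, 3, 1), 60, 2))
  fit <- fit_mixture(pts, K = 2, seed = 1)
  mc <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  ours <- fit$means[order(fit$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(mc$parameters$mean[1, ]), ]
  expect_equal(ours, theirs, tolerance = 0.1, ignore_attr = TRUE)
})
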