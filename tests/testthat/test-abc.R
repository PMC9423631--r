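test_that("prior draws are in-bounds and seed-reproducible", {
  pr <- prior_spec("mc3", "naming")
  set.seed(1); a <- draw_prior(pr)
  set.seed(1); b <- draw_prior(pr)
  expect_identical(a, b)
  expect_gte(a$rwm_scale, 1e-3)
  expect_lte(a$rwm_scale, 1)
  expect_gte(a$mc3_temp_ratio, 1.5)
  expect_lte(a$mc3_temp_ratio, 10)
  prt <- prior_spec("hmc", "timing", nominal_target = 3)
  set.seed(2); d <- draw_prior(prt)
  expect_gte(d$target_mean, 1.5)
  expect_lte(d$target_mean, 6)
  expect_true(d$hmc_leaps %in% 1:50)
})

test_that("simulate_summary is deterministic and flags degenerate runs", {
  p <- list(rwm_scale = 0.1, target_mean = 1, target_sd = 0.2, target = 1)
  a <- simulate_summary("rwm", p, "timing", 256, seed = 5)
  b <- simulate_summary("rwm", p, "timing", 256, seed = 5)
  expect_identical(a, b)
  expect_true(a$valid)
  # near-unit-root series from a tiny proposal scale: random-walk spectrum
  tiny <- simulate_summary("rwm", list(rwm_scale = 1e-4, target_mean = 1,
                                       target_sd = 0.2, target = 1),
                           "timing", 512, seed = 6)
  expect_gt(tiny$alpha, 1.5)
  # a stuck sampler in the naming task produces no IRIs -> invalid
  sp <- gen_semantic_space(16, 4, seed = 1)
  stuck <- simulate_summary("rwm", list(rwm_scale = 1e-9, space = sp,
                                        max_iter = 2000L),
                            "naming", 64, seed = 7)
  expect_false(stuck$valid)
  expect_true(is.na(stuck$alpha))
})

test_that("vacuous tolerance accepts everything and log_ml is monotone", {
  obs <- list(alpha = 1, mu = 2)
  pr <- prior_spec("rwm", "timing")
  sims <- cognoise:::abc_simulate("rwm", pr, 120, 128, seed = 3,
                                  params_extra = list())
  free <- cognoise:::abc_accept(obs, sims, epsilon = Inf)
  expect_equal(free$log_ml, 0)
  expect_equal(nrow(free$accepted), free$n_valid)
  d <- sort(free$distances)
  tight <- cognoise:::abc_accept(obs, sims, epsilon = d[20])
  tighter <- cognoise:::abc_accept(obs, sims, epsilon = d[10])
  expect_lte(tighter$log_ml, tight$log_ml)
  expect_lte(tight$log_ml, free$log_ml)
  expect_error(abc_fit(obs, "rwm", pr, n_sims = 50, n = 128), "at least 100")
})

test_that("zero accepted simulations floors the log marginal likelihood", {
  obs <- list(alpha = 1, mu = 2)
  pr <- prior_spec("rwm", "timing")
  sims <- cognoise:::abc_simulate("rwm", pr, 120, 128, seed = 4,
                                  params_extra = list())
  expect_warning(r <- cognoise:::abc_accept(obs, sims, epsilon = -1),
                 "floored")
  expect_true(r$floored)
  expect_equal(r$log_ml, log(1 / 121))
})

test_that("posterior-predictive histogram mode picks the densest bin", {
  x <- c(rep(1.05, 30), seq(0, 3, length.out = 30))
  m <- cognoise:::hist_mode(x)
  expect_lt(abs(m - 1.05), 3.2 / 30)
  expect_equal(cognoise:::hist_mode(2.2), 2.2)
  expect_equal(cognoise:::hist_mode(rep(5, 4)), 5)
})

test_that("group_compare sums evidence and tallies best fits with ties split", {
  m <- rbind(c(-1, -2), c(-1, -3))
  colnames(m) <- c("a", "b")
  g <- group_compare(m, n_draws = 2e4, seed = 1)
  expect_equal(unname(g$group_log_ml), c(-2, -5))
  expect_equal(unname(g$best_fit_counts), c(2, 0))
  # adding a constant to one row leaves counts unchanged
  m2 <- m; m2[1, ] <- m2[1, ] + 7
  g2 <- group_compare(m2, n_draws = 2e4, seed = 1)
  expect_equal(g2$best_fit_counts, g$best_fit_counts)
  # exact tie splits equally
  g3 <- group_compare(rbind(c(-1, -1)), n_draws = 2e4, seed = 1)
  expect_equal(unname(g3$best_fit_counts), c(0.5, 0.5))
  expect_error(group_compare(matrix(numeric(0), 0, 2)), "empty")
})

test_that("pxp is symmetric under identical evidence and sums to one", {
  m <- matrix(-3, nrow = 12, ncol = 3)
  r <- protected_exceedance_probability(m, n_draws = 5e4, seed = 2)
  expect_equal(r$pxp, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(sum(r$pxp), 1, tolerance = 1e-6)
  # random matrices still normalize
  set.seed(3)
  for (i in 1:5) {
    mm <- matrix(rnorm(8 * 3, -5, 2), 8, 3)
    rr <- protected_exceedance_probability(mm, n_draws = 2e4, seed = i)
    expect_equal(sum(rr$pxp), 1, tolerance = 1e-6)
  }
  expect_error(protected_exceedance_probability(matrix(NA_real_, 2, 2)),
               "finite")
  expect_error(protected_exceedance_probability(matrix(-1, 3, 1)),
               "2 models")
})

test_that("a dominant model attains pxp above 0.99", {
  m <- cbind(rep(0, 20), rep(-5, 20), rep(-5, 20))
  r <- protected_exceedance_probability(m, n_draws = 5e4, seed = 4)
  expect_gt(r$pxp[1], 0.99)
  expect_lt(r$bor, 0.01)
})

test_that("protection interpolates between EP and uniform with BOR", {
  ep <- c(0.7, 0.2, 0.1)
  expect_equal((1 - 0) * ep + 0 / 3, ep)                    # BOR -> 0
  expect_equal((1 - 1) * ep + 1 / 3, rep(1 / 3, 3))         # BOR -> 1
  # weak, conflicting evidence drives BOR up and pxp toward uniform
  set.seed(5)
  weak <- matrix(rnorm(30, -4, 0.01), 10, 3)
  r <- protected_exceedance_probability(weak, n_draws = 5e4, seed = 5)
  expect_gt(r$bor, 0.5)
  expect_lt(max(abs(r$pxp - 1 / 3)), 0.2)
})

test_that("posterior predictive classification cross-tabulates flags", {
  mk_res <- function(alpha, mu, floored = FALSE) {
    structure(list(model = "mc3", n_sims = 100, n_valid = 100,
                   accepted = data.frame(alpha = alpha, mu = mu),
                   log_ml = -1, pp_modal_alpha = alpha, pp_modal_mu = mu,
                   floored = floored), class = "abc_result")
  }
  res <- list(mk_res(1, 2), mk_res(0.1, 2), mk_res(1, 4))
  obs <- list(classify_noise(1, 2), classify_noise(0.2, 2.5),
              classify_noise(0.9, 3.5))
  pp <- posterior_predictive_classification(res, obs)
  expect_equal(sum(pp$one_over_f), 3)
  expect_equal(unname(pp$agreement["one_over_f"]), 1)
  expect_equal(unname(pp$agreement["heavy_tails"]), 1)
  # floored participants are excluded and reported
  res2 <- c(res, list(mk_res(1, 2, floored = TRUE)))
  obs2 <- c(obs, list(classify_noise(1, 2)))
  pp2 <- posterior_predictive_classification(res2, obs2)
  expect_equal(pp2$n_excluded, 1L)
  expect_equal(sum(pp2$one_over_f), 3)
  expect_error(posterior_predictive_classification(res, obs[1:2]),
               "per participant")
})
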