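#' Prior specification for ABC
#'
#' Describes the prior over the free parameters of one sampling model
#' for one task. Each entry is `list(dist, lo, hi)` with `dist` one of
#' `"loguniform"`, `"uniform"`, `"uniform_int"`; all bounds finite.
#' Draws are seed-reproducible (they consume R's global RNG stream).
#'
#' Defaults are weakly informative and span qualitatively distinct
#' sampler regimes: proposal scales and leapfrog step sizes log-uniform
#' over three decades below the target scale, leapfrog counts uniform
#' over 1-50, temperature ratios log-uniform over `[1.5, 10]` with 4
#' chains fixed, Poisson readout rate log-uniform over `[0.1, 10]`
#' samples/s, and (timing only) target mean uniform over `[0.5, 2]`
#' times the nominal interval with sd log-uniform over `[0.01, 1]`
#' times it.
#'
#' @param model One of `"rwm"`, `"hmc"`, `"mc3"`.
#' @param task `"timing"` or `"naming"`.
#' @param nominal_target Nominal interval (s), timing task only; scales
#'   the target-parameter priors.
#' @param scale_unit Unit for proposal-scale priors (the target SD for
#'   timing; the semantic-space scale for naming).
#' @return An object of class `"prior_spec"`: named list of entries.
#' @export
prior_spec <- function(model = c("rwm", "hmc", "mc3"),
                       task = c("timing", "naming"),
                       nominal_target = 1, scale_unit = 1) {
  model <- match.arg(model)
  task <- match.arg(task)
  pr <- list()
  if (model %in% c("rwm", "mc3"))
    pr$rwm_scale <- list(dist = "loguniform", lo = 1e-3 * scale_unit,
                         hi = 1 * scale_unit)
  if (model == "hmc") {
    pr$hmc_step <- list(dist = "loguniform", lo = 1e-3 * scale_unit,
                        hi = 1 * scale_unit)
    pr$hmc_leaps <- list(dist = "uniform_int", lo = 1, hi = 50)
  }
  if (model == "mc3")
    pr$mc3_temp_ratio <- list(dist = "loguniform", lo = 1.5, hi = 10)
  if (task == "timing") {
    pr$target_mean <- list(dist = "uniform", lo = 0.5 * nominal_target,
                           hi = 2 * nominal_target)
    pr$target_sd <- list(dist = "loguniform", lo = 0.01 * nominal_target,
                         hi = 1 * nominal_target)
  } else {
    pr$rate <- list(dist = "loguniform", lo = 0.1, hi = 10)
  }
  structure(list(model = model, task = task, params = pr,
                 nominal_target = nominal_target),
            class = "prior_spec")
}

#' Draw one parameter set from a prior specification
#'
#' @param prior A [prior_spec()].
#' @return Named list of parameter values.
#' @export
draw_prior <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  out <- lapply(prior$params, function(p) {
    switch(p$dist,
           loguniform = exp(runif(1, log(p$lo), log(p$hi))),
           uniform = runif(1, p$lo, p$hi),
           uniform_int = sample(seq(p$lo, p$hi), 1L),
           stop("unknown prior distribution: ", p$dist))
  })
  if (prior$task == "timing") out$target <- prior$nominal_target
  out
}

#' Simulate the (alpha, mu) summary pair for one parameter set
#'
#' Runs the full generative pipeline (target + sampler + readout) and
#' the noise analysis end-to-end, returning the summary statistics that
#' ABC compares directly: the simulated spectral exponent and tail
#' exponent. Degenerate behavior (too few responses or a failed fit) is
#' flagged invalid rather than raising.
#'
#' @param model One of `"rwm"`, `"hmc"`, `"mc3"`.
#' @param params Named parameter list, as drawn from a [prior_spec()].
#' @param task `"timing"` or `"naming"`.
#' @param n Length of the observed series being matched.
#' @param seed Integer seed; the pair is reproducible given the seed.
#' @return List with `alpha`, `mu`, `valid`.
#' @export
simulate_summary <- function(model, params, task, n, seed) {
  res <- try(with_seed(seed, {
    series <- gen_participant_unseeded(model, params, task, n)
    a <- analyze_series(series)
    list(alpha = a$spectral_fit$alpha, mu = a$tail_fit$mu, valid = TRUE)
  }), silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$alpha) || !is.finite(res$mu))
    return(list(alpha = NA_real_, mu = NA_real_, valid = FALSE))
  res
}

# gen_participant without its own seeding; consumes the current RNG
# stream so callers control reproducibility
gen_participant_unseeded <- function(model, params, task, n) {
  settings <- settings_from_params(model, params)
  if (task == "timing") {
    target_mean <- params$target_mean %||% 1
    target_sd <- params$target_sd %||% 0.2
    tg <- gaussian_target(target_mean, target_sd)
    tr <- run_sampler(tg, settings, n, init = target_mean)
    time_estimates_from_trace(tr, target = params$target %||% target_mean)
  } else {
    space <- params$space %||% gen_semantic_space(64L, 8L, seed = 1L)
    tg <- params$target
    if (is.null(tg)) {
      K <- params$K %||% length(unique(space$categories %||% "one"))
      tg <- fit_mixture(space, K = K, seed = 1L)
    }
    max_iter <- params$max_iter %||% max(100L * n, 10000L)
    s <- run_naming_series(tg, settings, space, params$rate %||% 1,
                           n, max_iter)
    if (length(s$iris) < n / 2)
      stop("iteration cap reached with fewer than n/2 responses")
    s
  }
}

#' Rejection-ABC fit of one model to one participant
#'
#' Draws `n_sims` parameter sets from the prior, simulates the summary
#' pair for each, and accepts simulations whose standardized Euclidean
#' distance to the observed `(alpha, mu)` falls within the tolerance.
#' The log marginal likelihood is estimated as the log acceptance
#' fraction among valid simulations. Posterior-predictive modal alpha
#' and mu are histogram modes over the accepted summaries (30 bins;
#' ties take the lower bin center).
#'
#' Standardization and the tolerance are supplied by the caller (via
#' [abc_compare()]) so that all models of one participant share them;
#' run standalone, the SDs of this model's own simulations and the
#' `tol_quantile` of its own distances are used.
#'
#' @param observed List or vector with observed `alpha` and `mu`.
#' @param model One of `"rwm"`, `"hmc"`, `"mc3"`.
#' @param prior A [prior_spec()] for this model/task.
#' @param n_sims Number of prior draws; at least 100.
#' @param n Observed series length (simulations match it).
#' @param seed Integer seed.
#' @param epsilon Absolute tolerance on the standardized distance;
#'   `NULL` to use `tol_quantile`.
#' @param tol_quantile Acceptance quantile of the distances when
#'   `epsilon` is `NULL`.
#' @param sds Length-2 standardization SDs for (alpha, mu); `NULL` to
#'   compute from this model's valid simulations.
#' @param params_extra Fixed parameters merged into every draw (e.g.
#'   `space`, `target`, `max_iter`).
#' @return An object of class `"abc_result"`: list with `model`,
#'   `n_sims`, `n_valid`, `accepted` (data frame of accepted draws and
#'   summaries), `log_ml`, `pp_modal_alpha`, `pp_modal_mu`,
#'   `distances`, `sds`, `epsilon`, `floored` (`TRUE` when nothing was
#'   accepted and the `log(1/(n_sims+1))` floor was reported).
#' @export
abc_fit <- function(observed, model, prior, n_sims, n, seed = 1L,
                    epsilon = NULL, tol_quantile = 0.05, sds = NULL,
                    params_extra = list()) {
  if (n_sims < 100) stop("`n_sims` must be at least 100")
  sims <- abc_simulate(model, prior, n_sims, n, seed, params_extra)
  abc_accept(observed, sims, epsilon = epsilon, tol_quantile = tol_quantile,
             sds = sds)
}

# draw + simulate stage: returns data frame of parameter draws and
# summaries, one row per simulation
abc_simulate <- function(model, prior, n_sims, n, seed, params_extra) {
  with_seed(seed, {
    rows <- vector("list", n_sims)
    for (i in seq_len(n_sims)) {
      params <- draw_prior(prior)
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      s <- simulate_summary(model, c(params, params_extra), prior$task, n,
                            sub_seed)
      rows[[i]] <- c(params[!vapply(params, is.list, logical(1))],
                     list(alpha = s$alpha, mu = s$mu, valid = s$valid))
    }
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    attr(df, "model") <- model
    attr(df, "n_sims") <- n_sims
    df
  })
}

# acceptance stage: standardized Euclidean distance, tolerance, log-ML,
# posterior-predictive modes
abc_accept <- function(observed, sims, epsilon = NULL, tol_quantile = 0.05,
                       sds = NULL) {
  model <- attr(sims, "model")
  n_sims <- attr(sims, "n_sims")
  valid <- sims[sims$valid & is.finite(sims$alpha) & is.finite(sims$mu), ,
                drop = FALSE]
  if (nrow(valid) == 0L) stop("no valid simulations to compare against")
  if (is.null(sds)) sds <- c(sd(valid$alpha), sd(valid$mu))
  sds <- pmax(sds, 1e-12)
  oa <- if (is.list(observed)) observed$alpha else observed[[1]]
  om <- if (is.list(observed)) observed$mu else observed[[2]]
  d <- sqrt(((valid$alpha - oa) / sds[1])^2 + ((valid$mu - om) / sds[2])^2)
  if (is.null(epsilon)) epsilon <- quantile(d, tol_quantile, names = FALSE)
  acc <- valid[d <= epsilon, , drop = FALSE]
  floored <- nrow(acc) == 0L
  log_ml <- if (floored) log(1 / (n_sims + 1)) else log(nrow(acc) / nrow(valid))
  if (floored)
    warning("no accepted simulations; log_ml floored at log(1/(n_sims+1))")
  structure(list(model = model, n_sims = n_sims, n_valid = nrow(valid),
                 accepted = acc, log_ml = log_ml,
                 pp_modal_alpha = if (floored) NA_real_ else hist_mode(acc$alpha),
                 pp_modal_mu = if (floored) NA_real_ else hist_mode(acc$mu),
                 distances = d, sds = sds, epsilon = epsilon,
                 floored = floored),
            class = "abc_result")
}

# histogram mode: 30 bins over the accepted range, ties -> lower center
hist_mode <- function(x, n_bins = 30L) {
  if (length(x) == 1L) return(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  edges <- seq(r[1], r[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  k <- which.max(counts)
  (edges[k] + edges[k + 1L]) / 2
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC fit [%s]: %d/%d valid sims, %d accepted (eps = %.3g), log ML = %.3f\n",
              toupper(x$model), x$n_valid, x$n_sims, nrow(x$accepted),
              x$epsilon, x$log_ml))
  if (!x$floored)
    cat(sprintf("  posterior-predictive modes: alpha = %.3f, mu = %.3f\n",
                x$pp_modal_alpha, x$pp_modal_mu))
  invisible(x)
}

#' Fit all three sampling models to one participant by ABC
#'
#' Simulates `n_sims` draws per model, standardizes (alpha, mu) by the
#' pooled SD across all models' valid simulations, sets one shared
#' tolerance at the `tol_quantile` of the pooled distances (so
#' acceptance fractions are comparable across models), and returns one
#' [abc_fit()] result per model.
#'
#' @param observed Observed summary: list with `alpha` and `mu` (e.g.
#'   from [analyze_series()]).
#' @param priors Named list of [prior_spec()]s, one per model.
#' @param n_sims Simulations per model.
#' @param n Observed series length.
#' @param seed Integer seed.
#' @param tol_quantile Shared acceptance quantile of pooled distances.
#' @param params_extra Fixed parameters merged into every draw.
#' @return Named list of `"abc_result"`, one per model.
#' @export
abc_compare <- function(observed, priors, n_sims = 2000L, n = 512L,
                        seed = 1L, tol_quantile = 0.05,
                        params_extra = list()) {
  models <- names(priors)
  sims <- lapply(seq_along(priors), function(i)
    abc_simulate(priors[[i]]$model, priors[[i]], n_sims, n,
                 seed + i, params_extra))
  names(sims) <- models
  pool <- do.call(rbind, lapply(sims, function(s)
    s[s$valid & is.finite(s$alpha) & is.finite(s$mu), c("alpha", "mu")]))
  if (nrow(pool) == 0L) stop("no valid simulations from any model")
  sds <- pmax(c(sd(pool$alpha), sd(pool$mu)), 1e-12)
  oa <- observed$alpha; om <- observed$mu
  dpool <- sqrt(((pool$alpha - oa) / sds[1])^2 + ((pool$mu - om) / sds[2])^2)
  eps <- quantile(dpool, tol_quantile, names = FALSE)
  out <- lapply(sims, function(s) {
    n_ok <- sum(s$valid & is.finite(s$alpha) & is.finite(s$mu))
    if (n_ok == 0L) {
      # a model whose simulations all degenerate gets the evidence floor
      warning("model `", attr(s, "model"),
              "` produced no valid simulations; log_ml floored")
      structure(list(model = attr(s, "model"), n_sims = attr(s, "n_sims"),
                     n_valid = 0L,
                     accepted = s[0, , drop = FALSE],
                     log_ml = log(1 / (attr(s, "n_sims") + 1)),
                     pp_modal_alpha = NA_real_, pp_modal_mu = NA_real_,
                     distances = numeric(0), sds = sds, epsilon = eps,
                     floored = TRUE),
                class = "abc_result")
    } else {
      suppressWarnings(abc_accept(observed, s, epsilon = eps, sds = sds))
    }
  })
  names(out) <- models
  out
}
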