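#' Generate fractional Gaussian noise with a known spectral exponent
#'
#' Spectral synthesis: Fourier amplitudes are set to `f^(-alpha/2)` with
#' independent uniform random phases and inverse-transformed to a real
#' series, which is then standardized to zero mean and unit variance.
#' The target spectral slope holds exactly in expectation by
#' construction (the generator is approximate in distribution, exact in
#' its scaling law), which is the property the spectral estimator is
#' validated against. `alpha = 0` gives white noise; `alpha = 2` a
#' random-walk-like spectrum.
#'
#' @param n Series length, at least 16.
#' @param alpha Spectral exponent in `[0, 2]`.
#' @param seed Integer seed; the series is a bit-reproducible function
#'   of it.
#' @return Numeric series of length `n`.
#' @export
gen_fgn <- function(n, alpha, seed) {
  if (n < 16L) stop("`n` must be at least 16")
  if (alpha < 0 || alpha > 2) stop("`alpha` must lie in [0, 2]")
  with_seed(seed, {
    half <- n %/% 2
    f <- (1:half) / n
    amp <- f^(-alpha / 2)
    phase <- runif(half, 0, 2 * pi)
    X <- complex(length.out = n)
    X[2:(half + 1L)] <- amp * exp(1i * phase)
    if (n %% 2L == 0L) X[half + 1L] <- amp[half] * sqrt(2) * cos(phase[half])
    nneg <- n - 1L - half
    X[seq(n, by = -1L, length.out = nneg)] <- Conj(X[seq(2L, length.out = nneg)])
    x <- Re(fft(X, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

#' Generate Pareto (power-law) variates
#'
#' Inverse-CDF draws from the continuous power law with density
#' `p(x) = (mu - 1)/xmin * (x/xmin)^-mu` on `x >= xmin`:
#' `x = xmin * u^(-1/(mu - 1))` for `u ~ Uniform(0, 1)`.
#'
#' @param n Number of draws.
#' @param mu Tail exponent; must exceed 1 (otherwise non-normalizable).
#' @param xmin Lower support bound; positive.
#' @param seed Integer seed.
#' @return Numeric vector of `n` positive values.
#' @export
gen_pareto <- function(n, mu, xmin = 1, seed) {
  if (mu <= 1) stop("`mu` must exceed 1 for a normalizable power law")
  if (xmin <= 0) stop("`xmin` must be positive")
  with_seed(seed, xmin * runif(n)^(-1 / (mu - 1)))
}

#' Generate a Levy flight
#'
#' A random walk whose step lengths are Pareto(`mu`) distributed with
#' uniformly random 2-D directions: heavy-tailed increments without
#' long-range autocorrelation, the classical contrast case for
#' 1/f-generating processes.
#'
#' @param n Number of steps.
#' @param mu Step-length tail exponent in `(1, 3]`.
#' @param seed Integer seed.
#' @return List with `steps` (length-`n` positive step lengths) and
#'   `positions` (`(n+1) x 2` matrix of visited positions starting at
#'   the origin, so `positions[k+1,] - positions[k,]` has norm
#'   `steps[k]` exactly).
#' @export
gen_levy_flight <- function(n, mu, seed) {
  if (mu <= 1 || mu > 3) stop("`mu` must lie in (1, 3]")
  with_seed(seed, {
    steps <- runif(n)^(-1 / (mu - 1))
    theta <- runif(n, 0, 2 * pi)
    dx <- steps * cos(theta)
    dy <- steps * sin(theta)
    positions <- rbind(c(0, 0), cbind(cumsum(dx), cumsum(dy)))
    list(steps = steps, positions = positions)
  })
}

#' Generate a synthetic patchy semantic space
#'
#' Category centers are scattered with standard deviation
#' `between_spread`; item coordinates are scattered around their
#' category center with a category-specific spread whose median is
#' `within_spread`. With `between_spread >> within_spread` this
#' produces the patchy (clumped) structure that multimodal hypothesis
#' spaces formalize. Three further properties of real semantic fields
#' are emulated, because together they give patches item densities
#' that vary over several orders of magnitude (the property that makes
#' retrieval-time scales patch-dependent):
#'
#' * category sizes follow a Zipf-like 1/rank profile (each category
#'   keeps at least one item), mirroring the strongly skewed category
#'   production frequencies of semantic fluency;
#' * category spreads are lognormal around `within_spread` (sdlog 1):
#'   some categories are compact, some diffuse;
#' * items cluster into roughly `sqrt(size)` subcategories per
#'   category, scattered with the category spread, with items tight
#'   around their subcategory center (0.3 x the category spread) --
#'   the core/periphery and subcategory structure of real categories.
#'
#' @param n_names Number of items; at least `n_categories`.
#' @param n_categories Number of categories (patches).
#' @param within_spread Within-category scatter SD; positive.
#' @param between_spread Between-category center SD; positive.
#' @param seed Integer seed.
#' @return A [semantic_space()] with category labels.
#' @export
gen_semantic_space <- function(n_names, n_categories, within_spread = 1,
                               between_spread = 10, seed = 1L) {
  if (n_categories < 1L || n_names < n_categories)
    stop("need `n_names` >= `n_categories` >= 1")
  if (within_spread <= 0 || between_spread <= 0)
    stop("spreads must be positive")
  with_seed(seed, {
    sizes <- zipf_sizes(n_names, n_categories)
    centers <- matrix(rnorm(2 * n_categories, 0, between_spread),
                      n_categories, 2)
    spreads <- within_spread * exp(rnorm(n_categories, 0, 1))
    coords <- matrix(0, n_names, 2)
    cat_of <- rep(seq_len(n_categories), sizes)
    i <- 1L
    for (k in seq_len(n_categories)) {
      n_k <- sizes[k]
      n_sub <- max(1L, round(sqrt(n_k)))
      sub_centers <- centers[rep(k, n_sub), , drop = FALSE] +
        matrix(rnorm(2 * n_sub, 0, spreads[k]), n_sub, 2)
      assignment <- sample.int(n_sub, n_k, replace = TRUE)
      coords[i:(i + n_k - 1L), ] <- sub_centers[assignment, , drop = FALSE] +
        matrix(rnorm(2 * n_k, 0, 0.3 * spreads[k]), n_k, 2)
      i <- i + n_k
    }
    semantic_space(sprintf("item%03d", seq_len(n_names)), coords,
                   sprintf("cat%02d", cat_of))
  })
}

# Zipf-like (1/rank) category sizes summing to n, each at least 1;
# integer apportionment by the largest-remainder method
zipf_sizes <- function(n, k) {
  w <- (1 / seq_len(k)) / sum(1 / seq_len(k))
  base <- pmax(1L, floor(n * w))
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - floor(n * w)
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  while (sum(base) > n) {
    j <- which(base > 1L)
    base[j[length(j)]] <- base[j[length(j)]] - 1L
  }
  as.integer(base)
}

# map a model name + parameter list to sampler settings
settings_from_params <- function(model, params) {
  sampler_settings(
    algorithm = model,
    rwm_scale = params$rwm_scale %||% 1,
    hmc_step = params$hmc_step %||% 0.1,
    hmc_leaps = params$hmc_leaps %||% 10L,
    mc3_chains = params$mc3_chains %||% 4L,
    mc3_temp_ratio = params$mc3_temp_ratio %||% 3,
    mc3_temps = params$mc3_temps %||% NULL,
    swap_every = params$swap_every %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fused sampler + count-readout run for the naming task (C++ path with
# early stopping); consumes the current RNG stream
run_naming_series <- function(target, settings, space, rate, n, max_iter) {
  raw <- cpp_run_naming(target_cspec(target), settings$algorithm,
                        space$coords, rate, as.integer(n),
                        as.integer(max_iter), as.numeric(target$means[1, ]),
                        settings$rwm_scale, settings$hmc_step,
                        settings$hmc_leaps, settings$mc3_temps,
                        settings$swap_every)
  iri_series(raw$iris, space$names[raw$labels])
}

#' Generate a full synthetic participant
#'
#' Composes target + sampler + readout into one behavior series with
#' known generating model and parameters, the end-to-end input of the
#' ABC model-recovery experiments.
#'
#' For `task = "timing"` the target is a Gaussian over durations
#' (`params$target_mean`, `params$target_sd`) and the series contains
#' exactly `n` direct-readout estimates. For `task = "naming"` the
#' sampler forages a Gaussian-mixture target fitted to a semantic space
#' (`params$space`, default a 64-item, 8-category synthetic space) and
#' the count-based Poisson readout (`params$rate`) emits IRIs until `n`
#' responses have been produced or `params$max_iter` sampler iterations
#' (default `max(100 * n, 10000)`) are exhausted; it is an error if
#' fewer than `n/2` responses arise.
#'
#' @param model One of `"rwm"`, `"hmc"`, `"mc3"`.
#' @param params Named list of sampler/target/readout parameters (see
#'   Details); missing entries take the package defaults.
#' @param task `"timing"` or `"naming"`.
#' @param n Requested series length (estimates or responses).
#' @param seed Integer seed; the series is bit-reproducible.
#' @return A [time_estimate_series()] or [iri_series()] with attributes
#'   `model`, `params`, `seed`.
#' @export
gen_participant <- function(model = c("rwm", "hmc", "mc3"), params = list(),
                            task = c("timing", "naming"), n = 512L,
                            seed = 1L) {
  model <- match.arg(model)
  task <- match.arg(task)
  if (n < 2L) stop("`n` must be at least 2")
  settings <- settings_from_params(model, params)
  out <- with_seed(seed, {
    if (task == "timing") {
      target_mean <- params$target_mean %||% 1
      target_sd <- params$target_sd %||% 0.2
      tg <- gaussian_target(target_mean, target_sd)
      tr <- run_sampler(tg, settings, n, init = target_mean)
      time_estimates_from_trace(tr, target = params$target %||% target_mean)
    } else {
      space <- params$space %||% gen_semantic_space(64L, 8L, seed = seed)
      K <- params$K %||% length(unique(space$categories %||% "one"))
      tg <- params$target %||% fit_mixture(space, K = K, seed = seed)
      max_iter <- params$max_iter %||% max(100L * n, 10000L)
      s <- run_naming_series(tg, settings, space, params$rate %||% 1,
                             n, max_iter)
      if (length(s$iris) < n / 2)
        stop("iteration cap reached with fewer than n/2 responses")
      s
    }
  })
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}
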