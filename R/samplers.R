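#' Sampler settings
#'
#' Collects the algorithm choice and its tuning parameters. Three MCMC
#' algorithms are available as models of hypothesis sampling:
#' Random Walk Metropolis (`"rwm"`), Hamiltonian Monte Carlo (`"hmc"`)
#' and Metropolis-coupled MCMC / parallel tempering (`"mc3"`), in which
#' a cold chain at temperature 1 produces the samples while hotter
#' chains explore the space and occasionally swap states with it.
#'
#' @param algorithm One of `"rwm"`, `"hmc"`, `"mc3"`.
#' @param rwm_scale Proposal standard deviation (target units) for RWM
#'   steps, including the within-chain steps of MC3.
#' @param hmc_step Leapfrog step size.
#' @param hmc_leaps Leapfrog step count per HMC proposal.
#' @param mc3_chains Number of chains M for MC3.
#' @param mc3_temp_ratio Ratio r of the geometric temperature ladder
#'   `T_m = r^(m-1)`; ignored when `mc3_temps` is given.
#' @param mc3_temps Explicit temperature ladder; must start at exactly 1
#'   and be strictly increasing.
#' @param swap_every Iterations between swap proposals (one uniformly
#'   chosen adjacent pair per proposal).
#' @param seed Integer RNG seed used by [run_sampler()]; `NULL` leaves
#'   the current RNG state untouched.
#' @return An object of class `"sampler_settings"`.
#' @export
sampler_settings <- function(algorithm = c("rwm", "hmc", "mc3"),
                             rwm_scale = 1, hmc_step = 0.1, hmc_leaps = 10L,
                             mc3_chains = 4L, mc3_temp_ratio = 3,
                             mc3_temps = NULL, swap_every = 1L, seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (rwm_scale <= 0) stop("`rwm_scale` must be positive")
  if (hmc_step <= 0) stop("`hmc_step` must be positive")
  if (hmc_leaps < 0) stop("`hmc_leaps` must be nonnegative")
  if (is.null(mc3_temps)) {
    if (mc3_chains < 1L) stop("`mc3_chains` must be at least 1")
    if (mc3_temp_ratio <= 1) stop("`mc3_temp_ratio` must exceed 1")
    mc3_temps <- mc3_temp_ratio^(seq_len(mc3_chains) - 1)
  }
  if (mc3_temps[1] != 1) stop("the temperature ladder must start at exactly 1")
  if (length(mc3_temps) > 1 && any(diff(mc3_temps) <= 0))
    stop("the temperature ladder must be strictly increasing")
  if (swap_every < 1L) stop("`swap_every` must be at least 1")
  structure(list(algorithm = algorithm, rwm_scale = rwm_scale,
                 hmc_step = hmc_step, hmc_leaps = as.integer(hmc_leaps),
                 mc3_temps = as.numeric(mc3_temps),
                 swap_every = as.integer(swap_every),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sampler_settings")
}

#' @export
print.sampler_settings <- function(x, ...) {
  cat(sprintf("Sampler settings: %s", toupper(x$algorithm)))
  if (x$algorithm == "mc3")
    cat(sprintf(" (%d chains, temps %s)", length(x$mc3_temps),
                paste(signif(x$mc3_temps, 3), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# plain-list description of a target for the compiled samplers
target_cspec <- function(target) {
  if (inherits(target, "gaussian_target")) {
    list(type = 1L, mean = target$mean, sd = target$sd)
  } else if (inherits(target, "mixture_target")) {
    list(type = 2L, weights = target$weights, means = target$means,
         covs = target$covariances)
  } else stop("`target` must be a gaussian_target or mixture_target")
}

#' Single Random Walk Metropolis step
#'
#' Proposes an isotropic Gaussian perturbation of `state` and accepts it
#' with probability `min(1, exp((logp(h') - logp(h)) / temperature))`.
#' Uses R's global RNG stream.
#'
#' @param state Current coordinate.
#' @param target A target distribution (see [log_density()]).
#' @param scale Proposal standard deviation; positive.
#' @param temperature Tempering temperature T (1 = untempered).
#' @return `list(state = new coordinate, accepted = flag)`.
#' @export
rwm_step <- function(state, target, scale, temperature = 1) {
  if (scale <= 0) stop("`scale` must be positive")
  cpp_rwm_step(as.numeric(state), target_cspec(target), scale, temperature)
}

#' Single Hamiltonian Monte Carlo step
#'
#' Draws a standard Gaussian momentum, integrates Hamiltonian dynamics
#' with `leaps` leapfrog steps of size `step`, and applies a Metropolis
#' correction with acceptance probability `min(1, exp(-deltaH))`. A
#' non-finite gradient along the path rejects the proposal.
#'
#' @inheritParams rwm_step
#' @param step Leapfrog step size; positive.
#' @param leaps Number of leapfrog steps; `0` is the degenerate identity
#'   step (always accepted), allowed for testing.
#' @return `list(state = new coordinate, accepted = flag)`.
#' @export
hmc_step <- function(state, target, step, leaps) {
  if (step <= 0) stop("`step` must be positive")
  if (leaps < 0) stop("`leaps` must be nonnegative")
  cpp_hmc_step(as.numeric(state), target_cspec(target), step, as.integer(leaps))
}

#' Deterministic leapfrog integration
#'
#' Integrates the Hamiltonian dynamics of the target from a given
#' position and momentum, without momentum refresh or accept step.
#' Exposed for checking reversibility and energy conservation.
#'
#' @inheritParams hmc_step
#' @param momentum Momentum vector, same dimension as `state`.
#' @return `list(state, momentum)` after integration.
#' @export
leapfrog <- function(state, momentum, target, step, leaps) {
  cpp_leapfrog(as.numeric(state), as.numeric(momentum),
               target_cspec(target), step, as.integer(leaps))
}

#' Single Metropolis-coupled MCMC sweep
#'
#' Each chain m takes one RWM step on the tempered density
#' `logp(h)/T_m`, with proposal scale `scale * sqrt(T_m)` so that every
#' chain's step matches the width of its tempered target; then, if
#' `propose_swap`, one uniformly chosen adjacent
#' pair (i, j) is proposed for a state swap, accepted with probability
#' `min(1, exp((logp(h_j) - logp(h_i)) (1/T_i - 1/T_j)))`. With a single
#' chain the sweep consumes exactly the randomness of one RWM step.
#'
#' @param states M x d matrix of per-chain coordinates (row 1 = cold chain).
#' @param target A target distribution.
#' @param temps Temperature ladder, first element exactly 1, strictly
#'   increasing.
#' @param scale Cold-chain RWM proposal scale (chain m uses
#'   `scale * sqrt(T_m)`).
#' @param propose_swap Whether to propose a swap this sweep.
#' @return `list(states = updated matrix, swap = NULL or
#'   list(i, j, accepted))`.
#' @export
mc3_sweep <- function(states, target, temps, scale, propose_swap = TRUE) {
  states <- as.matrix(states)
  if (temps[1] != 1) stop("the temperature ladder must start at exactly 1")
  if (length(temps) > 1 && any(diff(temps) <= 0))
    stop("the temperature ladder must be strictly increasing")
  if (nrow(states) != length(temps))
    stop("one temperature per chain is required")
  cpp_mc3_sweep(states, target_cspec(target), as.numeric(temps), scale,
                isTRUE(propose_swap))
}

#' Run a sampler and collect its trace
#'
#' Runs the configured algorithm for `n_iterations` steps from
#' `init` and returns the cold-chain trace with acceptance and swap
#' bookkeeping. With a seed in `settings` the trace is bit-reproducible.
#'
#' @param target A target distribution ([gaussian_target()] or
#'   [mixture_target()]).
#' @param settings A [sampler_settings()].
#' @param n_iterations Number of iterations (one retained state each).
#' @param init Initial coordinate; defaults to the target's (first) mean.
#' @return An object of class `"sample_trace"` with elements `samples`
#'   (n x d matrix of cold-chain states), `accept_flags`, `swap_events`
#'   (data frame `iteration, i, j, accepted`), and `settings`.
#' @examples
#' tg <- gaussian_target(1, 0.2)
#' tr <- run_sampler(tg, sampler_settings("rwm", rwm_scale = 0.5, seed = 1), 100)
#' mean(trace_values(tr))
#' @export
run_sampler <- function(target, settings, n_iterations, init = NULL) {
  stopifnot(inherits(settings, "sampler_settings"))
  if (n_iterations < 1) stop("`n_iterations` must be at least 1")
  if (is.null(init)) {
    init <- if (inherits(target, "gaussian_target")) target$mean
            else target$means[1, ]
  }
  run1 <- function() {
    cpp_run_sampler(target_cspec(target), settings$algorithm,
                    as.integer(n_iterations), as.numeric(init),
                    settings$rwm_scale, settings$hmc_step,
                    settings$hmc_leaps, settings$mc3_temps,
                    settings$swap_every)
  }
  raw <- if (is.null(settings$seed)) run1() else with_seed(settings$seed, run1())
  swaps <- data.frame(iteration = raw$swap_iter, i = raw$swap_i,
                      j = raw$swap_j, accepted = raw$swap_accepted == 1L)
  structure(list(samples = raw$samples,
                 accept_flags = as.logical(raw$accepted),
                 swap_events = swaps,
                 settings = settings),
            class = "sample_trace")
}

#' Extract trace values
#'
#' @param trace A `"sample_trace"`.
#' @return For 1-D traces a numeric vector, otherwise the n x d matrix.
#' @export
trace_values <- function(trace) {
  stopifnot(inherits(trace, "sample_trace"))
  if (ncol(trace$samples) == 1L) as.numeric(trace$samples) else trace$samples
}

#' @export
print.sample_trace <- function(x, ...) {
  cat(sprintf("Sample trace: %d iterations, %d-D, %s, acceptance %.2f\n",
              nrow(x$samples), ncol(x$samples),
              toupper(x$settings$algorithm), mean(x$accept_flags)))
  if (nrow(x$swap_events))
    cat(sprintf("  %d swap proposals, %.2f accepted\n", nrow(x$swap_events),
                mean(x$swap_events$accepted)))
  invisible(x)
}
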