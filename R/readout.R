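#' Time-estimate series
#'
#' An ordered sequence of reproduced durations together with the nominal
#' target interval of the task block.
#'
#' @param estimates Ordered durations in seconds; all positive.
#' @param target Nominal interval in seconds (1/3, 1 and 3 in the
#'   experimental design this package emulates).
#' @return An object of class `"time_estimate_series"`.
#' @export
time_estimate_series <- function(estimates, target) {
  estimates <- as.numeric(estimates)
  if (any(!is.finite(estimates)) || any(estimates <= 0))
    stop("all estimates must be positive and finite")
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("`target` must be a single positive duration")
  structure(list(estimates = estimates, target = as.numeric(target)),
            class = "time_estimate_series")
}

#' @export
print.time_estimate_series <- function(x, ...) {
  cat(sprintf("Time-estimate series: %d estimates, target %.3g s, mean %.3g s\n",
              length(x$estimates), x$target,
              if (length(x$estimates)) mean(x$estimates) else NA_real_))
  invisible(x)
}

#' Inter-response-interval series
#'
#' An ordered sequence of inter-response intervals (IRIs), optionally
#' with the item label reported at each response. Consecutive labels
#' always differ, matching the task constraint that successive names be
#' different.
#'
#' @param iris Ordered IRIs in seconds; all positive.
#' @param labels Optional per-response item labels.
#' @return An object of class `"iri_series"`.
#' @export
iri_series <- function(iris, labels = NULL) {
  iris <- as.numeric(iris)
  if (any(!is.finite(iris)) || any(iris <= 0))
    stop("all IRIs must be positive and finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(iris))
      stop("`labels` must have one entry per IRI")
    if (length(labels) > 1 && any(labels[-1] == labels[-length(labels)]))
      stop("consecutive labels must differ")
  }
  structure(list(iris = iris, labels = labels), class = "iri_series")
}

#' @export
print.iri_series <- function(x, ...) {
  cat(sprintf("IRI series: %d responses, mean IRI %.3g s\n",
              length(x$iris), if (length(x$iris)) mean(x$iris) else NA_real_))
  invisible(x)
}

#' Direct readout of time estimates from a sampler trace
#'
#' Time estimates are read out directly from the cold-chain hypothesis
#' samples: estimate_i = h_i. Samples at or below a small positive floor
#' are clipped to it (a Gaussian hypothesis space admits negative
#' durations; with priors keeping mass away from 0 this is rare, and the
#' number clipped is recorded).
#'
#' @param trace A 1-D `"sample_trace"`.
#' @param target Nominal interval of the task block, seconds.
#' @param floor Clipping floor in seconds.
#' @return A [time_estimate_series()]; attribute `n_clipped` counts
#'   clipped samples.
#' @export
time_estimates_from_trace <- function(trace, target, floor = 0.01) {
  stopifnot(inherits(trace, "sample_trace"))
  if (ncol(trace$samples) != 1L)
    stop("time-estimate readout requires a one-dimensional trace")
  x <- as.numeric(trace$samples)
  n_clipped <- sum(x < floor)
  x <- pmax(x, floor)
  out <- time_estimate_series(x, target)
  attr(out, "n_clipped") <- n_clipped
  out
}

# nearest-name index per trace row (vectorized over names)
nearest_name_index <- function(coords, samples) {
  n <- nrow(samples)
  m <- nrow(coords)
  # squared distances via the expanded product; n x m
  d2 <- outer(rowSums(samples^2), rep(1, m)) -
    2 * samples %*% t(coords) +
    outer(rep(1, n), rowSums(coords^2))
  max.col(-d2, ties.method = "first")
}

#' Count-based IRI readout from a 2-D sampler trace
#'
#' Each hypothesis sample arrives after an Exponential(rate)
#' inter-arrival time (samples generated at a constant rate but at
#' random times, i.e. a Poisson process). The item "in mind" after each
#' sample is the nearest name to the sampler's position; a response is
#' emitted whenever that name changes, and its IRI is the summed
#' inter-arrival time since the previous response. IRIs are therefore
#' on average proportional to the number of samples between name
#' changes.
#'
#' @param trace A 2-D `"sample_trace"`.
#' @param space A [semantic_space()].
#' @param rate Samples per second of the Poisson clock; positive.
#' @return An [iri_series()]; empty when the nearest name never changes.
#' @export
iris_from_trace_count <- function(trace, space, rate = 1) {
  stopifnot(inherits(trace, "sample_trace"), inherits(space, "semantic_space"))
  if (length(space$names) == 0L) stop("semantic space is empty")
  if (ncol(trace$samples) != 2L)
    stop("IRI readout requires a two-dimensional trace")
  if (rate <= 0) stop("`rate` must be positive")
  n <- nrow(trace$samples)
  if (n < 2L) return(iri_series(numeric(0), character(0)))
  idx <- nearest_name_index(space$coords, trace$samples)
  dt <- rexp(n, rate)
  change <- which(idx[-1] != idx[-n]) + 1L
  if (length(change) == 0L) return(iri_series(numeric(0), character(0)))
  ct <- cumsum(dt)
  # clock starts at the first sample's arrival
  iris <- diff(c(ct[1], ct[change]))
  iri_series(iris, space$names[idx[change]])
}

#' Distance-based IRI readout from a 2-D sampler trace
#'
#' Alternative readout in which the IRI between successive name-change
#' events is the Euclidean path length the sampler travelled in the
#' semantic plane between those events, divided by a travel speed.
#'
#' @inheritParams iris_from_trace_count
#' @param speed Travel speed in semantic-plane units per second; positive.
#' @return An [iri_series()].
#' @export
iris_from_trace_distance <- function(trace, space, speed = 1) {
  stopifnot(inherits(trace, "sample_trace"), inherits(space, "semantic_space"))
  if (length(space$names) == 0L) stop("semantic space is empty")
  if (ncol(trace$samples) != 2L)
    stop("IRI readout requires a two-dimensional trace")
  if (speed <= 0) stop("`speed` must be positive")
  n <- nrow(trace$samples)
  if (n < 2L) return(iri_series(numeric(0), character(0)))
  idx <- nearest_name_index(space$coords, trace$samples)
  steps <- sqrt(rowSums((trace$samples[-1, , drop = FALSE] -
                           trace$samples[-n, , drop = FALSE])^2))
  change <- which(idx[-1] != idx[-n]) + 1L
  if (length(change) == 0L) return(iri_series(numeric(0), character(0)))
  # cumulative path length up to each sample (position of sample i)
  cl <- c(0, cumsum(steps))
  iris <- diff(c(cl[1], cl[change])) / speed
  iri_series(iris, space$names[idx[change]])
}
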