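# shared fixtures and independent oracles, built in code

# small two-patch semantic space on a line (deterministic)
two_name_space <- function() {
  semantic_space(c("a", "b"), rbind(c(0, 0), c(10, 0)))
}

# hand-built trace object (bypasses the samplers) for readout tests
manual_trace <- function(samples, algorithm = "rwm") {
  samples <- as.matrix(samples)
  structure(list(samples = samples,
                 accept_flags = rep(TRUE, nrow(samples)),
                 swap_events = data.frame(iteration = integer(),
                                          i = integer(), j = integer(),
                                          accepted = logical()),
                 settings = sampler_settings(algorithm)),
            class = "sample_trace")
}

# central finite differences of log_density (gradient oracle)
fd_grad <- function(target, point, h = 1e-6) {
  vapply(seq_along(point), function(d) {
    e <- rep(0, length(point)); e[d] <- h
    (log_density(target, point + e) - log_density(target, point - e)) / (2 * h)
  }, numeric(1))
}

# naive DFT periodogram (double loop, one full-length window, mean removed)
naive_periodogram <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  half <- n %/% 2
  p <- numeric(half)
  for (k in seq_len(half)) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k] <- 2 * (re^2 + im^2) / n^2
    if (n %% 2 == 0 && k == half) p[k] <- p[k] / 2
  }
  list(freqs = (1:half) / n, power = p)
}

# the bimodal 1-D mixture used for mode-mixing checks
bimodal_1d <- function() {
  mixture_target(c(0.5, 0.5), matrix(c(-5, 5), 2, 1),
                 list(matrix(1), matrix(1)))
}
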