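#' Gaussian target distribution over a one-dimensional hypothesis space
#'
#' The hypothesis-space distribution `P(H)` used for the time-estimation
#' task: a unimodal Gaussian over candidate durations.
#'
#' @param mean Center of the duration hypotheses, in seconds.
#' @param sd Spread, in seconds; must be positive.
#' @return An object of class `c("gaussian_target", "target_density")`.
#' @examples
#' tg <- gaussian_target(mean = 1, sd = 0.2)
#' log_density(tg, 1)
#' @export
gaussian_target <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("`sd` must be positive")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = c("gaussian_target", "target_density"))
}

#' Gaussian mixture target distribution
#'
#' The hypothesis-space distribution `P(H)` used for the animal-naming
#' task: a mixture of Gaussians over the 2-D semantic plane, one patch
#' per cluster of semantically related items. One-dimensional mixtures
#' (K x 1 means, 1 x 1 covariances) are also supported, as multimodal
#' test targets for the samplers.
#'
#' @param weights Mixture weights; nonnegative, summing to 1.
#' @param means K x d matrix of component means, d in \{1, 2\}.
#' @param covariances List of K symmetric positive-definite d x d
#'   matrices (plain variances are accepted when d = 1).
#' @return An object of class `c("mixture_target", "target_density")`.
#' @export
mixture_target <- function(weights, means, covariances) {
  means <- as.matrix(means)
  d <- ncol(means)
  if (!d %in% 1:2) stop("`means` must be a K x 1 or K x 2 matrix")
  K <- nrow(means)
  weights <- as.numeric(weights)
  if (length(weights) != K || K != length(covariances))
    stop("weights, means and covariances must describe the same number of components")
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (!all(dim(S) == c(d, d))) stop("each covariance must be ", d, " x ", d)
    if (max(abs(S - t(S))) > 1e-10) stop("covariance matrices must be symmetric")
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance matrices must be positive-definite")
    (S + t(S)) / 2
  })
  structure(list(weights = weights, means = means, covariances = covariances,
                 dim = d),
            class = c("mixture_target", "target_density"))
}

#' @export
print.gaussian_target <- function(x, ...) {
  cat(sprintf("Gaussian target: mean = %g s, sd = %g s\n", x$mean, x$sd))
  invisible(x)
}

#' @export
print.mixture_target <- function(x, ...) {
  cat(sprintf("Gaussian mixture target over a 2-D plane: %d component(s)\n",
              length(x$weights)))
  invisible(x)
}

#' Log-density of a target distribution
#'
#' Evaluates `log P(H)` at a point of the hypothesis space. For mixture
#' targets the component sum is taken with a numerically stable
#' log-sum-exp.
#'
#' @param target A [gaussian_target()] or [mixture_target()].
#' @param point Numeric coordinate: length 1 for a Gaussian target,
#'   length 2 for a mixture target.
#' @return A finite log-density.
#' @export
log_density <- function(target, point) UseMethod("log_density")

#' @export
log_density.gaussian_target <- function(target, point) {
  if (length(point) != 1L) stop("Gaussian target is one-dimensional; got a point of length ",
                                length(point))
  dnorm(point, target$mean, target$sd, log = TRUE)
}

#' @export
log_density.mixture_target <- function(target, point) {
  d <- target$dim
  if (length(point) != d)
    stop("mixture target is ", d, "-dimensional; got a point of length ",
         length(point))
  lk <- vapply(seq_along(target$weights), function(k) {
    ld <- if (d == 1L) dnorm(point, target$means[k, 1],
                             sqrt(target$covariances[[k]][1, 1]), log = TRUE)
          else dmvnorm2_log(point, target$means[k, ], target$covariances[[k]])
    log(target$weights[k]) + ld
  }, numeric(1))
  m <- max(lk)
  m + log(sum(exp(lk - m)))
}

# log-density of a bivariate normal, direct closed form
dmvnorm2_log <- function(x, mu, S) {
  d <- x - mu
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  q <- (S[2, 2] * d[1]^2 - 2 * S[1, 2] * d[1] * d[2] + S[1, 1] * d[2]^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Gradient of the log-density of a target distribution
#'
#' Needed by the Hamiltonian Monte Carlo sampler. For mixture targets the
#' gradient is the responsibility-weighted sum of per-component gradients.
#'
#' @inheritParams log_density
#' @return Numeric gradient vector, same dimension as `point`.
#' @export
grad_log_density <- function(target, point) UseMethod("grad_log_density")

#' @export
grad_log_density.gaussian_target <- function(target, point) {
  if (length(point) != 1L) stop("Gaussian target is one-dimensional; got a point of length ",
                                length(point))
  -(point - target$mean) / target$sd^2
}

#' @export
grad_log_density.mixture_target <- function(target, point) {
  d <- target$dim
  if (length(point) != d)
    stop("mixture target is ", d, "-dimensional; got a point of length ",
         length(point))
  K <- length(target$weights)
  lk <- numeric(K)
  gk <- matrix(0, K, d)
  for (k in seq_len(K)) {
    S <- target$covariances[[k]]
    dx <- point - target$means[k, ]
    lk[k] <- if (d == 1L) log(target$weights[k]) +
               dnorm(point, target$means[k, 1], sqrt(S[1, 1]), log = TRUE)
             else log(target$weights[k]) +
               dmvnorm2_log(point, target$means[k, ], S)
    gk[k, ] <- -solve(S, dx)
  }
  r <- exp(lk - max(lk))
  r <- r / sum(r)
  as.numeric(colSums(r * gk))
}

#' Semantic space of named items
#'
#' A set of item labels placed in a two-dimensional abstract semantic
#' plane, optionally tagged with category labels (the "patches").
#'
#' @param names Character vector of unique item labels.
#' @param coords n x 2 numeric matrix of coordinates (finite).
#' @param categories Optional per-item category labels.
#' @return An object of class `"semantic_space"`.
#' @export
semantic_space <- function(names, coords, categories = NULL) {
  names <- as.character(names)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("`coords` must be an n x 2 matrix")
  if (length(names) != nrow(coords))
    stop("`names` and `coords` must have the same length")
  if (anyDuplicated(names)) stop("item names must be unique")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(categories) && length(categories) != length(names))
    stop("`categories` must have one label per name")
  structure(list(names = names, coords = coords,
                 categories = if (is.null(categories)) NULL else as.character(categories)),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("Semantic space: %d items%s\n", length(x$names),
              if (is.null(x$categories)) ""
              else sprintf(" in %d categories", length(unique(x$categories)))))
  invisible(x)
}

#' Nearest item to a point of the semantic plane
#'
#' The item "in mind" at a sampler position: the label minimizing
#' Euclidean distance to `point`. Ties are broken by lowest index.
#'
#' @param space A [semantic_space()].
#' @param point Length-2 numeric coordinate.
#' @return A single item label.
#' @export
nearest_name <- function(space, point) {
  stopifnot(inherits(space, "semantic_space"))
  if (length(space$names) == 0L) stop("semantic space is empty")
  if (length(point) != 2L) stop("`point` must be a 2-D coordinate")
  d2 <- (space$coords[, 1] - point[1])^2 + (space$coords[, 2] - point[2])^2
  space$names[which.min(d2)]
}

#' Fit a Gaussian mixture model to points in the semantic plane
#'
#' Maximum-likelihood fit by expectation-maximization, used to turn a
#' semantic space of item coordinates into a multimodal target
#' distribution. Initialization is k-means++-style seeding driven by
#' `seed`; covariances get a small diagonal ridge so that near-singular
#' components stay invertible.
#'
#' @param points n x 2 matrix of coordinates (or a [semantic_space()]).
#' @param K Number of mixture components, `1 <= K <= n`.
#' @param seed Integer seed; the fit is bit-reproducible given `seed`.
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param ridge Diagonal ridge added to every covariance update.
#' @param covariance One of `"full"`, `"diagonal"`, `"spherical"`.
#' @return A [mixture_target()] with attributes `loglik` (the EM
#'   log-likelihood trace) and `n_iter`.
#' @export
fit_mixture <- function(points, K, seed = 1L, max_iter = 500L, tol = 1e-8,
                        ridge = 1e-6,
                        covariance = c("full", "diagonal", "spherical")) {
  if (inherits(points, "semantic_space")) points <- points$coords
  points <- as.matrix(points)
  covariance <- match.arg(covariance)
  n <- nrow(points)
  if (K < 1L || K > n) stop("`K` must satisfy 1 <= K <= number of points")
  if (ncol(points) != 2L) stop("`points` must be n x 2")

  if (K == 1L) {
    mu <- colMeans(points)
    S <- crossprod(sweep(points, 2, mu)) / n + diag(ridge, 2)
    S <- constrain_cov(S, covariance)
    fit <- mixture_target(1, matrix(mu, 1), list(S))
    ll <- sum(apply(points, 1, function(p) log_density(fit, p)))
    attr(fit, "loglik") <- ll
    attr(fit, "n_iter") <- 0L
    return(fit)
  }

  centers <- with_seed(seed, kmeanspp_centers(points, K))
  mu <- centers
  S0 <- cov(points) / K + diag(ridge, 2)
  covs <- replicate(K, S0, simplify = FALSE)
  w <- rep(1 / K, K)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step: log responsibilities
    lr <- matrix(0, n, K)
    for (k in seq_len(K)) {
      lr[, k] <- log(w[k]) + dmvnorm2_log_rows(points, mu[k, ], covs[[k]])
    }
    m <- apply(lr, 1, max)
    lse <- m + log(rowSums(exp(lr - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(lr - lse)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    # M-step
    nk <- colSums(r)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(r[, k] * points) / nk[k]
      d <- sweep(points, 2, mu[k, ])
      S <- crossprod(d * sqrt(r[, k])) / nk[k] + diag(ridge, 2)
      covs[[k]] <- constrain_cov(S, covariance)
    }
  }
  fit <- mixture_target(w / sum(w), mu, covs)
  attr(fit, "loglik") <- ll_trace
  attr(fit, "n_iter") <- length(ll_trace)
  fit
}

constrain_cov <- function(S, covariance) {
  switch(covariance,
         full = S,
         diagonal = diag(diag(S), 2),
         spherical = diag(mean(diag(S)), 2))
}

# vectorized bivariate normal log-density over rows of X
dmvnorm2_log_rows <- function(X, mu, S) {
  d1 <- X[, 1] - mu[1]
  d2 <- X[, 2] - mu[2]
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  q <- (S[2, 2] * d1^2 - 2 * S[1, 2] * d1 * d2 + S[1, 1] * d2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# k-means++ style seeding followed by a short Lloyd refinement;
# assumes the RNG state is already set by the caller
kmeanspp_centers <- function(points, K) {
  n <- nrow(points)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  if (K > 1) {
    for (k in 2:K) {
      d2 <- rep(Inf, n)
      for (j in seq_len(k - 1)) {
        dj <- (points[, 1] - points[idx[j], 1])^2 +
          (points[, 2] - points[idx[j], 2])^2
        d2 <- pmin(d2, dj)
      }
      p <- d2 / sum(d2)
      idx[k] <- sample.int(n, 1, prob = p)
    }
  }
  km <- suppressWarnings(kmeans(points, centers = points[idx, , drop = FALSE],
                                iter.max = 25))
  km$centers
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
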