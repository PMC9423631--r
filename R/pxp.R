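#' Protected exceedance probability from a log-evidence matrix
#'
#' Random-effects Bayesian model selection. A variational Dirichlet
#' posterior over model frequencies is fitted to the per-participant
#' log marginal likelihoods (uniform Dirichlet(1) prior); exceedance
#' probabilities EP_k (the probability that model k is the most
#' frequent in the population) are computed by Monte Carlo from that
#' Dirichlet. Protection handles the possibility that all models are
#' equally frequent: with the Bayes omnibus risk BOR (posterior
#' probability of the equal-frequency null, from the free-energy
#' comparison of the null and random-effects models),
#' `pxp_k = (1 - BOR) EP_k + BOR / K`.
#'
#' @param log_ml Participants x models matrix of log marginal
#'   likelihoods (finite).
#' @param n_draws Monte Carlo draws from the Dirichlet posterior.
#' @param seed Seed for the Monte Carlo stage.
#' @param alpha0 Dirichlet prior count per model.
#' @param max_iter,tol Variational iteration controls.
#' @return List with `pxp`, `ep` (unprotected exceedance
#'   probabilities), `bor`, `dirichlet_alpha` (posterior counts) and
#'   `model_freq` (posterior mean frequencies). `pxp` sums to 1.
#' @export
protected_exceedance_probability <- function(log_ml, n_draws = 1e5L,
                                             seed = 1L, alpha0 = 1,
                                             max_iter = 200L, tol = 1e-8) {
  log_ml <- as.matrix(log_ml)
  if (!all(is.finite(log_ml))) stop("`log_ml` must be finite")
  N <- nrow(log_ml); K <- ncol(log_ml)
  if (K < 2L) stop("need at least 2 models")
  if (N < 1L) stop("need at least 1 participant")

  # variational Dirichlet posterior over model frequencies
  a <- rep(alpha0, K)
  g <- matrix(1 / K, N, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(log_ml, 2, digamma(a) - digamma(sum(a)), `+`)
    lg <- lg - apply(lg, 1, max)
    g_new <- exp(lg) / rowSums(exp(lg))
    a_new <- alpha0 + colSums(g_new)
    if (max(abs(a_new - a)) < tol) { a <- a_new; g <- g_new; break }
    a <- a_new; g <- g_new
  }

  # exceedance probabilities by Monte Carlo from Dirichlet(a)
  ep <- with_seed(seed, {
    draws <- matrix(rgamma(n_draws * K, shape = rep(a, each = n_draws)),
                    n_draws, K)
    tabulate(max.col(draws, ties.method = "first"), nbins = K) / n_draws
  })

  bor <- bayes_omnibus_risk(log_ml, a, g, alpha0)
  pxp <- (1 - bor) * ep + bor / K
  list(pxp = pxp / sum(pxp), ep = ep, bor = bor,
       dirichlet_alpha = a, model_freq = a / sum(a))
}

# Bayes omnibus risk: posterior probability of the equal-frequency null
# against the random-effects model, 1/(1 + exp(F1 - F0)).
bayes_omnibus_risk <- function(log_ml, a, g, alpha0) {
  N <- nrow(log_ml); K <- ncol(log_ml)
  # F0: null model, fixed r = 1/K
  m <- apply(log_ml, 1, max)
  F0 <- sum(m + log(rowSums(exp(log_ml - m)))) - N * log(K)
  # F1: free energy of the variational random-effects solution
  dga <- digamma(a) - digamma(sum(a))
  Elog <- sum(g * log_ml)                      # E[ln p(y | m)]
  Epm <- sum(g %*% dga)                        # E[ln p(m | r)]
  Epr <- lgamma(K * alpha0) - K * lgamma(alpha0) + sum((alpha0 - 1) * dga)
  Hm <- -sum(g[g > 0] * log(g[g > 0]))         # entropy of q(m)
  Hr <- lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * dga)
  F1 <- Elog + Epm + Epr + Hm - Hr
  1 / (1 + exp(F1 - F0))
}

#' Group-level model comparison from per-participant log evidences
#'
#' Summarizes the per-participant ABC marginal likelihoods into the
#' three group scores reported for model comparisons of this kind: the
#' group log marginal likelihood (column sum), the number of
#' best-fitting participants per model (per-row argmax; ties split
#' equally), and the protected exceedance probability.
#'
#' @param log_ml Participants x models matrix (column names = models).
#' @param ... Passed to [protected_exceedance_probability()].
#' @return An object of class `"group_comparison"`: list with
#'   `group_log_ml`, `best_fit_counts`, `pxp`, `bor`, `models`.
#' @export
group_compare <- function(log_ml, ...) {
  log_ml <- as.matrix(log_ml)
  if (nrow(log_ml) == 0L || ncol(log_ml) == 0L) stop("`log_ml` is empty")
  if (!all(is.finite(log_ml))) stop("`log_ml` must be finite")
  models <- colnames(log_ml)
  if (is.null(models)) models <- paste0("model", seq_len(ncol(log_ml)))
  counts <- rep(0, ncol(log_ml))
  for (i in seq_len(nrow(log_ml))) {
    best <- which(log_ml[i, ] == max(log_ml[i, ]))
    counts[best] <- counts[best] + 1 / length(best)
  }
  px <- protected_exceedance_probability(log_ml, ...)
  structure(list(group_log_ml = setNames(colSums(log_ml), models),
                 best_fit_counts = setNames(counts, models),
                 pxp = setNames(px$pxp, models),
                 bor = px$bor, models = models),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  m <- rbind(`log marginal likelihood` = x$group_log_ml,
             `best-fitting participants` = x$best_fit_counts,
             `protected exceedance prob.` = x$pxp)
  colnames(m) <- toupper(x$models)
  print(round(m, 4))
  invisible(x)
}

#' Posterior-predictive classification table
#'
#' For each participant, classifies the posterior-predictive modal
#' `(alpha, mu)` of an ABC fit with [classify_noise()] and
#' cross-tabulates the flags against the classification of the observed
#' data — the posterior-predictive check of whether the fitted model
#' reproduces the 1/f and heavy-tail signatures participant by
#' participant.
#'
#' @param results List of `"abc_result"`s, one per participant (for one
#'   model).
#' @param observed List of `"noise_classification"`s (or lists with
#'   `alpha`, `mu`), one per participant.
#' @return An object of class `"pp_classification"`: list with
#'   `one_over_f` and `heavy_tails` 2 x 2 contingency matrices
#'   (observed x predicted), `n_excluded` (participants with empty
#'   accepted sets) and `agreement` (diagonal fraction per flag).
#' @export
posterior_predictive_classification <- function(results, observed) {
  if (length(results) != length(observed))
    stop("`results` and `observed` must have one entry per participant")
  lev <- c("no", "yes")
  tab_f <- matrix(0L, 2, 2, dimnames = list(observed = lev, predicted = lev))
  tab_h <- tab_f
  n_excluded <- 0L
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (r$floored || nrow(r$accepted) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    o <- observed[[i]]
    obs_cls <- if (inherits(o, "noise_classification")) o
               else classify_noise(o$alpha, o$mu)
    pred_cls <- classify_noise(r$pp_modal_alpha, r$pp_modal_mu)
    f_o <- lev[obs_cls$is_one_over_f + 1L]
    f_p <- lev[pred_cls$is_one_over_f + 1L]
    h_o <- lev[obs_cls$is_heavy_tailed + 1L]
    h_p <- lev[pred_cls$is_heavy_tailed + 1L]
    tab_f[f_o, f_p] <- tab_f[f_o, f_p] + 1L
    tab_h[h_o, h_p] <- tab_h[h_o, h_p] + 1L
  }
  structure(list(one_over_f = tab_f, heavy_tails = tab_h,
                 n_excluded = n_excluded,
                 agreement = c(one_over_f = diag_frac(tab_f),
                               heavy_tails = diag_frac(tab_h))),
            class = "pp_classification")
}

diag_frac <- function(tab) if (sum(tab) == 0) NA_real_ else sum(diag(tab)) / sum(tab)

#' @export
print.pp_classification <- function(x, ...) {
  cat("1/f noise (observed x predicted):\n")
  print(x$one_over_f)
  cat("heavy tails (observed x predicted):\n")
  print(x$heavy_tails)
  cat(sprintf("agreement: 1/f %.2f, heavy tails %.2f; %d excluded\n",
              x$agreement[1], x$agreement[2], x$n_excluded))
  invisible(x)
}
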