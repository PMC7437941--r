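#' Stochastic-EM schedule
#'
#' @param warmup_iters full MCMC sweeps before the EM phase (default 100).
#' @param em_iters stochastic-EM sweeps (default 2000).
#' @param average_window final EM sweeps averaged into the starting values
#'   (default 200).
#' @return list of class `"em_schedule"`.
#' @export
em_schedule <- function(warmup_iters = 100, em_iters = 2000,
                        average_window = 200) {
  stopifnot(warmup_iters >= 0, em_iters >= 1,
            average_window >= 1, average_window <= em_iters)
  structure(list(warmup_iters = as.integer(warmup_iters),
                 em_iters = as.integer(em_iters),
                 average_window = as.integer(average_window)),
            class = "em_schedule")
}

# Randomized starting configuration. beta comes from jittered gene means
# and phi/lambda from their priors with h1 = 0, h2 = 1. The loading start
# is data-informed but stochastic: genes are hierarchically clustered on
# the Spearman correlation of log1p counts, each cluster seeds one factor
# column (signs from the correlation with the cluster medoid), and a
# random fraction of entries is then re-randomized so chains start from
# different configurations. A purely uniform random alpha start leaves the
# one-at-a-time sampler in poor local modes far more often.
random_start <- function(Y, n_factors, style = c("cluster", "uniform"),
                         jitter = 0.1) {
  style <- match.arg(style)
  G <- nrow(Y); N <- ncol(Y); F_ <- n_factors
  if (style == "cluster") {
    cc <- suppressWarnings(stats::cor(t(log1p(Y)), method = "spearman"))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - abs(cc)), method = "average")
    grp <- stats::cutree(hc, k = min(F_, G))
    alpha <- matrix(0L, G, F_)
    for (f in seq_len(max(grp))) {
      mem <- which(grp == f)
      med <- mem[which.max(colSums(abs(cc[mem, mem, drop = FALSE])))]
      alpha[mem, f] <- ifelse(cc[mem, med] >= 0, 1L, -1L)
    }
    flip <- matrix(stats::runif(G * F_) < jitter, G, F_)
    alpha[flip] <- sample(c(-1L, 0L, 1L), sum(flip), replace = TRUE,
                          prob = c(0.15, 0.7, 0.15))
  } else {
    alpha <- matrix(sample(c(-1L, 0L, 1L), G * F_, replace = TRUE,
                           prob = c(0.1, 0.8, 0.1)), G, F_)
  }
  beta <- pmax(rowMeans(Y), 1e-4) * exp(stats::rnorm(G, 0, 0.1))
  phi <- exp(stats::rnorm(F_, 0, 1))
  lambda <- matrix(exp(stats::rnorm(N * F_, 0, 1) *
                         rep(sqrt(phi), each = N)), N, F_)
  hbfm_state(beta, alpha, lambda, phi,
             theta = stats::rbeta(F_, 1, 1), h1 = 0, h2 = 1)
}

#' Stochastic-EM warm start for an MCMC chain
#'
#' Produces a starting state for [run_chain()]: a randomized,
#' data-informed start (loadings seeded from a hierarchical clustering of
#' the genes on Spearman correlation of log1p counts, then partially
#' re-randomized so chains differ; beta from jittered gene means; phi and
#' lambda from their priors), then `warmup_iters` full MCMC sweeps, then
#' `em_iters` stochastic-EM sweeps
#' in which beta is set to its conditional posterior mode, alpha to the
#' argmax of its three-point conditional and phi to the maximizer of its
#' conditional (theta, h1, h2 and lambda remain sampled). The continuous
#' parameters are averaged over the last `average_window` EM sweeps; each
#' alpha entry is set to its most frequent value in that window, with ties
#' broken uniformly at random.
#'
#' @param Y count matrix.
#' @param n_factors number of factors F.
#' @param schedule an [em_schedule()].
#' @param priors an [hbfm_priors()].
#' @param gig_b GIG proposal shrink factor for the sampled lambda block.
#' @param start `"cluster"` (loading columns seeded from a gene
#'   clustering, partially re-randomized) or `"uniform"` (loadings iid
#'   over \{-1,0,1\} with P(+-1) = 0.1). Multi-chain fits alternate the
#'   two styles so chains explore different mode families; see [hbfm()].
#' @param seed integer seed, or `NULL` to continue the current stream.
#' @return an [hbfm_state()] suitable as `init` for [run_chain()].
#' @export
initialize_chain <- function(Y, n_factors, schedule = em_schedule(),
                             priors = hbfm_priors(), gig_b = 0.9,
                             start = c("cluster", "uniform"),
                             seed = NULL) {
  stopifnot(inherits(schedule, "em_schedule"), n_factors >= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- random_start(Y, n_factors, style = match.arg(start))
  G <- state$G; N <- state$N; F_ <- state$F

  for (it in seq_len(schedule$warmup_iters))
    state <- mcmc_sweep(Y, state, priors, sigma = 0.3, gig_b = gig_b)$state

  win <- schedule$average_window
  first_avg <- schedule$em_iters - win + 1L
  beta_s <- numeric(G); phi_s <- numeric(F_); theta_s <- numeric(F_)
  lambda_s <- matrix(0, N, F_); h1_s <- 0; h2_s <- 0
  alpha_cnt <- array(0L, c(G, F_, 3L))   # counts of -1, 0, 1
  for (it in seq_len(schedule$em_iters)) {
    state <- mcmc_sweep(Y, state, priors, sigma = 0.3, gig_b = gig_b,
                        em = TRUE)$state
    if (it >= first_avg) {
      beta_s <- beta_s + state$beta
      phi_s <- phi_s + state$phi
      theta_s <- theta_s + state$theta
      lambda_s <- lambda_s + state$lambda
      h1_s <- h1_s + state$h1
      h2_s <- h2_s + state$h2
      idx <- state$alpha + 2L   # -1,0,1 -> 1,2,3
      for (k in 1:3)
        alpha_cnt[, , k] <- alpha_cnt[, , k] + (idx == k)
    }
  }
  # per-entry modal alpha; ties broken uniformly at random
  amode <- matrix(0L, G, F_)
  for (g in seq_len(G)) for (f in seq_len(F_)) {
    cnt <- alpha_cnt[g, f, ]
    best <- which(cnt == max(cnt))
    if (length(best) > 1L) best <- sample(best, 1L)
    amode[g, f] <- c(-1L, 0L, 1L)[best]
  }
  hbfm_state(beta_s / win, amode, lambda_s / win, phi_s / win,
             theta = theta_s / win, h1 = h1_s / win, h2 = h2_s / win)
}
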