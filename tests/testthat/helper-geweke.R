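# Joint-distribution (Geweke-style) test machinery: compare moments of
# forward draws from the (truncated) prior-and-data model with draws from
# the successive-conditional sampler (one Gibbs sweep, then redraw Y).
#
# Proper, tighter priors are used so forward simulation is numerically
# stable; sampler-transition correctness does not depend on the prior
# hyperparameter values. Truncations mirror the guards in the update code
# (phi in [1e-6, 1e3] on the prior path, |log lambda| <= 27.6).

geweke_priors <- function() {
  hbfm_priors(beta_a = 2, beta_b = 1, h1_mean = 0, h1_var = 0.25,
              h2_a = 3, h2_b = 2)
}

rtrunc_exp_norm <- function(n, mean, sd, lo, hi) {
  exp(pmin(pmax(rnorm(n, mean, sd), lo), hi))
}

geweke_forward_draw <- function(G, N, F_, pr) {
  h1 <- rnorm(1, pr$h1_mean, sqrt(pr$h1_var))
  h2 <- 1 / rgamma(1, pr$h2_a, rate = pr$h2_b)
  phi <- rtrunc_exp_norm(F_, h1, sqrt(h2), -13.8, 6.9)
  theta <- rbeta(F_, pr$theta_a, pr$theta_b)
  alpha <- matrix(0L, G, F_)
  for (f in seq_len(F_)) {
    u <- runif(G)
    alpha[, f] <- ifelse(u < theta[f] / 2, 1L,
                         ifelse(u < theta[f], -1L, 0L))
  }
  beta <- rgamma(G, pr$beta_a, rate = pr$beta_b)
  lambda <- matrix(0, N, F_)
  for (f in seq_len(F_))
    lambda[, f] <- rtrunc_exp_norm(N, 0, sqrt(phi[f]), -27.6, 27.6)
  st <- hbfm_state(beta, alpha, lambda, phi, theta, h1, h2)
  list(state = st, Y = matrix(rpois(G * N, factor_mean(st)), G, N))
}

geweke_stats <- function(state, Y) {
  c(mean_beta = mean(state$beta),
    mean_log_phi = mean(log(state$phi)),
    mean_theta = mean(state$theta),
    h1 = state$h1,
    log_h2 = log(state$h2),
    mean_active = mean(abs(state$alpha)),
    mean_y = mean(Y))
}

# spectral-free SE for a dependent chain: non-overlapping batch means
batch_se <- function(x, n_batch = 25) {
  m <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], m, n_batch))
  sd(bm) / sqrt(n_batch)
}

# |z| scores across the monitored statistics. The phi/h block of the
# successive-conditional chain mixes slowly, so a single chain's
# batch-means SE is unreliable; instead several independent successive
# chains are run and the spread of their means provides the SE.
geweke_zscores <- function(G = 4, N = 30, F_ = 2, M_fwd = 3e4,
                           M_suc = 2e4, n_suc_chains = 8, seed = 1) {
  pr <- geweke_priors()
  set.seed(seed)
  fwd <- t(replicate(M_fwd, {
    d <- geweke_forward_draw(G, N, F_, pr)
    geweke_stats(d$state, d$Y)
  }))
  chain_means <- matrix(NA_real_, n_suc_chains, ncol(fwd),
                        dimnames = list(NULL, colnames(fwd)))
  for (ch in seq_len(n_suc_chains)) {
    d <- geweke_forward_draw(G, N, F_, pr)
    state <- d$state; Y <- d$Y
    acc <- matrix(NA_real_, M_suc, ncol(fwd))
    for (m in seq_len(M_suc)) {
      state <- mcmc_sweep(Y, state, pr, sigma = 0.4, gig_b = 0.9)$state
      Y <- matrix(rpois(G * N, factor_mean(state)), G, N)
      acc[m, ] <- geweke_stats(state, Y)
    }
    chain_means[ch, ] <- colMeans(acc)
  }
  se_f <- apply(fwd, 2, sd) / sqrt(M_fwd)
  se_s <- apply(chain_means, 2, sd) / sqrt(n_suc_chains)
  abs(colMeans(fwd) - colMeans(chain_means)) / sqrt(se_f^2 + se_s^2)
}
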