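# shared fixtures: tiny states and datasets built in code

# a valid state with given dimensions and deterministic-ish contents
make_state <- function(G = 3, N = 4, F = 2, seed = 1,
                       alpha = NULL, phi = NULL, beta = NULL,
                       lambda = NULL, theta = NULL, h1 = 0, h2 = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- runif(G, 0.5, 3)
  if (is.null(alpha)) alpha <- matrix(sample(c(-1, 0, 1), G * F, TRUE), G, F)
  if (is.null(phi)) phi <- runif(F, 0.2, 0.8)
  if (is.null(lambda))
    lambda <- matrix(exp(rnorm(N * F) * rep(sqrt(phi), each = N)), N, F)
  if (is.null(theta)) theta <- runif(F)
  hbfm_state(beta, alpha, lambda, phi, theta, h1, h2)
}

# counts drawn from a state
make_counts <- function(state, seed = 1) {
  set.seed(seed)
  mu <- factor_mean(state)
  matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
}

# Monte-Carlo correlation of log mu between two genes given (alpha, phi)
mc_log_mu_cor <- function(alpha, phi, M = 1e5, seed = 1) {
  set.seed(seed)
  F_ <- length(phi)
  loglam <- matrix(rnorm(M * F_) * rep(sqrt(phi), each = M), M, F_)
  L <- loglam %*% t(alpha)    # M x G, log mu up to gene constants
  suppressWarnings(stats::cor(L))
}

# R-side log conditional density of phi_f (up to a constant), from the
# its closed-form conditional: used as an independent grid oracle for the MH step
phi_logcond_R <- function(phi, Y, state, f) {
  G <- state$G; N <- state$N
  lam <- state$lambda[, f]
  psi <- sapply(seq_len(N), function(i) {
    sapply(seq_len(G), function(g) {
      fs <- setdiff(seq_len(state$F), f)
      if (length(fs) == 0) return(1)
      prod(exp(-state$phi[fs] / 2 * abs(state$alpha[g, fs])) *
             state$lambda[i, fs]^state$alpha[g, fs])
    })
  })  # G x N
  psi <- matrix(psi, G, N)
  sapply(phi, function(ph) {
    term <- 0
    for (g in seq_len(G)) {
      a <- state$alpha[g, f]
      term <- term + state$beta[g] * sum(exp(-ph / 2 * abs(a)) *
                                           lam^a * psi[g, ])
    }
    -(N / 2 + 1) * log(ph) -
      (ph / 2) * sum(abs(state$alpha[, f]) * rowSums(Y)) -
      sum(log(lam)^2) / (2 * ph) -
      (log(ph) - state$h1)^2 / (2 * state$h2) - term
  })
}

# R-side log conditional of lambda_if (up to a constant)
lambda_logcond_R <- function(lam, Y, state, i, f) {
  G <- state$G
  psi <- sapply(seq_len(G), function(g) {
    fs <- setdiff(seq_len(state$F), f)
    if (length(fs) == 0) return(1)
    prod(exp(-state$phi[fs] / 2 * abs(state$alpha[g, fs])) *
           state$lambda[i, fs]^state$alpha[g, fs])
  })
  a <- state$alpha[, f]
  kap <- sum(Y[, i] * a)
  tau <- 2 * sum((a == 1) * state$beta * exp(-state$phi[f] / 2) * psi)
  chi <- 2 * sum((a == -1) * state$beta * exp(-state$phi[f] / 2) * psi)
  (kap - 1) * log(lam) -
    (tau * lam + chi / lam + log(lam)^2 / state$phi[f]) / 2
}

# total-variation distance between a sample and a density known on a grid
tv_sample_vs_density <- function(x, logdens, lo, hi, nbin = 40) {
  grid_n <- 4000
  xs <- seq(lo, hi, length.out = grid_n)
  ld <- logdens(xs)
  d <- exp(ld - max(ld))
  d <- d / sum(d)
  breaks <- seq(lo, hi, length.out = nbin + 1)
  pe <- as.vector(table(cut(pmin(pmax(x, lo), hi), breaks))) / length(x)
  pt <- vapply(seq_len(nbin), function(k)
    sum(d[xs >= breaks[k] & xs < breaks[k + 1]]), numeric(1))
  pt[nbin] <- pt[nbin] + sum(d[xs >= breaks[nbin + 1]])
  sum(abs(pe - pt / sum(pt))) / 2
}
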