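#' Sampler configuration
#'
#' @param n_iter total MCMC sweeps per chain (default 4000).
#' @param n_retain number of final sweeps retained for inference
#'   (default 1000).
#' @param phi_proposal_sd initial scale sigma of the lognormal random-walk
#'   proposal for phi: `log phi_cand ~ Normal(log phi, sigma^2)`.
#' @param gig_b shrink factor in (0, 1] applied to both rate parameters of
#'   the generalized inverse Gaussian proposal for lambda; values below 1
#'   thicken the proposal tails (default 0.9).
#' @param adapt logical; tune `phi_proposal_sd` per factor toward a 25-45\%
#'   acceptance rate during the pre-retention window (every
#'   `adapt_window` sweeps), frozen before the first retained sweep.
#' @param adapt_window sweeps between tuning decisions.
#' @return list of class `"hbfm_control"`.
#' @export
hbfm_control <- function(n_iter = 4000, n_retain = 1000,
                         phi_proposal_sd = 0.3, gig_b = 0.9,
                         adapt = TRUE, adapt_window = 50) {
  stopifnot(n_iter >= 1, n_retain >= 1, n_retain <= n_iter,
            phi_proposal_sd > 0, gig_b > 0, gig_b <= 1, adapt_window >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_retain = as.integer(n_retain),
                 phi_proposal_sd = phi_proposal_sd, gig_b = gig_b,
                 adapt = isTRUE(adapt),
                 adapt_window = as.integer(adapt_window)),
            class = "hbfm_control")
}

#' Prior hyperparameters
#'
#' Defaults are the model's conditionally conjugate, non-informative priors:
#' beta_g ~ Gamma(0.001, 0.001) (shape/rate), phi_f ~ Lognormal(h1, h2) with
#' h1 ~ Normal(0, 100) and h2 ~ InverseGamma(1, 1) (shape/scale), and
#' |alpha_gf| ~ Bernoulli(theta_f) with theta_f ~ Beta(1, 1), split evenly
#' between +1 and -1. Tighter values are useful for prior-sensitive
#' diagnostics such as joint-distribution (Geweke) tests, where diffuse
#' priors make forward simulation numerically degenerate.
#'
#' @param beta_a,beta_b Gamma shape and rate for beta.
#' @param h1_mean,h1_var Normal mean and variance for h1.
#' @param h2_a,h2_b InverseGamma shape and scale for h2.
#' @param theta_a,theta_b Beta parameters for theta.
#' @return list of class `"hbfm_priors"`.
#' @export
hbfm_priors <- function(beta_a = 0.001, beta_b = 0.001,
                        h1_mean = 0, h1_var = 100,
                        h2_a = 1, h2_b = 1,
                        theta_a = 1, theta_b = 1) {
  stopifnot(beta_a > 0, beta_b > 0, h1_var > 0, h2_a > 0, h2_b > 0,
            theta_a > 0, theta_b > 0)
  structure(list(beta_a = beta_a, beta_b = beta_b, h1_mean = h1_mean,
                 h1_var = h1_var, h2_a = h2_a, h2_b = h2_b,
                 theta_a = theta_a, theta_b = theta_b),
            class = "hbfm_priors")
}

#' One sweep of the Metropolis-within-Gibbs sampler
#'
#' Runs the update blocks in order — beta, theta, alpha, (h1, h2), phi,
#' lambda — and returns the updated state. Conditionals: beta_g is
#' Gamma(0.001 + sum_i y_gi, 0.001 + sum_i C_gi) with C_gi the factor
#' product; theta_f is Beta(1 + n_active, 1 + G - n_active); alpha_gf is
#' resampled one-at-a-time from its three-point conditional computed on the
#' log scale; h1 and h2 are conjugate Normal / InverseGamma; phi_f uses a
#' lognormal random-walk Metropolis step (or a Lognormal(h1, h2) prior draw
#' when the factor is inactive everywhere); lambda_if uses an independence
#' Metropolis step with a GIG(kappa, b*tau, b*chi) proposal (prior draw when
#' tau = chi = 0). With `em = TRUE` the beta, alpha and phi blocks optimize
#' their conditionals instead of sampling (stochastic EM).
#'
#' Mostly an internal building block; exposed for diagnostics and testing.
#'
#' @param Y count matrix.
#' @param state an [hbfm_state()].
#' @param priors an [hbfm_priors()].
#' @param sigma per-factor phi proposal scales (recycled to length F).
#' @param gig_b GIG proposal shrink factor.
#' @param em logical, stochastic-EM mode.
#' @param blocks length-6 logical enabling the beta, theta, alpha, (h1,h2),
#'   phi and lambda blocks.
#' @return list with the updated `state`, `loglik` (conditional Poisson
#'   log-likelihood after the sweep), `phi_accept` (per-factor code:
#'   0 reject, 1 accept, 2 prior draw) and `lambda_accept`/`lambda_total`.
#' @export
mcmc_sweep <- function(Y, state, priors = hbfm_priors(),
                       sigma = 0.3, gig_b = 0.9, em = FALSE,
                       blocks = rep(TRUE, 6)) {
  stopifnot(inherits(state, "hbfm_state"), length(blocks) == 6)
  if (nrow(Y) != state$G || ncol(Y) != state$N)
    stop("counts dimensions do not match the state")
  sigma <- rep_len(sigma, state$F)
  res <- cpp_sweep(Y, state$beta, storage_int(state$alpha), state$lambda,
                   state$phi, state$theta, state$h1, state$h2,
                   unclass(priors), sigma, gig_b, em, as.logical(blocks))
  new_state <- hbfm_state(res$beta, res$alpha, res$lambda, res$phi,
                          res$theta, res$h1, res$h2)
  list(state = new_state, loglik = res$loglik,
       phi_accept = res$phi_accept,
       lambda_accept = res$lambda_accept,
       lambda_total = res$lambda_total)
}

storage_int <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Run one MCMC chain
#'
#' Executes `control$n_iter` full sweeps from `init` and retains the last
#' `control$n_retain` sweeps. At each retained sweep the trace records the
#' log-mean correlation matrix (lower triangle), the conditional Poisson
#' log-likelihood and deviance (-2 log-likelihood), and the (beta, alpha,
#' phi) configuration needed for posterior predictive simulation. Given the
#' same `seed` and `init` the trace is bit-for-bit reproducible.
#'
#' @param Y count matrix.
#' @param init initial [hbfm_state()], typically from [initialize_chain()].
#' @param control an [hbfm_control()].
#' @param priors an [hbfm_priors()].
#' @param seed integer seed for this chain, or `NULL` to continue the
#'   current RNG stream.
#' @return object of class `"hbfm_chain"`: list with matrices `rho`
#'   (n_retain x G(G-1)/2, column order = lower triangle by column),
#'   `beta`, `phi`, `theta`, vectors `loglik`, `deviance`, array `alpha`
#'   (G x F x n_retain), `final_state`, acceptance summaries and the frozen
#'   proposal scales.
#' @export
run_chain <- function(Y, init, control = hbfm_control(),
                      priors = hbfm_priors(), seed = NULL) {
  stopifnot(inherits(init, "hbfm_state"), inherits(control, "hbfm_control"))
  if (!is.null(seed)) set.seed(seed)
  G <- init$G; N <- init$N; F_ <- init$F
  n_iter <- control$n_iter; n_retain <- control$n_retain
  first_keep <- n_iter - n_retain + 1L
  sigma <- rep_len(control$phi_proposal_sd, F_)

  P <- G * (G - 1L) / 2L
  lt <- lower.tri(matrix(0, G, G))
  rho <- matrix(NA_real_, n_retain, P)
  beta_tr <- matrix(NA_real_, n_retain, G)
  phi_tr <- matrix(NA_real_, n_retain, F_)
  theta_tr <- matrix(NA_real_, n_retain, F_)
  loglik <- numeric(n_retain)
  alpha_tr <- array(NA_integer_, c(G, F_, n_retain))

  state <- init
  win_att <- integer(F_); win_acc <- integer(F_)
  phi_acc_kept <- integer(F_); phi_att_kept <- integer(F_)
  lam_acc <- 0; lam_tot <- 0
  for (it in seq_len(n_iter)) {
    sw <- mcmc_sweep(Y, state, priors, sigma, control$gig_b,
                     em = FALSE, blocks = rep(TRUE, 6))
    state <- sw$state
    mh <- sw$phi_accept != 2L
    if (control$adapt && it < first_keep) {
      win_att <- win_att + as.integer(mh)
      win_acc <- win_acc + as.integer(sw$phi_accept == 1L & mh)
      if (it %% control$adapt_window == 0L) {
        rate <- ifelse(win_att > 0L, win_acc / pmax(win_att, 1L), NA_real_)
        sigma <- ifelse(!is.na(rate) & rate < 0.25, sigma / 1.3,
                        ifelse(!is.na(rate) & rate > 0.45, sigma * 1.3, sigma))
        win_att[] <- 0L; win_acc[] <- 0L
      }
    }
    if (it >= first_keep) {
      m <- it - first_keep + 1L
      r <- log_mu_correlation(state$alpha, state$phi)
      rho[m, ] <- r[lt]
      beta_tr[m, ] <- state$beta
      phi_tr[m, ] <- state$phi
      theta_tr[m, ] <- state$theta
      loglik[m] <- sw$loglik
      alpha_tr[, , m] <- state$alpha
      phi_att_kept <- phi_att_kept + as.integer(mh)
      phi_acc_kept <- phi_acc_kept + as.integer(sw$phi_accept == 1L & mh)
      lam_acc <- lam_acc + sw$lambda_accept
      lam_tot <- lam_tot + sw$lambda_total
    }
  }
  structure(list(rho = rho, beta = beta_tr, phi = phi_tr, theta = theta_tr,
                 alpha = alpha_tr, loglik = loglik, deviance = -2 * loglik,
                 final_state = state,
                 acceptance = list(
                   phi = ifelse(phi_att_kept > 0,
                                phi_acc_kept / pmax(phi_att_kept, 1L),
                                NA_real_),
                   lambda = if (lam_tot > 0) lam_acc / lam_tot else NA_real_),
                 sigma = sigma, gene_ids = rownames(Y),
                 G = G, N = N, F = F_, seed = seed,
                 control = control),
            class = "hbfm_chain")
}

#' @export
print.hbfm_chain <- function(x, ...) {
  cat("MCMC chain: G =", x$G, "N =", x$N, "F =", x$F, "\n")
  cat("  retained sweeps:", length(x$loglik),
      " mean loglik:", format(mean(x$loglik), digits = 6), "\n")
  cat("  lambda MH acceptance:", format(x$acceptance$lambda, digits = 3), "\n")
  invisible(x)
}
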