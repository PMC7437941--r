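#' Construct and validate a model parameter state
#'
#' A state bundles one joint configuration of the factor model for G genes,
#' N cells and F factors:
#' \itemize{
#'   \item `beta`  length-G positive baseline expression rates;
#'   \item `alpha` G x F loading matrix with entries in \{-1, 0, 1\};
#'   \item `lambda` N x F positive cell-specific factor scores,
#'     a priori Lognormal(0, phi_f) — `phi` is the \emph{variance} of
#'     `log(lambda)` throughout the package;
#'   \item `phi`   length-F positive log-scale variances;
#'   \item `theta` length-F activation probabilities in [0, 1];
#'   \item `h1`, `h2` hyperparameters of the Lognormal(h1, h2) prior on phi.
#' }
#'
#' @param beta,alpha,lambda,phi,theta,h1,h2 see above.
#' @return an object of class `"hbfm_state"` (a named list).
#' @export
hbfm_state <- function(beta, alpha, lambda, phi,
                       theta = rep(0.5, length(phi)), h1 = 0, h2 = 1) {
  beta <- as.numeric(beta)
  alpha <- as.matrix(alpha)
  lambda <- as.matrix(lambda)
  phi <- as.numeric(phi)
  theta <- as.numeric(theta)
  G <- length(beta); F_ <- length(phi); N <- nrow(lambda)
  if (!all(is.finite(beta)) || any(beta <= 0)) stop("beta must be positive")
  if (!identical(dim(alpha), c(G, F_)) )
    stop("alpha must be ", G, " x ", F_)
  if (!all(alpha %in% c(-1, 0, 1))) stop("alpha entries must be in {-1,0,1}")
  if (ncol(lambda) != F_) stop("lambda must have ", F_, " columns")
  if (!all(is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be positive")
  if (!all(is.finite(phi)) || any(phi <= 0)) stop("phi must be positive")
  if (length(theta) != F_ || any(theta < 0 | theta > 1))
    stop("theta must be length-F probabilities")
  if (!is.finite(h1) || !is.finite(h2) || h2 <= 0)
    stop("h1 must be finite and h2 positive")
  structure(list(beta = beta, alpha = alpha, lambda = lambda, phi = phi,
                 theta = theta, h1 = h1, h2 = h2,
                 G = G, N = N, F = F_),
            class = "hbfm_state")
}

#' @export
print.hbfm_state <- function(x, ...) {
  cat("Factor model state: G =", x$G, "genes, N =", x$N,
      "cells, F =", x$F, "factors\n")
  cat("  active loadings:", sum(x$alpha != 0), "of", x$G * x$F, "\n")
  invisible(x)
}

#' Poisson mean matrix of the factor model
#'
#' Computes mu_gi = beta_g * prod_f exp(-phi_f/2 * |alpha_gf|) *
#' lambda_if^alpha_gf. The product is accumulated in log space and
#' exponentiated once, so moderate factor counts cannot overflow
#' intermediate terms.
#'
#' @param state an [hbfm_state()].
#' @return G x N matrix of positive means.
#' @export
factor_mean <- function(state) {
  stopifnot(inherits(state, "hbfm_state"))
  # log mu = log beta + alpha %*% t(log lambda) - (|alpha| phi)/2
  loglam <- log(state$lambda)                       # N x F
  logmu <- log(state$beta) -
    0.5 * as.numeric(abs(state$alpha) %*% state$phi) +
    state$alpha %*% t(loglam)                       # G x N
  mu <- exp(logmu)
  if (!all(is.finite(mu)) || any(mu <= 0)) {
    bad <- which(!is.finite(mu) | mu <= 0, arr.ind = TRUE)[1L, ]
    stop("numeric overflow in factor mean at gene ", bad[1L],
         ", cell ", bad[2L])
  }
  mu
}

#' Conditional Poisson log-likelihood
#'
#' Sum over genes and cells of the Poisson log-pmf of the counts at the
#' model means, conditional on the latent factor scores.
#'
#' @param Y count matrix (see [as_counts()]).
#' @param state an [hbfm_state()].
#' @return a finite scalar.
#' @export
loglik_conditional <- function(Y, state) {
  stopifnot(inherits(state, "hbfm_state"))
  if (nrow(Y) != state$G || ncol(Y) != state$N)
    stop("counts are ", nrow(Y), " x ", ncol(Y), " but state is ",
         state$G, " x ", state$N)
  sum(stats::dpois(Y, factor_mean(state), log = TRUE))
}

#' Marginal mean and variance of a gene's counts
#'
#' With the factor scores integrated out, E(Y_gi) = beta_g regardless of the
#' loadings (that is what the exp(-phi_f/2 |alpha_gf|) adjustment in the mean
#' buys), and
#' Var(Y_gi) = beta_g + beta_g^2 * (exp(sum_f phi_f |alpha_gf|) - 1),
#' by the law of total variance with lognormal factor moments. The variance
#' always exceeds the mean when any factor is active: the model is
#' conditionally Poisson but marginally overdispersed.
#'
#' @param beta_g positive scalar baseline rate.
#' @param alpha_row length-F loadings in \{-1,0,1\}.
#' @param phi length-F positive log-scale variances.
#' @return named numeric vector `c(mean=, variance=)`.
#' @export
marginal_moments <- function(beta_g, alpha_row, phi) {
  stopifnot(length(beta_g) == 1L, beta_g > 0,
            length(alpha_row) == length(phi),
            all(alpha_row %in% c(-1, 0, 1)), all(phi > 0))
  v <- beta_g + beta_g^2 * expm1(sum(phi * abs(alpha_row)))
  c(mean = beta_g, variance = v)
}

#' Log-mean correlation structure implied by the loadings
#'
#' The covariance of log mu between two genes, marginally over the factor
#' scores, is sum_f phi_f alpha_gf alpha_g'f and the variance of log mu_gi
#' is sum_f phi_f alpha_gf^2, so
#' \deqn{\rho_{gg'} = \frac{\sum_f \phi_f \alpha_{gf}\alpha_{g'f}}
#'   {\sqrt{(\sum_f \phi_f \alpha_{gf}^2)(\sum_f \phi_f \alpha_{g'f}^2)}}.}
#' A pair sharing a single active factor has correlation +1 (same signs) or
#' -1 (opposite signs); disjoint supports give 0. Any 0/0 case — a gene with
#' no active factor — is defined as exactly 0, including that gene's
#' diagonal entry, so all-inactive genes can never form edges.
#'
#' @param alpha G x F loading matrix in \{-1,0,1\}.
#' @param phi length-F positive variances.
#' @return symmetric G x G matrix with entries in [-1, 1].
#' @export
log_mu_correlation <- function(alpha, phi) {
  alpha <- as.matrix(alpha)
  phi <- as.numeric(phi)
  stopifnot(ncol(alpha) == length(phi), all(phi > 0),
            all(alpha %in% c(-1, 0, 1)))
  cov <- alpha %*% (phi * t(alpha))        # G x G, sum_f phi_f a_gf a_g'f
  v <- diag(cov)                           # sum_f phi_f a_gf^2
  denom <- sqrt(outer(v, v))
  rho <- ifelse(denom > 0, cov / denom, 0)
  rho[v == 0, ] <- 0                       # 0/0 rule, incl. diagonal
  rho[, v == 0] <- 0
  # clamp roundoff
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  dimnames(rho) <- list(rownames(alpha), rownames(alpha))
  rho
}
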