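# Update-block correctness: each Gibbs block is exercised in isolation via
# the `blocks` mask of mcmc_sweep() and compared against closed-form
# conditionals, brute-force enumeration, or grid-integration oracles.

collect_sweeps <- function(Y, state, n, blocks, field, priors = hbfm_priors(),
                           fresh = FALSE, sigma = 0.3, gig_b = 0.9) {
  out <- vector("list", n)
  cur <- state
  for (k in seq_len(n)) {
    cur <- mcmc_sweep(Y, if (fresh) state else cur, priors,
                      sigma = sigma, gig_b = gig_b, blocks = blocks)$state
    out[[k]] <- cur[[field]]
  }
  out
}

test_that("beta conditional is the closed-form Gamma when no factor is active", {
  Y <- rbind(c(3, 1), c(0, 2))
  st <- make_state(G = 2, N = 2, F = 1, alpha = matrix(0, 2, 1))
  set.seed(10)
  draws <- collect_sweeps(Y, st, 2e4, c(TRUE, rep(FALSE, 5)), "beta")
  b1 <- vapply(draws, `[`, numeric(1), 1)
  b2 <- vapply(draws, `[`, numeric(1), 2)
  # gene 1: Gamma(0.001 + 4, 0.001 + 2), rate parameterization
  m <- 4.001 / 2.001
  v <- 4.001 / 2.001^2
  expect_lt(abs(mean(b1) - m), 4 * sd(b1) / sqrt(length(b1)))
  expect_lt(abs(var(b1) - v) / v, 0.06)
  expect_lt(abs(mean(b2) - 2.001 / 2.001), 4 * sd(b2) / sqrt(length(b2)))
  # draws are independent across genes given the rest
  expect_lt(abs(cor(b1, b2)), 0.03)
})

test_that("theta conditional is Beta(1 + active, 1 + G - active)", {
  G <- 10
  a <- matrix(0, G, 1); a[1:4, 1] <- c(1, -1, 1, 1)
  st <- make_state(G = G, N = 2, F = 1, alpha = a)
  Y <- make_counts(st)
  set.seed(11)
  th <- unlist(collect_sweeps(Y, st, 2e4, c(FALSE, TRUE, rep(FALSE, 4)),
                              "theta"))
  expect_lt(abs(mean(th) - 5 / 12), 4 * sd(th) / sqrt(length(th)))
})

test_that("alpha conditional matches brute-force enumeration of the joint", {
  # one gene, three cells, one factor: enumerate the three alpha values
  Y <- matrix(c(2, 0, 1), 1, 3)
  lam <- matrix(c(0.8, 1.3, 2.0), 3, 1)
  st0 <- hbfm_state(beta = 1.5, alpha = matrix(0L, 1, 1), lambda = lam,
                    phi = 0.6, theta = 0.4)
  logjoint <- function(a) {
    st <- hbfm_state(st0$beta, matrix(as.integer(a), 1, 1), lam,
                     st0$phi, st0$theta)
    prior <- if (a == 0) log(1 - 0.4) else log(0.4 / 2)
    loglik_conditional(Y, st) + prior
  }
  lw <- vapply(c(-1, 0, 1), logjoint, numeric(1))
  pexp <- exp(lw - max(lw)); pexp <- pexp / sum(pexp)

  set.seed(12)
  n <- 3e4
  draws <- unlist(collect_sweeps(Y, st0, n, c(FALSE, FALSE, TRUE, rep(FALSE, 3)),
                                 "alpha", fresh = TRUE))
  pobs <- tabulate(draws + 2L, 3L) / n
  se <- sqrt(pexp * (1 - pexp) / n)
  expect_true(all(abs(pobs - pexp) < 4 * se + 1e-12))
})

test_that("alpha is forced inactive when theta is zero and balanced when the factor is flat", {
  st <- make_state(G = 3, N = 5, F = 1, theta = 0)
  Y <- make_counts(st)
  set.seed(13)
  draws <- unlist(collect_sweeps(Y, st, 50, c(FALSE, FALSE, TRUE, rep(FALSE, 3)),
                                 "alpha", fresh = TRUE))
  expect_true(all(draws == 0))
  # lambda = 1 everywhere and phi -> small: P = (1-theta, theta/2, theta/2)
  st2 <- hbfm_state(beta = rep(1, 3), alpha = matrix(0L, 3, 1),
                    lambda = matrix(1, 5, 1), phi = 1e-9, theta = 0.6)
  draws2 <- unlist(collect_sweeps(Y, st2, 4000,
                                  c(FALSE, FALSE, TRUE, rep(FALSE, 3)),
                                  "alpha", fresh = TRUE))
  pobs <- tabulate(draws2 + 2L, 3L) / length(draws2)
  expect_lt(abs(pobs[2] - 0.4), 0.03)
  expect_lt(abs(pobs[1] - 0.3), 0.03)
})

test_that("h1 conditional has the derived Normal mean and variance", {
  # F = 4, log phi = 1 each, h2 = 1: mean 4/4.01, var 1/4.01
  st <- make_state(G = 3, N = 2, F = 4, phi = rep(exp(1), 4), h2 = 1)
  Y <- make_counts(st)
  set.seed(14)
  h1s <- unlist(collect_sweeps(Y, st, 8000, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                               "h1", fresh = TRUE))
  expect_lt(abs(mean(h1s) - 4 / 4.01), 4 * sd(h1s) / sqrt(length(h1s)))
  expect_lt(abs(var(h1s) - 1 / 4.01) / (1 / 4.01), 0.08)
})

test_that("h2 conditional is InverseGamma with shape F/2+1 and the residual scale", {
  # pin h1 at 0 via a degenerate prior; log phi = +-1 gives SS = 2
  st <- make_state(G = 3, N = 2, F = 2, phi = exp(c(1, -1)))
  Y <- make_counts(st)
  pr <- hbfm_priors(h1_mean = 0, h1_var = 1e-12)
  set.seed(15)
  h2s <- unlist(collect_sweeps(Y, st, 2e4, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                               "h2", priors = pr, fresh = TRUE))
  expect_true(all(h2s > 0))
  # IG(2, 2): mean b/(a-1) = 2
  expect_lt(abs(mean(h2s) - 2) / 2, 0.05)
})

test_that("phi for an everywhere-inactive factor is drawn from its Lognormal(h1, h2) prior", {
  st <- make_state(G = 3, N = 4, F = 1, alpha = matrix(0L, 3, 1),
                   h1 = 0.3, h2 = 0.5)
  Y <- make_counts(st)
  set.seed(16)
  ph <- unlist(collect_sweeps(Y, st, 1e4, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                              "phi"))
  expect_gt(ks.test(ph, stats::plnorm, meanlog = 0.3,
                    sdlog = sqrt(0.5))$p.value, 0.01)
})

test_that("single-site phi MH chain matches the grid-integrated conditional (TV < 0.05)", {
  st <- make_state(G = 3, N = 8, F = 1,
                   alpha = matrix(c(1L, -1L, 1L), 3, 1), seed = 8)
  Y <- make_counts(st, seed = 2)
  set.seed(17)
  ph <- unlist(collect_sweeps(Y, st, 4e4, c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                              "phi"))
  lo <- quantile(ph, 5e-4); hi <- quantile(ph, 1 - 5e-4)
  tv <- tv_sample_vs_density(ph, function(x) phi_logcond_R(x, Y, st, 1),
                             lo, hi, nbin = 30)
  expect_lt(tv, 0.05)
  # acceptance strictly inside (0, 1) for an active factor
  acc <- 0
  cur <- st
  for (k in 1:1000) {
    sw <- mcmc_sweep(Y, cur, blocks = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
    acc <- acc + (sw$phi_accept[1] == 1)
    cur <- sw$state
  }
  expect_gt(acc, 0); expect_lt(acc, 1000)
})

test_that("lambda for an inactive factor is drawn from its Lognormal(0, phi) prior", {
  st <- make_state(G = 3, N = 1, F = 1, alpha = matrix(0L, 3, 1),
                   phi = 0.7)
  Y <- make_counts(st)
  set.seed(18)
  ls <- unlist(collect_sweeps(Y, st, 1e4, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
                              "lambda"))
  expect_gt(ks.test(ls, stats::plnorm, meanlog = 0,
                    sdlog = sqrt(0.7))$p.value, 0.01)
})

test_that("single-site lambda MH chain matches its grid-integrated conditional at b = 0.9 and b = 1", {
  st <- make_state(G = 3, N = 1, F = 1,
                   alpha = matrix(c(1L, -1L, 1L), 3, 1), seed = 9)
  Y <- matrix(c(4, 0, 2), 3, 1)
  for (b in c(0.9, 1)) {
    set.seed(19)
    ls <- unlist(collect_sweeps(Y, st, 4e4,
                                c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
                                "lambda", gig_b = b))
    lo <- quantile(ls, 5e-4); hi <- quantile(ls, 1 - 5e-4)
    tv <- tv_sample_vs_density(ls, function(x) lambda_logcond_R(x, Y, st, 1, 1),
                               lo, hi, nbin = 30)
    expect_lt(tv, 0.05)
  }
})

test_that("chains are reproducible and keep consistent traces", {
  st <- make_state(G = 4, N = 10, F = 2, seed = 30)
  Y <- make_counts(st, seed = 31)
  ctrl <- hbfm_control(n_iter = 60, n_retain = 25)
  tr1 <- run_chain(Y, st, ctrl, seed = 99)
  tr2 <- run_chain(Y, st, ctrl, seed = 99)
  expect_identical(tr1$rho, tr2$rho)
  expect_identical(tr1$loglik, tr2$loglik)
  expect_identical(tr1$final_state$lambda, tr2$final_state$lambda)
  expect_length(tr1$loglik, 25)
  expect_equal(tr1$deviance, -2 * tr1$loglik)
  # incremental factor-product bookkeeping agrees with a full recomputation
  expect_equal(tr1$loglik[25], loglik_conditional(Y, tr1$final_state),
               tolerance = 1e-8)
})
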