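fake_chain_with_rho <- function(rho_samples, G, gene_ids = paste0("g", seq_len(G))) {
  structure(list(rho = rho_samples, loglik = rep(0, nrow(rho_samples)),
                 deviance = rep(0, nrow(rho_samples)),
                 G = G, gene_ids = gene_ids),
            class = "hbfm_chain")
}

test_that("correlation summaries: mean, equal-tailed CI and a* behave on constructed samples", {
  G <- 3  # pairs ordered (2,1), (3,1), (3,2)
  M <- 1000
  set.seed(1)
  s <- cbind(rep(0.4, M),                       # constant
             c(rep(-0.5, M / 2), rep(0.5, M / 2)),  # symmetric two-point
             pmin(pmax(rnorm(M, 0.3, 0.1), -1), 1)) # truncated normal
  cp <- correlations(fake_chain_with_rho(s, G), level = 0.95)
  expect_equal(cp$rho_hat[2, 1], 0.4)
  expect_equal(cp$ci_lo[2, 1], 0.4)
  expect_equal(cp$ci_hi[2, 1], 0.4)     # zero width
  expect_equal(cp$rho_hat[3, 1], 0)
  expect_lt(abs(cp$rho_hat[3, 2] - 0.3), 3 * 0.1 / sqrt(M))
  expect_lt(abs(cp$ci_lo[3, 2] - 0.104), 0.02)
  expect_lt(abs(cp$ci_hi[3, 2] - 0.496), 0.02)
  # structural invariants
  expect_identical(cp$rho_hat, t(cp$rho_hat))
  expect_true(all(cp$ci_lo <= cp$rho_hat + 1e-12) &&
                all(cp$rho_hat <= cp$ci_hi + 1e-12))
})

test_that("approximate p-value is the smallest zero-covering equal-tailed interval size", {
  expect_equal(approx_pvalue(c(0.1, 0.2, 0.5)), 0)
  expect_equal(approx_pvalue(c(-1, -2, 1, 2)), 1)
  expect_equal(approx_pvalue(c(rep(1, 950), rep(-1, 50))), 0.10)
})

test_that("edges require the credible interval to exclude zero; levels nest", {
  G <- 4
  M <- 2000
  set.seed(2)
  s <- cbind(rnorm(M, 0.4, 0.1),   # clear positive     (2,1)
             rnorm(M, 0.1, 0.3),   # straddles zero     (3,1)
             rnorm(M, -0.5, 0.1),  # clear negative     (4,1)
             rnorm(M, 0.05, 0.02), # narrowly positive  (3,2)
             rnorm(M, 0, 0.2),     # null               (4,2)
             rnorm(M, 0.2, 0.25))  # borderline         (4,3)
  s <- pmin(pmax(s, -1), 1)
  ch <- fake_chain_with_rho(s, G)
  net <- gcn(correlations(ch, 0.95), 0.95)
  key <- paste(net$gene_a, net$gene_b)
  expect_true("g1 g2" %in% key && "g1 g4" %in% key && "g2 g3" %in% key)
  expect_false("g1 g3" %in% key || "g2 g4" %in% key)
  expect_equal(net$sign[net$gene_a == "g1" & net$gene_b == "g4"], -1)

  # monotone nesting: raising the level never adds edges
  lv <- c(0.8, 0.9, 0.95, 0.99)
  nets <- lapply(lv, function(l) gcn(correlations(ch, l), l))
  sizes <- vapply(nets, nrow, integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (k in seq_len(length(lv) - 1)) {
    k1 <- paste(nets[[k + 1]]$gene_a, nets[[k + 1]]$gene_b)
    k0 <- paste(nets[[k]]$gene_a, nets[[k]]$gene_b)
    expect_true(all(k1 %in% k0))
  }
})

test_that("the CI edge rule and the a* threshold rule agree up to sampling discreteness", {
  G <- 6
  M <- 1e4
  set.seed(3)
  mus <- runif(G * (G - 1) / 2, -0.15, 0.25)
  s <- sapply(mus, function(m) pmin(pmax(rnorm(M, m, 0.1), -1), 1))
  cp <- correlations(fake_chain_with_rho(s, G), 0.95)
  lt <- lower.tri(cp$rho_hat)
  is_edge <- cp$ci_lo[lt] > 0 | cp$ci_hi[lt] < 0
  p <- cp$approx_p[lt]
  clear <- abs(p - 0.05) > 4 / M
  expect_identical(is_edge[clear], (p < 0.05)[clear])
})

test_that("network evaluation counts TPR and FDR and ranks AUC by inverse a*", {
  truth <- data.frame(a = c("g1", "g1", "g2", "g3"),
                      b = c("g2", "g3", "g3", "g4"))
  est <- structure(data.frame(gene_a = c("g1", "g3", "g2", "g1"),
                              gene_b = c("g2", "g1", "g3", "g4"),
                              rho_hat = c(.9, .8, .7, .6),
                              approx_p = c(0, 0, 0.01, 0.01),
                              sign = c(1, 1, 1, 1)),
                   genes = paste0("g", 1:4), class = c("gcn", "data.frame"))
  m <- evaluate_gcn(est, truth)
  expect_equal(unname(m["tpr"]), 0.75)
  expect_equal(unname(m["fdr"]), 0.25)
  expect_equal(unname(m["n_edges"]), 4)
  expect_error(evaluate_gcn(est, truth[0, ]), "empty truth")

  # perfect recovery from a synthetic posterior: TPR 1, FDR 0, AUC 1
  G <- 5; M <- 200
  set.seed(4)
  pairs <- which(lower.tri(diag(G)), arr.ind = TRUE)
  true_idx <- c(1, 4, 7)
  s <- sapply(seq_len(nrow(pairs)), function(k)
    if (k %in% true_idx) rnorm(M, 0.7, 0.05) else rnorm(M, 0, 0.02))
  cp <- correlations(fake_chain_with_rho(pmin(pmax(s, -1), 1), G), 0.95)
  truth2 <- data.frame(a = paste0("g", pairs[true_idx, 2]),
                       b = paste0("g", pairs[true_idx, 1]))
  m2 <- evaluate_gcn(gcn(cp, 0.95), truth2, cp)
  expect_equal(unname(m2[c("tpr", "fdr", "auc")]), c(1, 0, 1))
})

test_that("AUC of a random ranking is 1/2 and agrees with an independent ROC implementation", {
  set.seed(5)
  aucs <- replicate(200, {
    G <- 15
    P <- G * (G - 1) / 2
    p <- sample(seq(0, 1, length.out = 50), P, TRUE)
    rho <- runif(P, -1, 1)
    lab <- seq_len(P) %in% sample(P, 20)
    r <- rank(-p + abs(rho) * 1e-6)
    (sum(r[lab]) - 20 * 21 / 2) / (20 * (P - 20))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)

  # cross-check the package AUC against pROC on one synthetic posterior
  G <- 8; M <- 500
  set.seed(6)
  P <- G * (G - 1) / 2
  mus <- runif(P, -0.3, 0.5)
  s <- sapply(mus, function(m) pmin(pmax(rnorm(M, m, 0.15), -1), 1))
  cp <- correlations(fake_chain_with_rho(s, G), 0.95)
  pairs <- which(lower.tri(diag(G)), arr.ind = TRUE)
  lab <- abs(mus) > 0.25
  truth <- data.frame(a = paste0("g", pairs[lab, 2]),
                      b = paste0("g", pairs[lab, 1]))
  m <- evaluate_gcn(gcn(cp, 0.95), truth, cp)
  score <- -cp$approx_p[lower.tri(cp$approx_p)] +
    abs(cp$rho_hat[lower.tri(cp$rho_hat)]) * 1e-6
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, score, direction = "<")))
  expect_equal(unname(m["auc"]), as.numeric(ref), tolerance = 1e-10)
})

test_that("edge lists round-trip through CSV and GraphML", {
  net <- structure(data.frame(gene_a = c("g1", "g2", "g4"),
                              gene_b = c("g2", "g3", "g5"),
                              rho_hat = c(0.912345678901, -0.5, 0.25),
                              approx_p = c(0, 0.002, 0.04),
                              sign = c(1, -1, 1)),
                   genes = paste0("g", 1:5), level = 0.95,
                   class = c("gcn", "data.frame"))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "edges.csv")
  gml <- file.path(dir, "net.graphml")
  export_gcn(net, csv)
  export_gcn(net, gml)
  back_csv <- read_gcn(csv)
  expect_equal(back_csv$rho_hat, net$rho_hat, tolerance = 1e-12)
  expect_equal(back_csv$gene_a, net$gene_a)
  back_gml <- read_gcn(gml)
  ord <- order(back_gml$gene_a)
  expect_equal(back_gml$rho_hat[ord], net$rho_hat, tolerance = 1e-12)
  expect_equal(back_gml$approx_p[ord], net$approx_p, tolerance = 1e-12)

  # empty network: header-only CSV
  empty <- structure(net[0, ], genes = paste0("g", 1:5), level = 0.95,
                     class = c("gcn", "data.frame"))
  csv0 <- file.path(dir, "empty.csv")
  export_gcn(empty, csv0)
  expect_length(readLines(csv0), 1L)
  expect_equal(nrow(read_gcn(csv0)), 0L)
})
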