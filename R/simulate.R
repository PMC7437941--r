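#' Block simulation designs
#'
#' A design sorts G = n_groups * genes_per_group genes into groups that
#' share identical loading rows, fixes the factor variances, and draws
#' baseline rates from a Gamma distribution. Two canonical designs ship
#' with the package:
#' \describe{
#'   \item{`"sim10"`}{F = 10. Each group k owns factor k and group k+1
#'     (cyclically) cross-loads it with alternating sign, wiring a 10-cycle
#'     of correlated group pairs: 100 within-group + 250 between-group =
#'     350 true edges. phi = (0.20, 0.20, 0.35, 0.35, 0.50, 0.50, 0.65,
#'     0.65, 0.80, 0.80).}
#'   \item{`"sim15"`}{F = 15. Factors 1-10 are group-private; factors 11-14
#'     are each shared by a triple of groups and factor 15 by one pair
#'     (mixed signs), wiring 13 correlated group pairs: 100 + 325 = 425
#'     true edges. phi repeats (0.20, 0.35, 0.50, 0.65, 0.80) three times
#'     in the layout (f1, f2, f11) = 0.20, (f3, f4, f12) = 0.35, ...}
#' }
#' The exact group-pair wiring is this package's canonical choice; any
#' wiring with the same group structure, phi multiset and edge counts is
#' statistically equivalent.
#'
#' @param name `"sim10"`, `"sim15"`, or `"custom"` (then supply
#'   `group_loadings` and `phi`).
#' @param n_cells number of cells N.
#' @param genes_per_group genes per group (default 5).
#' @param group_loadings n_groups x F matrix in \{-1,0,1\} for custom
#'   designs.
#' @param phi length-F positive factor variances for custom designs.
#' @param beta_shape,beta_rate Gamma(shape, rate) for the baseline rates
#'   (default Gamma(3, 0.5), mean 6).
#' @param seed integer seed stored in the design.
#' @return object of class `"hbfm_design"`.
#' @export
sim_design <- function(name = c("sim10", "sim15", "custom"), n_cells,
                       genes_per_group = 5, group_loadings = NULL,
                       phi = NULL, beta_shape = 3, beta_rate = 0.5,
                       seed = 1) {
  name <- match.arg(name)
  if (name == "sim10") {
    L <- matrix(0L, 10, 10)
    for (k in 1:10) {
      L[k, k] <- 1L
      L[k %% 10 + 1L, k] <- if (k %% 2 == 1) 1L else -1L
    }
    phi <- rep(c(0.20, 0.35, 0.50, 0.65, 0.80), each = 2)
  } else if (name == "sim15") {
    L <- matrix(0L, 10, 15)
    for (k in 1:10) L[k, k] <- 1L
    shared <- list(`11` = c(1, 2, 3),   `12` = c(4, 5, 6),
                   `13` = c(7, 8, 9),   `14` = c(10, 1, 4),
                   `15` = c(2, 5))
    signs <- list(`11` = c(1, 1, -1),   `12` = c(1, -1, 1),
                  `13` = c(1, 1, 1),    `14` = c(1, -1, -1),
                  `15` = c(1, -1))
    for (f in names(shared))
      L[shared[[f]], as.integer(f)] <- as.integer(signs[[f]])
    phi <- c(rep(c(0.20, 0.35, 0.50, 0.65, 0.80), each = 2),
             c(0.20, 0.35, 0.50, 0.65, 0.80))
  } else {
    if (is.null(group_loadings) || is.null(phi))
      stop("custom designs need group_loadings and phi")
    L <- storage_int(group_loadings)
  }
  stopifnot(ncol(L) == length(phi), all(phi > 0),
            all(L %in% c(-1L, 0L, 1L)), n_cells >= 1,
            beta_shape > 0, beta_rate > 0)
  if (any(rowSums(abs(L)) == 0))
    stop("every group must have at least one active factor")
  structure(list(name = name, n_groups = nrow(L),
                 genes_per_group = as.integer(genes_per_group),
                 F_sim = ncol(L), group_loadings = L,
                 phi = as.numeric(phi),
                 beta_shape = beta_shape, beta_rate = beta_rate,
                 N = as.integer(n_cells), seed = as.integer(seed)),
            class = "hbfm_design")
}

#' @export
print.hbfm_design <- function(x, ...) {
  cat("Simulation design '", x$name, "': ", x$n_groups, " groups x ",
      x$genes_per_group, " genes, F = ", x$F_sim, ", N = ", x$N, "\n",
      sep = "")
  bl <- build_block_loadings(x)
  cat("  true edges:", attr(bl, "n_true_edges"), "\n")
  invisible(x)
}

#' Expand group loadings to the gene level
#'
#' Every gene in a group receives its group's loading row. The attribute
#' `n_true_edges` carries the number of gene pairs with nonzero log-mean
#' correlation under the design's phi.
#'
#' @param design an [sim_design()].
#' @return G x F integer loading matrix with rownames `gene1..geneG` and
#'   attribute `n_true_edges`.
#' @export
build_block_loadings <- function(design) {
  stopifnot(inherits(design, "hbfm_design"))
  alpha <- design$group_loadings[rep(seq_len(design$n_groups),
                                     each = design$genes_per_group), ,
                                 drop = FALSE]
  rownames(alpha) <- paste0("gene", seq_len(nrow(alpha)))
  attr(alpha, "n_true_edges") <-
    nrow(true_network(alpha, design$phi))
  alpha
}

#' Enumerate the true network of a loading configuration
#'
#' An unordered gene pair is a true edge when its log-mean correlation
#' (see [log_mu_correlation()]) is nonzero (|rho| > 1e-12).
#'
#' @param alpha G x F loadings.
#' @param phi length-F positive variances.
#' @return data.frame with columns gene_a, gene_b, rho.
#' @export
true_network <- function(alpha, phi) {
  rho <- log_mu_correlation(alpha, phi)
  genes <- rownames(rho) %||% paste0("gene", seq_len(nrow(rho)))
  lt <- which(lower.tri(rho), arr.ind = TRUE)
  keep <- abs(rho[lt]) > 1e-12
  data.frame(gene_a = genes[lt[keep, 2L]],
             gene_b = genes[lt[keep, 1L]],
             rho = rho[lt][keep], stringsAsFactors = FALSE)
}

#' Simulate counts from the factor model
#'
#' Draws beta_g ~ Gamma(shape, rate), lambda_if ~ Lognormal(0, phi_f),
#' forms the Poisson means from the block loadings and samples
#' Y_gi ~ Poisson(mu_gi). Reproducible from `design$seed`.
#'
#' @param design an [sim_design()].
#' @return object of class `"hbfm_sim"`: list with `counts` (G x N),
#'   `state` (the generating [hbfm_state()]), `rho_true` (G x G),
#'   `truth` (true edge data.frame).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "hbfm_design"))
  set.seed(design$seed)
  alpha <- build_block_loadings(design)
  G <- nrow(alpha); F_ <- design$F_sim; N <- design$N
  beta <- stats::rgamma(G, shape = design$beta_shape,
                        rate = design$beta_rate)
  lambda <- matrix(exp(stats::rnorm(N * F_) *
                         rep(sqrt(design$phi), each = N)), N, F_)
  state <- hbfm_state(beta, alpha, lambda, design$phi)
  mu <- factor_mean(state)
  Y <- matrix(stats::rpois(G * N, mu), G, N)
  Y <- as_counts(Y, gene_ids = rownames(alpha),
                 cell_ids = paste0("cell", seq_len(N)))
  structure(list(counts = Y, state = state,
                 rho_true = log_mu_correlation(alpha, design$phi),
                 truth = true_network(alpha, design$phi),
                 design = design),
            class = "hbfm_sim")
}

#' @export
print.hbfm_sim <- function(x, ...) {
  cat("Simulated dataset: G =", nrow(x$counts), "N =", ncol(x$counts),
      "F_sim =", x$design$F_sim, "\n")
  cat("  true edges:", nrow(x$truth),
      " zero fraction:", format(mean(x$counts == 0), digits = 3), "\n")
  invisible(x)
}

#' Zero-inflated negative binomial parameter table
#'
#' @param pi0 zero-inflation probabilities in [0, 1].
#' @param size NB dispersion (size) parameters, positive.
#' @param mu NB means, positive.
#' @return data.frame of class `"zinb_params"` with one row per gene.
#' @export
zinb_params <- function(pi0, size, mu) {
  stopifnot(length(pi0) == length(size), length(size) == length(mu),
            all(pi0 >= 0 & pi0 <= 1), all(size > 0), all(mu > 0))
  structure(data.frame(pi0 = pi0, size = size, mu = mu),
            class = c("zinb_params", "data.frame"))
}

#' Synthetic ZINB parameter set
#'
#' A plausible synthetic parameter table for NORTA-style simulations, in
#' the range typical of moderately expressed single-cell genes: means from
#' Gamma(3, 0.5), dispersions uniform in [0.5, 2], zero inflation uniform
#' in [0, 0.4]. This is \emph{not} estimated from any real dataset; users
#' modeling a specific dataset should fit their own marginals and pass
#' them through [zinb_params()].
#'
#' @param G number of genes.
#' @param seed integer seed.
#' @return a [zinb_params()] table.
#' @export
synthetic_zinb_params <- function(G, seed = 1) {
  set.seed(seed)
  zinb_params(pi0 = stats::runif(G, 0, 0.4),
              size = stats::runif(G, 0.5, 2),
              mu = stats::rgamma(G, shape = 3, rate = 0.5))
}

# ZINB quantile: point mass pi0 at zero plus (1 - pi0) * NB
qzinb <- function(u, pi0, size, mu) {
  q <- numeric(length(u))
  nb <- u > pi0
  q[nb] <- stats::qnbinom((u[nb] - pi0) / (1 - pi0), size = size, mu = mu)
  q
}

#' Simulate correlated ZINB counts via the NORTA algorithm
#'
#' Draws a latent multivariate normal vector per cell with the given
#' correlation matrix, maps it through the standard normal CDF, and applies
#' each gene's zero-inflated negative binomial quantile function
#' ("NORmal To Anything"). Marginals are exactly ZINB; the latent
#' correlation induces the gene-gene dependence. A non-positive
#' semi-definite input is repaired by clipping negative eigenvalues (with a
#' warning) and rescaling to unit diagonal.
#'
#' @param zinb a [zinb_params()] table, one row per gene.
#' @param latent_corr G x G correlation matrix for the Gaussian copula. A
#'   natural choice for factor-model designs is the true log-mean
#'   correlation matrix ([log_mu_correlation()]) of the matching design.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return count matrix (G x N) validated by [as_counts()].
#' @export
simulate_norta <- function(zinb, latent_corr, n_cells, seed = 1) {
  stopifnot(inherits(zinb, "zinb_params"))
  G <- nrow(zinb)
  latent_corr <- as.matrix(latent_corr)
  stopifnot(nrow(latent_corr) == G, ncol(latent_corr) == G)
  set.seed(seed)
  ev <- eigen(latent_corr, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warning("latent correlation not positive semi-definite; ",
            "clipping negative eigenvalues")
  }
  vals <- pmax(ev$values, 1e-10)
  R <- ev$vectors %*% (vals * t(ev$vectors))
  R <- stats::cov2cor(R)
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), G)
  Z <- A %*% matrix(stats::rnorm(G * n_cells), G, n_cells)
  U <- stats::pnorm(Z)
  Y <- matrix(0, G, n_cells)
  for (g in seq_len(G))
    Y[g, ] <- qzinb(U[g, ], zinb$pi0[g], zinb$size[g], zinb$mu[g])
  as_counts(Y, gene_ids = rownames(latent_corr) %||%
              paste0("gene", seq_len(G)),
            cell_ids = paste0("cell", seq_len(n_cells)))
}
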