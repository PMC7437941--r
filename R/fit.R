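#' Fit the sparse hierarchical Bayesian factor model
#'
#' Runs `n_chains` independent chains for a fixed number of factors, each
#' warm-started by its own stochastic-EM pass ([initialize_chain()]), keeps
#' the `n_keep` chains with the highest average retained conditional
#' log-likelihood, and computes the DIC from the pooled deviance draws of
#' the kept chains. All randomness descends from `seed`: per-chain seeds
#' are drawn once from it, so chains are independent of execution order.
#'
#' "Average marginal likelihood" chain ranking is implemented as the mean
#' retained conditional log-likelihood log p(Y | beta, alpha, phi, lambda);
#' the true marginal over lambda is intractable.
#'
#' @param Y genes x cells count matrix (see [as_counts()]).
#' @param n_factors number of latent factors F.
#' @param n_chains chains to run (default 8).
#' @param n_keep chains retained for inference (default 5).
#' @param control an [hbfm_control()].
#' @param schedule an [em_schedule()] for the warm start.
#' @param priors an [hbfm_priors()].
#' @param seed root integer seed.
#' @param verbose print per-chain progress.
#' @return object of class `"hbfm"`: list with `chains` (all
#'   [run_chain()] traces), `kept` (indices of retained chains, best
#'   first), `chain_loglik` (per-chain mean retained log-likelihood),
#'   `dic`, model dimensions and the configuration used.
#' @seealso [hbfm_select()] to choose F by DIC, [correlations()] and
#'   [gcn()] for network inference, [simulate.hbfm()] for posterior
#'   predictive datasets.
#' @export
hbfm <- function(Y, n_factors, n_chains = 8, n_keep = 5,
                 control = hbfm_control(), schedule = em_schedule(),
                 priors = hbfm_priors(), seed = 1, verbose = FALSE) {
  Y <- as_counts(Y)
  stopifnot(n_factors >= 1, n_chains >= 1, n_keep >= 1)
  if (n_keep > n_chains) {
    warning("n_keep > n_chains; keeping all chains")
    n_keep <- n_chains
  }
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    # alternate start styles so chains explore different mode families;
    # spurious weak factors then differ across chains and pooling the
    # retained draws filters them out of the credible intervals
    init <- initialize_chain(Y, n_factors, schedule, priors,
                             gig_b = control$gig_b,
                             start = if (ch %% 2 == 1) "cluster" else "uniform")
    chains[[ch]] <- run_chain(Y, init, control, priors, seed = NULL)
    chains[[ch]]$seed <- chain_seeds[ch]
    if (verbose)
      message(sprintf("chain %d/%d: mean loglik %.2f", ch, n_chains,
                      mean(chains[[ch]]$loglik)))
  }
  kept <- rank_chains(chains, n_keep, indices = TRUE)
  dev <- unlist(lapply(chains[kept], `[[`, "deviance"))
  structure(list(chains = chains, kept = kept,
                 chain_loglik = vapply(chains, function(tr)
                   mean(tr$loglik), numeric(1)),
                 dic = dic(dev),
                 n_factors = n_factors, G = nrow(Y), N = ncol(Y),
                 gene_ids = rownames(Y),
                 n_chains = n_chains, n_keep = n_keep,
                 control = control, schedule = schedule, priors = priors,
                 seed = seed),
            class = "hbfm")
}

#' Rank chains by average retained log-likelihood
#'
#' Chains are scored by the mean of their retained conditional
#' log-likelihood draws and the top `keep` are returned, ties broken by
#' chain index. With fewer chains than `keep`, all are kept with a warning.
#'
#' @param chains list of `"hbfm_chain"` traces.
#' @param keep number to retain.
#' @param indices return indices instead of the traces.
#' @return the retained traces (scores non-increasing), or their indices.
#' @export
rank_chains <- function(chains, keep, indices = FALSE) {
  stopifnot(length(chains) >= 1, keep >= 1)
  if (length(chains) < keep) {
    warning("fewer chains than keep; keeping all")
    keep <- length(chains)
  }
  score <- vapply(chains, function(tr) mean(tr$loglik), numeric(1))
  score[is.nan(score)] <- -Inf
  ord <- order(score, decreasing = TRUE)   # stable: ties by index
  idx <- ord[seq_len(keep)]
  if (indices) idx else chains[idx]
}

#' Deviance information criterion
#'
#' DIC = mean(D) + pD with the effective number of parameters pD estimated
#' as half the posterior variance of the deviance (sample variance, n-1
#' denominator). Deviance here is -2 times the conditional Poisson
#' log-likelihood, pooled with equal weight across retained chains.
#'
#' @param x numeric vector of deviance draws, a `"hbfm_chain"`, or a list
#'   of chains (pooled).
#' @return the DIC, a finite scalar.
#' @export
dic <- function(x) {
  if (inherits(x, "hbfm_chain")) x <- x$deviance
  if (is.list(x)) x <- unlist(lapply(x, function(tr)
    if (inherits(tr, "hbfm_chain")) tr$deviance else tr))
  x <- as.numeric(x)
  if (length(x) < 2L) stop("DIC needs at least two deviance samples")
  mean(x) + stats::var(x) / 2
}

#' Select the number of factors by DIC
#'
#' Fits the model for each F in `F_grid` and returns the fit with the
#' lowest DIC. If the grid maximum wins, the grid is automatically extended
#' once by `extend_by` and the comparison repeated, so a boundary optimum
#' is double-checked.
#'
#' @param Y count matrix.
#' @param F_grid integer vector of candidate factor numbers.
#' @param ... passed on to [hbfm()] (`n_chains`, `control`, ...).
#' @param extend_by grid extension step when the maximum wins (default 3).
#' @param seed root seed; each F reuses it so runs differ only in F.
#' @param verbose print per-F progress.
#' @return object of class `"hbfm_select"`: list with `best` (the winning
#'   `"hbfm"` fit), `table` (data.frame of F, DIC and per-chain mean
#'   log-likelihoods), `extended` (logical).
#' @export
hbfm_select <- function(Y, F_grid, ..., extend_by = 3, seed = 1,
                        verbose = FALSE) {
  F_grid <- sort(unique(as.integer(F_grid)))
  stopifnot(length(F_grid) >= 1, all(F_grid >= 1))
  fits <- list()
  run_one <- function(F_) {
    if (verbose) message("fitting F = ", F_)
    hbfm(Y, n_factors = F_, seed = seed, verbose = verbose, ...)
  }
  for (F_ in F_grid) fits[[as.character(F_)]] <- run_one(F_)
  dics <- vapply(fits, `[[`, numeric(1), "dic")
  extended <- FALSE
  if (length(F_grid) > 1L &&
      F_grid[which.min(dics)] == max(F_grid)) {
    Fx <- max(F_grid) + as.integer(extend_by)
    fits[[as.character(Fx)]] <- run_one(Fx)
    F_grid <- c(F_grid, Fx)
    dics <- vapply(fits, `[[`, numeric(1), "dic")
    extended <- TRUE
  }
  tab <- data.frame(
    F = F_grid,
    dic = unname(dics),
    mean_loglik = vapply(fits, function(f)
      mean(f$chain_loglik[f$kept]), numeric(1)))
  best <- fits[[which.min(dics)]]
  structure(list(best = best, table = tab, fits = fits,
                 extended = extended),
            class = "hbfm_select")
}

#' @export
print.hbfm_select <- function(x, ...) {
  cat("Factor-number selection by DIC\n")
  print(x$table, row.names = FALSE)
  cat("selected F =", x$best$n_factors,
      if (x$extended) "(grid was extended once at the boundary)" else "",
      "\n")
  invisible(x)
}

#' Write a per-F DIC table and a JSON run manifest
#'
#' @param x an `"hbfm_select"` object.
#' @param csv path for the CSV table (F, DIC, mean kept log-likelihood).
#' @param manifest optional path for a JSON manifest echoing seeds and
#'   configuration.
#' @return `csv`, invisibly.
#' @export
write_selection <- function(x, csv, manifest = NULL) {
  stopifnot(inherits(x, "hbfm_select"))
  utils::write.csv(x$table, csv, row.names = FALSE)
  if (!is.null(manifest)) {
    best <- x$best
    jsonlite::write_json(list(
      selected_F = best$n_factors,
      extended = x$extended,
      n_chains = best$n_chains, n_keep = best$n_keep,
      seed = best$seed,
      chain_seeds = vapply(best$chains, `[[`, numeric(1), "seed"),
      control = unclass(best$control),
      dic_table = x$table), manifest, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}

#' Posterior predictive datasets
#'
#' Draws `nsim` replicate count matrices from the fitted model: each
#' replicate takes the (beta, alpha, phi) configuration of one retained
#' sweep of one kept chain (uniformly at random), redraws the factor scores
#' lambda from their Lognormal(0, phi_f) prior, forms the Poisson means and
#' samples counts. Summaries record each replicate's per-gene mean,
#' variance and proportion of zeros.
#'
#' @param object a fitted `"hbfm"` model.
#' @param nsim number of posterior predictive datasets (default 100).
#' @param seed optional seed.
#' @param ... unused.
#' @return object of class `"hbfm_ppd"`: list with `datasets` (list of
#'   count matrices) and `summary` (data.frame with columns ppd, gene,
#'   mean, variance, zero_prop).
#' @export
simulate.hbfm <- function(object, nsim = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  G <- object$G; N <- object$N
  kept <- object$kept
  datasets <- vector("list", nsim)
  summaries <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    tr <- object$chains[[sample(kept, 1L)]]
    m <- sample(length(tr$loglik), 1L)
    beta <- tr$beta[m, ]
    alpha <- tr$alpha[, , m]
    phi <- tr$phi[m, ]
    lambda <- matrix(exp(stats::rnorm(N * length(phi)) *
                           rep(sqrt(phi), each = N)), N, length(phi))
    st <- hbfm_state(beta, alpha, lambda, phi)
    mu <- factor_mean(st)
    yrep <- matrix(stats::rpois(G * N, mu), G, N,
                   dimnames = list(object$gene_ids, NULL))
    datasets[[s]] <- yrep
    summaries[[s]] <- data.frame(
      ppd = s, gene = rownames(yrep) %||% seq_len(G),
      mean = rowMeans(yrep),
      variance = apply(yrep, 1, stats::var),
      zero_prop = rowMeans(yrep == 0), row.names = NULL)
  }
  structure(list(datasets = datasets,
                 summary = do.call(rbind, summaries)),
            class = "hbfm_ppd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hbfm_ppd <- function(x, ...) {
  cat("Posterior predictive datasets:", length(x$datasets), "replicates\n")
  od <- with(x$summary, mean(log(variance / mean) > 0, na.rm = TRUE))
  cat(sprintf("  gene-replicate pairs with variance > mean: %.1f%%\n",
              100 * od))
  invisible(x)
}
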