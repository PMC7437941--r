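#' @export
print.hbfm <- function(x, ...) {
  cat("Sparse hierarchical Bayesian factor model fit\n")
  cat("  G =", x$G, "genes, N =", x$N, "cells, F =", x$n_factors,
      "factors\n")
  cat("  chains:", x$n_chains, "run,", length(x$kept),
      "kept (by mean retained log-likelihood)\n")
  cat("  DIC:", format(x$dic, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.hbfm <- function(object, level = 0.95, ...) {
  cp <- correlations(object, level)
  net <- gcn(cp, level)
  structure(list(fit = object, corr = cp, network = net, level = level),
            class = "summary.hbfm")
}

#' @export
print.summary.hbfm <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$corr)
  cat("\n")
  print(x$network)
  invisible(x)
}

#' Posterior mean parameter estimates
#'
#' @param object a fitted `"hbfm"`.
#' @param ... unused.
#' @return list with `beta` (posterior mean baseline rates, pooled over
#'   kept chains), `phi`, `theta` and `rho` (posterior mean log-mean
#'   correlation matrix).
#' @export
coef.hbfm <- function(object, ...) {
  kept <- object$chains[object$kept]
  pool <- function(field) do.call(rbind, lapply(kept, `[[`, field))
  list(beta = stats::setNames(colMeans(pool("beta")), object$gene_ids),
       phi = colMeans(pool("phi")),
       theta = colMeans(pool("theta")),
       rho = correlations(object)$rho_hat)
}

#' Marginal fitted means
#'
#' With the factor scores integrated out, E(Y_gi) = beta_g; the fitted
#' value for every cell of gene g is the posterior mean of beta_g.
#'
#' @param object a fitted `"hbfm"`.
#' @param ... unused.
#' @return G x N matrix.
#' @export
fitted.hbfm <- function(object, ...) {
  b <- coef(object)$beta
  matrix(b, object$G, object$N, dimnames = list(object$gene_ids, NULL))
}

#' Pearson residuals under the marginal moments
#'
#' (y_gi - beta_g) / sd_g with the marginal standard deviation from
#' [marginal_moments()] evaluated at the posterior means (modal loadings).
#'
#' @param object a fitted `"hbfm"`.
#' @param Y the count matrix the model was fitted to.
#' @param ... unused.
#' @return G x N matrix of residuals.
#' @export
residuals.hbfm <- function(object, Y, ...) {
  Y <- as_counts(Y)
  stopifnot(nrow(Y) == object$G, ncol(Y) == object$N)
  est <- coef(object)
  best <- object$chains[[object$kept[1L]]]
  # modal loadings over the best chain's retained sweeps
  amode <- apply(best$alpha, c(1, 2), function(v) {
    tab <- tabulate(v + 2L, 3L)
    c(-1L, 0L, 1L)[which.max(tab)]
  })
  sdv <- vapply(seq_len(object$G), function(g)
    sqrt(marginal_moments(est$beta[g], amode[g, ], est$phi)["variance"]),
    numeric(1))
  (Y - est$beta) / sdv
}

#' Heatmap of the posterior mean correlation structure
#'
#' @param x a fitted `"hbfm"` or an `"hbfm_corr"`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.hbfm <- function(x, ...) {
  cp <- if (inherits(x, "hbfm_corr")) x else correlations(x)
  G <- length(cp$gene_ids)
  pal <- grDevices::hcl.colors(41, "Blue-Red 3")
  graphics::image(seq_len(G), seq_len(G),
                  t(cp$rho_hat[G:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "gene", ylab = "gene", ...)
  graphics::box()
  invisible(cp$rho_hat)
}

#' @export
plot.hbfm_corr <- plot.hbfm
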