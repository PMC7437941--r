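#' Posterior summaries of the log-mean correlation matrix
#'
#' Pools the retained correlation draws of the kept chains (equal weight)
#' and, for every gene pair, computes the posterior mean rho-hat, an
#' equal-tailed credible interval at the requested level, and the
#' approximate p-value a* — the size of the smallest equal-tailed credible
#' interval containing zero (see [approx_pvalue()]).
#'
#' @param fit a fitted `"hbfm"` object, a single `"hbfm_chain"`, or a list
#'   of chains.
#' @param level credible level 1 - alpha* (default 0.95).
#' @return object of class `"hbfm_corr"`: symmetric G x G matrices
#'   `rho_hat`, `ci_lo`, `ci_hi`, `approx_p`, plus `level`, `M` (pooled
#'   sample count) and `gene_ids`.
#' @export
correlations <- function(fit, level = 0.95) {
  chains <- if (inherits(fit, "hbfm")) fit$chains[fit$kept]
            else if (inherits(fit, "hbfm_chain")) list(fit)
            else fit
  stopifnot(length(chains) >= 1, level > 0, level < 1)
  rho <- do.call(rbind, lapply(chains, `[[`, "rho"))
  M <- nrow(rho)
  if (M == 0L) stop("no retained correlation samples")
  G <- chains[[1L]]$G
  gene_ids <- chains[[1L]]$gene_ids %||% paste0("gene", seq_len(G))
  a <- 1 - level
  qs <- apply(rho, 2L, stats::quantile, probs = c(a / 2, 1 - a / 2),
              names = FALSE)
  p <- apply(rho, 2L, approx_pvalue)
  unpack <- function(v, diag_val) {
    m <- matrix(diag_val, G, G, dimnames = list(gene_ids, gene_ids))
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  structure(list(rho_hat = unpack(colMeans(rho), 1),
                 ci_lo = unpack(qs[1L, ], 1),
                 ci_hi = unpack(qs[2L, ], 1),
                 approx_p = unpack(p, 0),
                 level = level, M = M, gene_ids = gene_ids),
            class = "hbfm_corr")
}

#' @export
print.hbfm_corr <- function(x, ...) {
  G <- length(x$gene_ids)
  cat("Posterior correlation summary:", G, "genes,", x$M,
      "pooled samples, level", x$level, "\n")
  sig <- sum(x$ci_lo[lower.tri(x$ci_lo)] > 0 |
               x$ci_hi[lower.tri(x$ci_hi)] < 0)
  cat("  pairs with CI excluding 0:", sig, "of", G * (G - 1) / 2, "\n")
  invisible(x)
}

#' Approximate p-value from posterior correlation samples
#'
#' a* is the size of the smallest equal-tailed credible interval that
#' contains zero: `a* = 2 * min(#samples < 0, #samples > 0) / M`, clipped
#' to [0, 1]. It is 0 when every sample shares one strict sign and is used
#' to rank gene pairs by significance.
#'
#' @param samples numeric vector of posterior draws for one pair.
#' @return scalar in [0, 1].
#' @export
approx_pvalue <- function(samples) {
  M <- length(samples)
  stopifnot(M >= 1)
  min(1, 2 * min(sum(samples < 0), sum(samples > 0)) / M)
}

#' Build the gene co-expression network from credible intervals
#'
#' A pair (g, g') is an edge when zero is excluded from its 100(1-alpha*)%
#' equal-tailed credible interval; the edge sign is the sign of the
#' posterior mean. Raising `level` can only remove edges (equal-tailed
#' intervals are nested).
#'
#' @param x an `"hbfm_corr"` summary or a fitted `"hbfm"` object.
#' @param level credible level (default 0.95; re-summarizes if `x` is a
#'   fit or was summarized at another level).
#' @return object of class `"gcn"`: data.frame with one row per edge
#'   (columns gene_a, gene_b, rho_hat, approx_p, sign), attributes `level`
#'   and `genes`.
#' @export
gcn <- function(x, level = 0.95) {
  if (inherits(x, "hbfm")) x <- correlations(x, level)
  stopifnot(inherits(x, "hbfm_corr"))
  if (!isTRUE(all.equal(x$level, level))) {
    stop("summary was computed at level ", x$level,
         "; recompute with correlations(fit, level)")
  }
  G <- length(x$gene_ids)
  lt <- which(lower.tri(x$rho_hat), arr.ind = TRUE)
  lo <- x$ci_lo[lt]; hi <- x$ci_hi[lt]
  is_edge <- lo > 0 | hi < 0
  edges <- data.frame(
    gene_a = x$gene_ids[lt[is_edge, 2L]],
    gene_b = x$gene_ids[lt[is_edge, 1L]],
    rho_hat = x$rho_hat[lt][is_edge],
    approx_p = x$approx_p[lt][is_edge],
    sign = sign(x$rho_hat[lt][is_edge]),
    stringsAsFactors = FALSE)
  structure(edges, level = level, genes = x$gene_ids, class = c("gcn", "data.frame"))
}

#' @export
print.gcn <- function(x, ...) {
  cat("Gene co-expression network:", nrow(x), "edges among",
      length(attr(x, "genes")), "genes (level",
      attr(x, "level"), ")\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more edges\n")
  invisible(x)
}

# canonical unordered pair keys
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

#' Evaluate an estimated network against a known truth
#'
#' TPR = TP / |truth|; FDR = FP / max(1, #edges). The AUC ranks every
#' unordered gene pair by the inverse approximate p-value (so smaller a* is
#' stronger evidence), with ties broken by |rho-hat| and remaining ties by
#' average rank, and is computed as the rank-sum (Mann-Whitney) statistic
#' against the truth labels.
#'
#' @param net a `"gcn"` (or data.frame with gene_a, gene_b).
#' @param truth true edges: a two-column data.frame/matrix of gene pairs.
#' @param cp an `"hbfm_corr"` summary supplying the full approx_p and
#'   rho-hat matrices for the AUC ranking; if `NULL`, AUC is `NA`.
#' @return named numeric vector `c(tpr=, fdr=, auc=, n_edges=)`.
#' @export
evaluate_gcn <- function(net, truth, cp = NULL) {
  truth <- as.data.frame(truth)
  if (nrow(truth) == 0L) stop("empty truth set: TPR undefined")
  tkey <- pair_key(truth[[1L]], truth[[2L]])
  ekey <- if (nrow(net) > 0L) pair_key(net$gene_a, net$gene_b) else character()
  tp <- sum(ekey %in% tkey)
  tpr <- tp / length(unique(tkey))
  fdr <- (length(ekey) - tp) / max(1L, length(ekey))
  auc <- NA_real_
  if (!is.null(cp)) {
    stopifnot(inherits(cp, "hbfm_corr"))
    genes <- cp$gene_ids
    lt <- which(lower.tri(cp$approx_p), arr.ind = TRUE)
    keys <- pair_key(genes[lt[, 1L]], genes[lt[, 2L]])
    labels <- keys %in% tkey
    p <- cp$approx_p[lt]
    arho <- abs(cp$rho_hat[lt])
    # composite score: primary -p (a* is a multiple of 2/M >> 1e-6), then
    # |rho| as tie-break; exact remaining ties get averaged ranks
    r <- rank(-p + arho * 1e-6, ties.method = "average")
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L) stop("degenerate truth labelling for AUC")
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(tpr = tpr, fdr = fdr, auc = auc, n_edges = length(ekey))
}

#' Export a network as an edge-list CSV or GraphML file
#'
#' @param net a `"gcn"`.
#' @param path output file.
#' @param format `"csv"` (edge list: gene_a, gene_b, rho_hat, approx_p,
#'   sign) or `"graphml"`; default from the extension.
#' @return `path`, invisibly.
#' @export
export_gcn <- function(net, path, format = c("auto", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "csv"
  df <- as.data.frame(net)[, c("gene_a", "gene_b", "rho_hat",
                               "approx_p", "sign"), drop = FALSE]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                       vertices = attr(net, "genes"))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from CSV or GraphML
#'
#' Round-trips the files written by [export_gcn()].
#'
#' @param path file to read.
#' @param format `"csv"` or `"graphml"` (default from extension).
#' @return a `"gcn"` data.frame.
#' @export
read_gcn <- function(path, format = c("auto", "csv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    genes <- sort(unique(c(df$gene_a, df$gene_b)))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    names(df)[1:2] <- c("gene_a", "gene_b")
    genes <- igraph::V(g)$name %||% igraph::V(g)$id
  }
  structure(as.data.frame(df), genes = genes, class = c("gcn", "data.frame"))
}
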