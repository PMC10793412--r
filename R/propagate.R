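#' Weighted gene co-expression network container
#'
#' @param genes Character vector of node names.
#' @param W Symmetric numeric weight matrix in `[0, 1]` over `genes`.
#' @param kind `"adjacency"` (zero diagonal) or `"tom"` (unit diagonal).
#' @return Object of class `weighted_network`.
#' @export
weighted_network <- function(genes, W, kind = c("adjacency", "tom")) {
  kind <- match.arg(kind)
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop2("'W' must be square")
  if (length(genes) != nrow(W)) stop2("'genes' must match the matrix dimension")
  if (max(abs(W - t(W))) > 1e-12) stop2("weight matrix must be symmetric")
  if (min(W) < -1e-12 || max(W) > 1 + 1e-12)
    stop2("weights must lie in [0, 1]")
  expected_diag <- if (kind == "adjacency") 0 else 1
  if (max(abs(diag(W) - expected_diag)) > 1e-12)
    stop2("%s matrix must have diagonal %g", kind, expected_diag)
  dimnames(W) <- list(genes, genes)
  structure(list(genes = genes, W = W, kind = kind),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  up <- x$W[upper.tri(x$W)]
  cat(sprintf("weighted_network (%s): %d genes, mean off-diagonal weight %.4g\n",
              x$kind, length(x$genes), mean(up)))
  invisible(x)
}

#' Signed-free soft-threshold adjacency
#'
#' WGCNA-style unsigned soft adjacency from a genes x cells (or genes x
#' samples) expression matrix: \eqn{a_{ij} = |cor(i, j)|^\beta} with zero
#' diagonal. Genes with zero variance are dropped with a warning.
#'
#' @param expr Numeric genes x cells matrix with rownames (e.g. the
#'   normalized layer of one cell type), or an [sc_dataset()] restricted
#'   beforehand.
#' @param beta Soft-threshold exponent, >= 1 (default 8).
#' @return A [weighted_network()] of kind `"adjacency"`.
#' @export
soft_adjacency <- function(expr, beta = 8) {
  if (inherits(expr, "sc_dataset")) {
    if (is.null(expr$normalized)) expr <- sc_normalize(expr)
    expr <- expr$normalized
  }
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop2("'expr' must be a genes x cells matrix with rownames")
  if (beta < 1) stop2("'beta' must be >= 1")
  if (ncol(expr) < 3L) stop2("need at least 3 cells")
  v <- row_vars(expr)
  drop <- v == 0 | !is.finite(v)
  if (any(drop)) {
    warn2("%d zero-variance gene(s) dropped from the network", sum(drop))
    expr <- expr[!drop, , drop = FALSE]
  }
  if (nrow(expr) < 3L) stop2("fewer than 3 usable genes")
  A <- abs(stats::cor(t(expr)))^beta
  diag(A) <- 0
  weighted_network(rownames(expr), A, "adjacency")
}

#' Topological overlap matrix
#'
#' Smooths an adjacency by shared-neighbor structure:
#' \eqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} for \eqn{i \ne j} with connectivity
#' \eqn{k_i = \sum_u a_{iu}}, and \eqn{TOM_{ii} = 1}.
#'
#' @param adj A [weighted_network()] of kind `"adjacency"`.
#' @return A [weighted_network()] of kind `"tom"`.
#' @export
tom_matrix <- function(adj) {
  stopifnot(inherits(adj, "weighted_network"))
  if (adj$kind != "adjacency") stop2("input must be an adjacency network")
  A <- adj$W
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  TOM <- (TOM + t(TOM)) / 2   # symmetrize away float asymmetry
  weighted_network(adj$genes, TOM, "tom")
}

#' Percentile-threshold network edges
#'
#' Computes the given percentile of the strictly-upper-triangle weights
#' (linear-interpolation quantile) and keeps only edges strictly above it,
#' zeroing the rest. Kept edges retain their weights.
#'
#' @param net A [weighted_network()].
#' @param percentile Percentile in (0, 100), default 90.
#' @return A `weighted_network` of the same kind with sub-threshold weights
#'   zeroed (diagonal preserved) and an `edges` element (`data.frame`:
#'   `from`, `to`, `weight`).
#' @export
threshold_edges <- function(net, percentile = 90) {
  stopifnot(inherits(net, "weighted_network"))
  if (percentile <= 0 || percentile >= 100)
    stop2("'percentile' must lie in (0, 100)")
  W <- net$W
  up <- W[upper.tri(W)]
  thr <- stats::quantile(up, percentile / 100, names = FALSE, type = 7)
  keep <- W > thr
  diag(keep) <- FALSE
  if (!any(keep)) warn2("no edge above the %g-th percentile", percentile)
  W2 <- W * keep
  diag(W2) <- diag(net$W)
  out <- weighted_network(net$genes, W2, net$kind)
  iu <- which(upper.tri(W) & keep, arr.ind = TRUE)
  out$edges <- data.frame(from = net$genes[iu[, 1L]], to = net$genes[iu[, 2L]],
                          weight = W[iu], stringsAsFactors = FALSE)
  out$threshold <- thr
  out
}

#' Random walk with restart
#'
#' Network propagation from a set of seed genes: with the column-normalized
#' weight matrix W (dangling nodes receive a self-loop), restart
#' distribution \eqn{p_0} uniform over the seeds and restart probability r,
#' iterates \eqn{p \leftarrow (1 - r) W p + r p_0} until the L1 change
#' falls below `tol`. The steady state scores every gene's network
#' proximity to the seeds and sums to 1.
#'
#' @param net A [weighted_network()] (typically thresholded TOM). Diagonal
#'   entries are ignored; only off-diagonal weights carry the walk.
#' @param seeds Character vector of seed genes present in the network.
#' @param r Restart probability in (0, 1] (default 0.7).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1e4).
#' @return Object of class `rwr_result`: `p` (named steady-state vector),
#'   `seeds`, `r`, `iterations`, `converged`.
#' @export
rwr <- function(net, seeds, r = 0.7, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "weighted_network"))
  if (r <= 0 || r > 1) stop2("'r' must lie in (0, 1]")
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, net$genes)
  if (length(missing)) stop2("seed(s) absent from the network: %s",
                             paste(missing, collapse = ", "))
  W <- net$W
  diag(W) <- 0
  if (all(W == 0)) stop2("network has no edge")
  cs <- colSums(W)
  dangling <- cs == 0
  if (any(dangling)) {
    diag(W)[dangling] <- 1
    cs[dangling] <- 1
  }
  W <- sweep(W, 2, cs, "/")
  n <- length(net$genes)
  p0 <- stats::setNames(numeric(n), net$genes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- (1 - r) * as.numeric(W %*% p) + r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop2("RWR did not converge within %d iterations (last L1 change %g)",
          max_iter, delta)
  p <- p / sum(p)
  names(p) <- net$genes
  structure(list(p = p, seeds = seeds, r = r, iterations = iter,
                 converged = converged),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("rwr_result: %d genes, %d seeds, r = %g, %d iterations\n",
              length(x$p), length(x$seeds), x$r, x$iterations))
  top <- utils::head(sort(x$p[setdiff(names(x$p), x$seeds)], decreasing = TRUE), 5)
  cat("  top non-seed genes:",
      paste(sprintf("%s (%.3g)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Top propagation neighbors
#'
#' The k non-seed genes with the highest steady-state probability,
#' descending, ties broken lexicographically.
#'
#' @param result An [rwr()] result.
#' @param k Number of neighbors (>= 1), default 30.
#' @return Character vector of at most `min(k, non-seed genes)` genes.
#' @export
top_neighbors <- function(result, k = 30L) {
  stopifnot(inherits(result, "rwr_result"))
  if (k < 1L) stop2("'k' must be >= 1")
  p <- result$p[setdiff(names(result$p), result$seeds)]
  ord <- order(-p, names(p))
  utils::head(names(p)[ord], k)
}

#' Functional enrichment of propagation neighbors
#'
#' Convenience wrapper running [ora_hypergeom()] on a neighbor gene list.
#'
#' @param neighbors Non-empty character vector (e.g. from
#'   [top_neighbors()]).
#' @param collection A [gene_set_collection()].
#' @param universe Background gene universe.
#' @return An [ora_hypergeom()] result.
#' @export
neighbor_enrichment <- function(neighbors, collection, universe) {
  if (!length(neighbors)) stop2("neighbor list is empty")
  ora_hypergeom(neighbors, collection, universe)
}

#' Scale-free fit helper for the soft-threshold exponent
#'
#' Scans candidate exponents and reports the R^2 of the log-log linear fit
#' of the (binned) degree distribution of the resulting adjacency, the
#' usual scale-free topology criterion for picking beta.
#'
#' @param expr Genes x cells matrix (or [sc_dataset()]).
#' @param betas Candidate exponents (default 1:20).
#' @param n_bins Histogram bins for the connectivity distribution.
#' @return `data.frame`: `beta`, `r_squared`, `mean_connectivity`.
#' @export
fit_scale_free_beta <- function(expr, betas = 1:20, n_bins = 10L) {
  rows <- lapply(betas, function(b) {
    net <- suppressWarnings(soft_adjacency(expr, beta = b))
    k <- rowSums(net$W)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- as.numeric(table(bin)) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    r2 <- if (sum(ok) >= 3L)
      summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared else NA_real_
    data.frame(beta = b, r_squared = r2, mean_connectivity = mean(k))
  })
  do.call(rbind, rows)
}
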