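#' Hypergeometric over-representation analysis
#'
#' Tests every set in a collection for over-representation of a query gene
#' list against an all-gene background: with universe size N, set size K
#' (restricted to the universe), query size n and overlap k, the p-value is
#' the upper tail \eqn{P[X \ge k]}, \eqn{X \sim Hypergeom(N, K, n)}.
#' Benjamini-Hochberg correction is applied over all tested sets and rows
#' are sorted by (q, p, set name) so a deterministic top-30 can be cut.
#'
#' @param query Character vector of genes of interest; genes outside the
#'   universe are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector: the background gene universe.
#' @return `data.frame` of class `ora_result`: `set`, `k`, `K`, `n`, `N`,
#'   `p`, `q`.
#' @export
ora_hypergeom <- function(query, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop2("universe must be non-empty")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn2("%d query gene(s) outside the universe dropped", length(outside))
    query <- setdiff(query, outside)
  }
  N <- length(universe); n <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Extract the top enriched rows of an enrichment table
#'
#' @param res Result table with `q`, `p` and a name column (`set`).
#' @param n Number of rows to keep (default 30).
#' @return The first `n` rows after the deterministic (q, p, name) sort.
#' @export
top_enriched <- function(res, n = 30L) {
  res <- res[order(res$q, res$p, res$set), , drop = FALSE]
  utils::head(res, n)
}

# running-sum enrichment score given sorted |scores| and hit positions.
# s_abs: |score| in rank order; pos: sorted hit ranks. Weight exponent 1.
# Returns list(es, at) where `at` is the rank of the extremum.
es_from_positions <- function(s_abs, pos) {
  N <- length(s_abs)
  m <- length(pos)
  hit_w <- s_abs[pos]
  tot <- sum(hit_w)
  if (tot == 0) hit_w <- rep(1 / m, m) else hit_w <- hit_w / tot
  H <- cumsum(hit_w)
  miss <- 1 / (N - m)
  # value just after hit i, and just before hit i
  after <- H - (pos - seq_len(m)) * miss
  before <- c(0, H[-m]) - (pos - 1 - (seq_len(m) - 1)) * miss
  hi <- max(after); lo <- min(before)
  if (hi >= -lo) list(es = hi, at = pos[which.max(after)])
  else list(es = lo, at = pos[which.min(before)])
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA on a preranked gene
#' list. Genes are sorted by score (descending, ties broken by gene name so
#' results are deterministic); walking down the list, set members add
#' \eqn{|s_i| / \sum_{set} |s|} and non-members subtract \eqn{1/(N - |S|)};
#' the enrichment score ES is the signed extremum of the running sum. The
#' null is generated by gene-label permutation: random sets of the same size
#' drawn from the ranked genes. NES divides ES by the mean |null ES| of the
#' same sign and the permutation p-value is
#' \eqn{(1 + \#\{ |ES_{null}| \ge |ES|, same sign \}) / (1 + n_{same sign})}.
#'
#' @param ranks Named numeric vector: gene -> ranking score (no NAs).
#' @param set Character vector of member genes; must intersect the ranked
#'   genes.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @return One-row `data.frame`: `es`, `nes`, `p`, `n_perm`, plus a
#'   `leading_edge` list-column of the genes driving the ES.
#' @export
gsea_preranked <- function(ranks, set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(ranks)) || anyNA(ranks))
    stop2("'ranks' must be a named numeric vector without NAs")
  if (length(ranks) < 2L) stop2("need at least 2 ranked genes")
  ord <- order(-ranks, names(ranks))
  genes <- names(ranks)[ord]
  s_abs <- abs(as.numeric(ranks)[ord])
  N <- length(genes)
  pos <- which(genes %in% set)
  m <- length(pos)
  if (m == 0L) stop2("gene set is disjoint from the ranked genes")
  if (m == N) stop2("gene set covers every ranked gene; ES undefined")
  obs <- es_from_positions(s_abs, pos)
  es <- obs$es
  # leading edge: members at or before (after, for negative ES) the extremum
  le <- if (es >= 0) genes[pos[pos <= obs$at]] else genes[pos[pos >= obs$at]]
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    es_from_positions(s_abs, sort.int(sample.int(N, m)))$es
  }, numeric(1)))
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  n_same <- length(same)
  nes <- if (n_same > 0 && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + n_same)
  out <- data.frame(es = es, nes = nes, p = p, n_perm = n_perm)
  out$leading_edge <- list(le)
  out
}

#' GSEA over a whole collection
#'
#' Runs [gsea_preranked()] for every set with at least `min_size` members
#' among the ranked genes and BH-adjusts the permutation p-values.
#'
#' @param ranks Named numeric score vector.
#' @param collection A [gene_set_collection()].
#' @param n_perm Permutations per set.
#' @param seed Integer seed; set i uses `seed + i` so sets are independent
#'   but reproducible.
#' @param min_size Minimum member count among ranked genes (default 2).
#' @return `data.frame` of class `gsea_result`: `set`, `es`, `nes`, `p`,
#'   `q`, `leading_edge`.
#' @export
gsea_collection <- function(ranks, collection, n_perm = 1000L, seed = 1L,
                            min_size = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  keep <- vapply(collection$sets,
                 function(s) sum(names(ranks) %in% s) >= min_size, logical(1))
  sets <- collection$sets[keep]
  if (!length(sets)) stop2("no set has >=%d members among the ranked genes", min_size)
  rows <- lapply(seq_along(sets), function(i)
    gsea_preranked(ranks, sets[[i]], n_perm = n_perm, seed = seed + i))
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(set = names(sets), stringsAsFactors = FALSE), res)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$set),
             c("set", "es", "nes", "p", "q", "n_perm", "leading_edge")]
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  res
}

#' Wilcoxon rank-sum test
#'
#' Mann-Whitney U with midranks for ties. The p-value is exact (by
#' enumeration) when \eqn{n_x + n_y \le 12} and there are no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' correction. Thin wrapper over [stats::wilcox.test()], which implements
#' exactly these conventions; shared by the bulk dual post-hoc test and the
#' single-cell marker test.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (statistic for `x`) and two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop2("both vectors must be non-empty")
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # all observations tied: no evidence either way
  list(U = unname(ht$statistic), p = min(1, p))
}

#' Dual post-hoc test linking glycosylation pathways to enriched pathways
#'
#' For every (glycosylation pathway, enriched pathway) pair runs two tests:
#' (1) a hypergeometric test of the glyco-pathway's members within the
#' enriched pathway against the all-gene meta-analysis universe, and (2) a
#' Wilcoxon rank-sum test comparing |combined effect size| of the enriched
#' pathway's glyco-members against its other members (switchable to the
#' genome background). P-values are BH-adjusted within each test family and
#' a pair passes iff both q-values are at or below `fdr` (inclusive).
#'
#' @param enriched A [gene_set_collection()] of already-significant
#'   pathways.
#' @param glyco A [glycogene_table()]; its pathway groups are the glyco
#'   side of each pair.
#' @param effect_table A [meta_differential_expression()] result covering
#'   the genes involved.
#' @param fdr Significance threshold on both q-values (default 0.05).
#' @param wilcoxon_background `"pathway"` (default: other members of the
#'   enriched pathway) or `"genome"` (all other meta-analyzed genes).
#' @return `data.frame`: `glyco_pathway`, `enriched_set`, `k`, `p_hyper`,
#'   `q_hyper`, `p_wilcox`, `q_wilcox`, `pass`.
#' @export
glyco_posthoc_dual_test <- function(enriched, glyco, effect_table, fdr = 0.05,
                                    wilcoxon_background = c("pathway", "genome")) {
  stopifnot(inherits(enriched, "gene_set_collection"),
            inherits(glyco, "glycogene_table"))
  wilcoxon_background <- match.arg(wilcoxon_background)
  universe <- unique(effect_table$gene)
  if (!length(universe)) stop2("effect table is empty")
  abs_eff <- abs(effect_table$mu)
  names(abs_eff) <- effect_table$gene
  N <- length(universe)
  gp <- split(glyco$gene, glyco$pathway)
  rows <- list()
  for (gname in names(gp)) {
    gmem <- intersect(gp[[gname]], universe)
    if (length(gmem) < 1L) {
      warn2("glyco pathway '%s' has no member in the universe; skipped", gname)
      next
    }
    K <- length(gmem)
    for (sname in names(enriched$sets)) {
      smem <- intersect(enriched$sets[[sname]], universe)
      n <- length(smem)
      k <- length(intersect(gmem, smem))
      p_h <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      in_glyco <- intersect(smem, gmem)
      background <- switch(wilcoxon_background,
                           pathway = setdiff(smem, gmem),
                           genome = setdiff(universe, gmem))
      p_w <- if (length(in_glyco) && length(background))
        wilcoxon_rank_sum(abs_eff[in_glyco], abs_eff[background])$p else 1
      rows[[length(rows) + 1L]] <- data.frame(
        glyco_pathway = gname, enriched_set = sname, k = k,
        p_hyper = p_h, p_wilcox = p_w, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop2("no testable (glyco pathway, enriched set) pair")
  res <- do.call(rbind, rows)
  res$q_hyper <- bh_fdr(res$p_hyper)
  res$q_wilcox <- bh_fdr(res$p_wilcox)
  res$pass <- res$q_hyper <= fdr & res$q_wilcox <= fdr
  res[, c("glyco_pathway", "enriched_set", "k", "p_hyper", "q_hyper",
          "p_wilcox", "q_wilcox", "pass")]
}
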