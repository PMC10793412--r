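#' End-to-end functional hub glycogene discovery
#'
#' Chains the bulk stages of the workflow: (1) random-effects meta-analysis
#' of all genes to obtain per-gene combined effect sizes; (2) a
#' glycogene-restricted meta-analysis to flag DE glycogenes; (3) preranked
#' GSEA of the pathway collection on the combined effect sizes, keeping
#' pathways with q below `fdr`; (4) the pathway-glycogene bipartite graph
#' over the enriched pathways and DE glycogenes; (5) degree ranking and hub
#' selection.
#'
#' @param cohorts List of [expr_matrix()] objects.
#' @param collection A [gene_set_collection()] of candidate pathways.
#' @param glycogenes A [glycogene_table()].
#' @param fdr Threshold for both DEG flagging and pathway enrichment
#'   (default 0.05).
#' @param gsea_n_perm Permutations per pathway (default 500).
#' @param seed Integer seed for the GSEA permutation nulls.
#' @param method `tau^2` estimator for the meta-analyses.
#' @return List: `meta_all`, `meta_glyco`, `gsea`, `enriched`
#'   (significant-set collection), `de_glycogenes`, `graph`, `ranking`,
#'   `hub` (or `NULL` when no DE glycogene sits in an enriched pathway).
#' @export
hub_discovery <- function(cohorts, collection, glycogenes, fdr = 0.05,
                          gsea_n_perm = 500L, seed = 1L,
                          method = c("REML", "DL")) {
  method <- match.arg(method)
  meta_all <- meta_differential_expression(cohorts, method = method, fdr = fdr)
  meta_glyco <- suppressWarnings(
    meta_differential_expression(cohorts, glycogenes, method = method, fdr = fdr))
  de_glyco <- meta_glyco$gene[meta_glyco$is_deg]
  ranks <- stats::setNames(meta_all$mu, meta_all$gene)
  gsea <- gsea_collection(ranks, collection, n_perm = gsea_n_perm, seed = seed)
  sig <- gsea$set[gsea$q < fdr]
  out <- list(meta_all = meta_all, meta_glyco = meta_glyco, gsea = gsea,
              de_glycogenes = de_glyco, enriched = NULL, graph = NULL,
              ranking = NULL, hub = NULL)
  if (!length(sig) || !length(de_glyco)) return(out)
  out$enriched <- subset_sets(collection, sig)
  out$graph <- suppressWarnings(build_bipartite(out$enriched, de_glyco))
  if (!length(out$graph$genes)) return(out)
  out$ranking <- rank_by_degree(out$graph)
  out$hub <- select_hub(out$graph)
  out
}
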