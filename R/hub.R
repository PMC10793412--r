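#' Pathway-glycogene bipartite graph
#'
#' Builds the two-part graph linking significantly enriched pathways to the
#' differentially expressed glycogenes they contain: pathway nodes are the
#' enriched sets containing at least one DE glycogene, gene nodes the DE
#' glycogenes appearing in at least one such set, and an edge records
#' membership. A glycogene's degree — the number of incident pathways — is
#' the importance measure used to pick the functional hub.
#'
#' @param enriched_sets A [gene_set_collection()] already filtered to
#'   significant pathways.
#' @param de_glycogenes Non-empty character vector of DE glycogene symbols.
#' @return Object of class `bipartite_graph`: `pathways`, `genes`, `edges`
#'   (`data.frame` with `pathway`, `gene`), `degree` (named integer vector).
#' @export
build_bipartite <- function(enriched_sets, de_glycogenes) {
  stopifnot(inherits(enriched_sets, "gene_set_collection"))
  de_glycogenes <- unique(as.character(de_glycogenes))
  if (!length(de_glycogenes)) stop2("'de_glycogenes' must be non-empty")
  edges <- list()
  for (nm in names(enriched_sets$sets)) {
    hit <- intersect(enriched_sets$sets[[nm]], de_glycogenes)
    if (length(hit))
      edges[[length(edges) + 1L]] <- data.frame(pathway = nm, gene = hit,
                                                stringsAsFactors = FALSE)
  }
  if (!length(edges)) {
    warn2("no enriched pathway contains a DE glycogene; graph is empty")
    edges <- data.frame(pathway = character(), gene = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- do.call(rbind, edges)
  }
  genes <- sort(unique(edges$gene))
  degree <- vapply(genes, function(g) sum(edges$gene == g), integer(1))
  structure(list(pathways = unique(edges$pathway), genes = genes,
                 edges = edges, degree = degree),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("bipartite_graph: %d pathways, %d glycogenes, %d edges\n",
              length(x$pathways), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Rank glycogenes by bipartite degree
#'
#' Descending by degree with competition ranking (tied genes share a rank;
#' the next rank skips accordingly) and lexicographic order within ties.
#'
#' @param graph A [build_bipartite()] result.
#' @return `data.frame`: `gene`, `degree`, `rank` (empty for an empty graph).
#' @export
rank_by_degree <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (!length(graph$genes))
    return(data.frame(gene = character(), degree = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  deg <- graph$degree
  ord <- order(-deg, names(deg))
  deg <- deg[ord]
  # competition ranking: rank = 1 + number of genes with strictly larger degree
  rank <- vapply(deg, function(d) 1L + sum(graph$degree > d), integer(1))
  data.frame(gene = names(deg), degree = as.integer(deg), rank = rank,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the functional hub glycogene
#'
#' The glycogene with the highest bipartite degree. Ties at rank 1 are all
#' returned with `tied = TRUE`.
#'
#' @param graph A [build_bipartite()] result with at least one gene node.
#' @return List with `gene` (character vector, length > 1 iff tied),
#'   `degree`, `tied`.
#' @export
select_hub <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (!length(graph$genes)) stop2("cannot select a hub from an empty graph")
  rk <- rank_by_degree(graph)
  top <- rk[rk$rank == 1L, , drop = FALSE]
  list(gene = top$gene, degree = top$degree[1L], tied = nrow(top) > 1L)
}
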