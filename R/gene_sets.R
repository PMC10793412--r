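#' Gene set collections
#'
#' A `gene_set_collection` holds named gene sets (as in MSigDB's canonical
#' pathway GMT files) together with one description per set. Member order is
#' preserved because downstream enrichment statistics depend on it.
#'
#' @param sets Named list of character vectors of gene symbols. Names must be
#'   unique; each set must be non-empty and free of duplicate members.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled from `""` when missing.
#' @return An object of class `gene_set_collection` with elements `sets`
#'   (named list) and `descriptions` (named character vector).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop2("'sets' must be a list of character vectors")
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || any(nm == "") || anyNA(nm)))
    stop2("every gene set must be named")
  if (anyDuplicated(nm))
    stop2("duplicate gene set name: %s", nm[duplicated(nm)][1L])
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (!is.character(s) || length(s) == 0L)
      stop2("gene set '%s' must be a non-empty character vector", nm[i])
    if (anyDuplicated(s))
      stop2("gene set '%s' has duplicate members", nm[i])
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- as.character(descriptions)
  if (length(descriptions) != length(sets))
    stop2("'descriptions' must have one entry per set")
  names(descriptions) <- nm
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x$sets)))
  if (length(x$sets)) {
    sizes <- lengths(x$sets)
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Subset a gene set collection by set name
#'
#' @param x A `gene_set_collection`.
#' @param names Character vector of set names to keep (order preserved).
#' @return A `gene_set_collection` restricted to `names`.
#' @export
subset_sets <- function(x, names) {
  stopifnot(inherits(x, "gene_set_collection"))
  missing <- setdiff(names, base::names(x$sets))
  if (length(missing))
    stop2("unknown set name(s): %s", paste(missing, collapse = ", "))
  gene_set_collection(x$sets[names], x$descriptions[names])
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format: one set per line, field 1 the set
#' name, field 2 a description, fields 3+ the member genes. Duplicate members
#' within a line are dropped, keeping the first occurrence.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop2("GMT parse error at line %d: expected >=3 tab-separated fields, got %d",
            lineno[i], length(fields))
    nm[i] <- fields[1L]
    desc[i] <- fields[2L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[i]] <- members[!duplicated(members)]
  }
  if (anyDuplicated(nm))
    stop2("duplicate gene set name in GMT: %s", nm[duplicated(nm)][1L])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene set collection to GMT
#'
#' @param x A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(seq_along(x$sets), function(i) {
    paste(c(names(x$sets)[i], x$descriptions[i], x$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Glycogene annotation tables
#'
#' A glycogene table maps glycosyltransferase (and related) gene symbols to
#' their glycosylation pathway and synthesis step, mirroring curated
#' glycogene resources in which roughly 200 enzymes are grouped into the
#' major glycosylation pathways.
#'
#' @param gene Character vector of unique gene symbols.
#' @param pathway Character vector of glycosylation pathway labels
#'   (non-empty), one per gene.
#' @param step Optional synthesis-step labels.
#' @param pathway_specific Optional logical flag per gene.
#' @return A `data.frame` of class `glycogene_table` with columns `gene`,
#'   `pathway`, `step`, `pathway_specific`.
#' @export
glycogene_table <- function(gene, pathway, step = NULL, pathway_specific = NULL) {
  gene <- as.character(gene)
  pathway <- as.character(pathway)
  if (length(gene) != length(pathway))
    stop2("'gene' and 'pathway' must have equal length")
  if (anyDuplicated(gene))
    stop2("duplicate glycogene symbol: %s", gene[duplicated(gene)][1L])
  if (any(!nzchar(pathway) | is.na(pathway)))
    stop2("every glycogene needs a non-empty pathway label")
  step <- step %||% rep("", length(gene))
  pathway_specific <- pathway_specific %||% rep(TRUE, length(gene))
  out <- data.frame(gene = gene, pathway = pathway, step = as.character(step),
                    pathway_specific = as.logical(pathway_specific),
                    stringsAsFactors = FALSE)
  class(out) <- c("glycogene_table", "data.frame")
  out
}

#' Read a glycogene annotation TSV
#'
#' Expects a header with columns `gene` and `pathway`; optional columns
#' `step` and `pathway_specific`.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A [glycogene_table()].
#' @export
read_glycogene_table <- function(path) {
  if (!file.exists(path)) stop2("glycogene table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "pathway") %in% names(df)))
    stop2("glycogene table needs 'gene' and 'pathway' columns")
  glycogene_table(df$gene, df$pathway, df$step, df$pathway_specific)
}

#' Group a glycogene table into gene sets by pathway
#'
#' @param tab A [glycogene_table()].
#' @return A [gene_set_collection()] with one set per glycosylation pathway.
#' @export
glyco_pathway_sets <- function(tab) {
  stopifnot(inherits(tab, "glycogene_table"))
  sets <- split(tab$gene, tab$pathway)
  gene_set_collection(sets, rep("glycosylation pathway", length(sets)))
}
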