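#' Bulk expression matrices with sample metadata
#'
#' Container for a genes x samples matrix of (log-scale) expression values
#' plus per-sample metadata: cohort, brain region and case/control condition.
#' All downstream bulk analyses (meta-analysis, pathway activity,
#' correlations) consume this container. Values are required to be finite;
#' the meta-analysis stage assumes they are on a log scale so that
#' standardized mean differences are comparable across cohorts.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param meta `data.frame` with columns `sample`, `cohort`, `region`,
#'   `condition` (`"case"`/`"control"`), covering every column of `values`.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `meta` (rows of `meta` ordered to match columns of `values`).
#' @export
expr_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop2("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("'values' needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate gene id: %s", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample id: %s", colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop2("non-finite expression value at gene '%s', sample '%s'",
          rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  need <- c("sample", "cohort", "region", "condition")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop2("'meta' must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  for (j in need) meta[[j]] <- as.character(meta[[j]])
  missing <- setdiff(colnames(values), meta$sample)
  if (length(missing))
    stop2("metadata missing for sample(s): %s", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- setdiff(unique(meta$condition), c("case", "control"))
  if (length(bad))
    stop2("condition labels must be 'case'/'control'; found: %s",
          paste(bad, collapse = ", "))
  structure(list(values = values, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  cohorts: %s\n", paste(unique(x$meta$cohort), collapse = ", ")))
  cat(sprintf("  regions: %s\n", paste(unique(x$meta$region), collapse = ", ")))
  cat(sprintf("  case/control: %d/%d\n", sum(x$meta$condition == "case"),
              sum(x$meta$condition == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a bulk expression matrix and its sample metadata
#'
#' The expression TSV has genes in rows with a first column named `gene` and
#' one column per sample; the metadata TSV is keyed by `sample` and must
#' cover every expression column.
#'
#' @param path Expression TSV path.
#' @param metadata_path Sample metadata TSV path.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  if (!file.exists(path)) stop2("expression file not found: %s", path)
  if (!file.exists(metadata_path)) stop2("metadata file not found: %s", metadata_path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "gene") stop2("first expression column must be 'gene'")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop2("duplicate gene id: %s", genes[duplicated(genes)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(storage) & !is.na(vals))) {
    bad <- which(is.na(storage) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop2("non-numeric expression value at gene '%s', sample '%s'",
          genes[bad[1L]], colnames(vals)[bad[2L]])
  }
  dimnames(storage) <- list(genes, colnames(vals))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expr_matrix(storage, meta)
}

#' Write a bulk expression matrix and its metadata
#'
#' @param x An [expr_matrix()].
#' @param path Expression TSV output path.
#' @param metadata_path Metadata TSV output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# split an expr_matrix into per-(cohort, region) strata
split_strata <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  key <- paste(x$meta$cohort, x$meta$region, sep = "\r")
  idx <- split(seq_len(ncol(x$values)), key)
  lapply(idx, function(i)
    expr_matrix(x$values[, i, drop = FALSE], x$meta[i, , drop = FALSE]))
}
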