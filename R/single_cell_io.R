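#' Labeled single-cell count datasets
#'
#' Container for a genes x cells count matrix with a cell-type label and a
#' condition label per cell (e.g. `"NCI"`/`"AD"` or synthetic equivalents).
#' Counts must be non-negative integers. A log-normalized layer is attached
#' by [sc_normalize()] and is absent until then.
#'
#' @param counts Matrix (dense or `Matrix` sparse), genes in rows with
#'   unique rownames, cells in columns with unique barcodes as colnames.
#' @param cell_type Character vector, one label per cell.
#' @param condition Character vector, one label per cell.
#' @return An object of class `sc_dataset` with elements `counts`,
#'   `cell_type`, `condition` and `normalized` (initially `NULL`).
#' @export
sc_dataset <- function(counts, cell_type, condition) {
  if (!inherits(counts, "Matrix") && !is.matrix(counts))
    stop2("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("'counts' needs gene rownames and barcode colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop2("duplicate gene or barcode id")
  v <- if (inherits(counts, "Matrix")) counts@x else as.numeric(counts)
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop2("counts must be non-negative integers")
  n <- ncol(counts)
  cell_type <- as.character(cell_type)
  condition <- as.character(condition)
  if (length(cell_type) != n || length(condition) != n)
    stop2("labels must cover all %d cells (got %d cell_type, %d condition)",
          n, length(cell_type), length(condition))
  if (anyNA(cell_type) || anyNA(condition))
    stop2("labels must not contain NA")
  structure(list(counts = counts, cell_type = cell_type,
                 condition = condition, normalized = NULL),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  tt <- table(x$cell_type)
  cat(sprintf("  cell types: %s\n",
              paste(sprintf("%s (%d)", names(tt), tt), collapse = ", ")))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$condition), collapse = ", ")))
  cat(sprintf("  normalized layer: %s\n",
              if (is.null(x$normalized)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Read a single-cell dataset from MatrixMarket or dense TSV
#'
#' `matrix_path` may be a MatrixMarket sparse triplet file (genes x cells,
#' 1-based indices per the MTX standard) or a dense tab-separated numeric
#' table with genes in rows. `genes_path` and `barcodes_path` are one-id-per-
#' line text files; `labels_path` is a TSV with header columns `barcode`,
#' `cell_type`, `condition`.
#'
#' @param matrix_path Count matrix file (MTX or dense TSV).
#' @param genes_path One gene symbol per line.
#' @param barcodes_path One barcode per line.
#' @param labels_path TSV with `barcode`, `cell_type`, `condition` columns.
#' @return An [sc_dataset()].
#' @export
read_single_cell <- function(matrix_path, genes_path, barcodes_path, labels_path) {
  for (p in c(matrix_path, genes_path, barcodes_path, labels_path))
    if (!file.exists(p)) stop2("file not found: %s", p)
  genes <- readLines(genes_path, warn = FALSE)
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(barcodes_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  first <- readLines(matrix_path, n = 1L, warn = FALSE)
  if (grepl("^%%MatrixMarket", first)) {
    counts <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  } else {
    df <- utils::read.delim(matrix_path, header = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df)
    if (!is.numeric(counts)) stop2("dense count table must be numeric")
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  if (nrow(counts) != length(genes))
    stop2("gene list length (%d) does not match matrix rows (%d)",
          length(genes), nrow(counts))
  if (ncol(counts) != length(barcodes))
    stop2("barcode list length (%d) does not match matrix columns (%d)",
          length(barcodes), ncol(counts))
  dimnames(counts) <- list(genes, barcodes)
  labels <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  need <- c("barcode", "cell_type", "condition")
  if (!all(need %in% names(labels)))
    stop2("labels file needs columns %s", paste(need, collapse = ", "))
  missing <- setdiff(barcodes, labels$barcode)
  if (length(missing))
    stop2("labels missing for barcode(s): %s", paste(missing, collapse = ", "))
  labels <- labels[match(barcodes, labels$barcode), , drop = FALSE]
  sc_dataset(counts, labels$cell_type, labels$condition)
}

#' Write a single-cell dataset as MTX plus sidecar TSVs
#'
#' @param x An [sc_dataset()].
#' @param dir Output directory (created if absent). Files written:
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `labels.tsv`.
#' @return `dir`, invisibly.
#' @export
write_single_cell <- function(x, dir) {
  stopifnot(inherits(x, "sc_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- x$counts
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = colnames(x$counts), cell_type = x$cell_type,
               condition = x$condition, stringsAsFactors = FALSE),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Pipeline configuration with defaults
#'
#' Reads an optional YAML file of analysis thresholds and merges it over the
#' package defaults: `fdr` 0.05, `top_n` 30, `percentile` 90, `n_perm` 999,
#' `beta` 8, `restart` 0.7, `seed` 1.
#'
#' @param path Optional YAML file path.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(fdr = 0.05, top_n = 30L, percentile = 90, n_perm = 999L,
              beta = 8, restart = 0.7, seed = 1L)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop2("reading a config file requires the 'yaml' package")
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}
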