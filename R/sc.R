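#' Log-normalize single-cell counts
#'
#' Library-size normalization followed by a log transform, per cell:
#' \eqn{ln(1 + c \cdot scale / total)} with `scale` defaulting to 1e4
#' (counts per ten thousand). The result is attached as the dataset's
#' `normalized` layer.
#'
#' @param ds An [sc_dataset()].
#' @param scale Scale factor (default `1e4`).
#' @return The dataset with a dense `normalized` genes x cells matrix.
#' @export
sc_normalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "sc_dataset"))
  assert_scalar(scale, function(x) x > 0, "positive")
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0))
    stop2("cell(s) with zero total counts: %s",
          paste(colnames(ds$counts)[totals == 0], collapse = ", "))
  norm <- log1p(t(t(as.matrix(ds$counts)) / totals) * scale)
  dimnames(norm) <- dimnames(ds$counts)
  ds$normalized <- norm
  ds
}

#' Highly variable gene selection (variance-stabilizing style)
#'
#' Fits a mean-variance trend on raw counts — a second-degree polynomial of
#' log10 variance against log10 mean — then standardizes each gene's counts
#' by its trend-expected SD, clips standardized values at
#' \eqn{\sqrt{n_{cells}}}, and ranks genes by the variance of the clipped
#' standardized values. The top `n` genes are returned, ties broken
#' lexicographically; constant genes get standardized variance 0.
#'
#' @param ds An [sc_dataset()].
#' @param n Number of genes to select.
#' @return Character vector of `n` gene symbols.
#' @export
select_hvg <- function(ds, n) {
  stopifnot(inherits(ds, "sc_dataset"))
  X <- as.matrix(ds$counts)
  if (n > nrow(X)) stop2("requested %d genes but only %d available", n, nrow(X))
  mu <- rowMeans(X)
  v <- row_vars(X)
  usable <- mu > 0 & v > 0
  std_var <- numeric(nrow(X))
  if (sum(usable) >= 3L) {
    lm_fit <- stats::lm(log10(v[usable]) ~ stats::poly(log10(mu[usable]), 2))
    exp_sd <- sqrt(10^stats::predict(lm_fit))
    clip <- sqrt(ncol(X))
    Z <- (X[usable, , drop = FALSE] - mu[usable]) / exp_sd
    Z[Z > clip] <- clip
    Z[Z < -clip] <- -clip
    std_var[usable] <- row_vars(Z)
  } else {
    std_var[usable] <- v[usable]
  }
  names(std_var) <- rownames(X)
  ord <- order(-std_var, names(std_var))
  names(std_var)[ord][seq_len(n)]
}

#' Per-cell-type expression profile of one gene
#'
#' Mean normalized expression and detection fraction (share of cells with a
#' positive count) per cell type, optionally split by condition.
#'
#' @param ds A normalized [sc_dataset()] (see [sc_normalize()]).
#' @param gene Gene symbol.
#' @param by_condition Also split by condition label? Default `FALSE`.
#' @return `data.frame`: `cell_type` (and `condition`), `mean_norm`,
#'   `frac_detected`, `n_cells`.
#' @export
celltype_profile <- function(ds, gene, by_condition = FALSE) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (!gene %in% rownames(ds$counts)) stop2("unknown gene: %s", gene)
  if (is.null(ds$normalized)) ds <- sc_normalize(ds)
  norm <- ds$normalized[gene, ]
  detected <- as.numeric(ds$counts[gene, ]) > 0
  key <- if (by_condition) paste(ds$cell_type, ds$condition, sep = "\r")
         else ds$cell_type
  idx <- split(seq_along(norm), key)
  rows <- lapply(names(idx), function(k) {
    i <- idx[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    out <- data.frame(cell_type = parts[1L], stringsAsFactors = FALSE)
    if (by_condition) out$condition <- parts[2L]
    out$mean_norm <- mean(norm[i])
    out$frac_detected <- mean(detected[i])
    out$n_cells <- length(i)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank-sum marker genes between two groups
#'
#' Per gene: Wilcoxon rank-sum test on normalized values between the two
#' groups (shared implementation with [wilcoxon_rank_sum()]) and a log2
#' fold change \eqn{log_2((mean(expm1(g1)) + \epsilon)/(mean(expm1(g2)) +
#' \epsilon))}, \eqn{\epsilon = 10^{-9}}. Genes are pre-filtered by minimum
#' detection fraction and absolute fold change before testing, and BH
#' correction runs across the tested genes.
#'
#' @param ds A normalized [sc_dataset()].
#' @param group_by Label axis: `"cell_type"` or `"condition"`.
#' @param g1,g2 The two labels to compare.
#' @param min_frac Minimum detection fraction in either group (default 0.1).
#' @param min_lfc Minimum |log2 fold change| (default 0.25). Set both
#'   filters to 0 to test every gene.
#' @return `data.frame`: `gene`, `lfc`, `p`, `q`, sorted by `p`.
#' @export
find_markers <- function(ds, group_by = c("cell_type", "condition"), g1, g2,
                         min_frac = 0.1, min_lfc = 0.25) {
  stopifnot(inherits(ds, "sc_dataset"))
  group_by <- match.arg(group_by)
  if (is.null(ds$normalized)) ds <- sc_normalize(ds)
  labels <- ds[[group_by]]
  i1 <- which(labels == g1); i2 <- which(labels == g2)
  if (!length(i1) || !length(i2))
    stop2("empty group: %s has %d cells, %s has %d cells",
          g1, length(i1), g2, length(i2))
  N1 <- ds$normalized[, i1, drop = FALSE]
  N2 <- ds$normalized[, i2, drop = FALSE]
  eps <- 1e-9
  lfc <- log2((rowMeans(expm1(N1)) + eps) / (rowMeans(expm1(N2)) + eps))
  f1 <- rowMeans(as.matrix(ds$counts[, i1, drop = FALSE]) > 0)
  f2 <- rowMeans(as.matrix(ds$counts[, i2, drop = FALSE]) > 0)
  keep <- (pmax(f1, f2) >= min_frac) & (abs(lfc) >= min_lfc)
  if (!any(keep)) {
    return(data.frame(gene = character(), lfc = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  genes <- rownames(ds$normalized)[keep]
  p <- vapply(which(keep), function(g)
    wilcoxon_rank_sum(N1[g, ], N2[g, ])$p, numeric(1))
  res <- data.frame(gene = genes, lfc = lfc[keep], p = p,
                    q = bh_fdr(p), stringsAsFactors = FALSE)
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cell-type x pathway matrix of -log10(FDR) enrichment scores
#'
#' Collates per-cell-type ORA results into a heatmap-ready matrix restricted
#' to pathways whose names contain any of the extracellular-matrix tokens
#' (default `"ECM"`, `"Extracellular"`, `"Matrisome"`, `"Collagen"`).
#' Entries are `-log10(q)` with q floored at the smallest positive double.
#'
#' @param ora_by_type Named list (cell type -> [ora_hypergeom()] result).
#' @param tokens Name tokens to keep.
#' @return Numeric matrix, rows = cell types, columns = matched pathways.
#' @export
ecm_score_matrix <- function(ora_by_type,
                             tokens = c("ECM", "Extracellular", "Matrisome",
                                        "Collagen")) {
  if (!length(ora_by_type) || is.null(names(ora_by_type)))
    stop2("'ora_by_type' must be a named list of ORA results")
  all_sets <- unique(unlist(lapply(ora_by_type, function(d) d$set)))
  hit <- Reduce(`|`, lapply(tokens, function(tk)
    grepl(tk, all_sets, ignore.case = TRUE)))
  cols <- sort(all_sets[hit])
  if (!length(cols)) {
    warn2("no pathway name matches tokens %s", paste(tokens, collapse = "/"))
    return(matrix(numeric(0), nrow = length(ora_by_type), ncol = 0,
                  dimnames = list(names(ora_by_type), NULL)))
  }
  out <- matrix(0, nrow = length(ora_by_type), ncol = length(cols),
                dimnames = list(names(ora_by_type), cols))
  for (ct in names(ora_by_type)) {
    d <- ora_by_type[[ct]]
    m <- d[d$set %in% cols, , drop = FALSE]
    q <- pmax(m$q, .Machine$double.xmin)
    out[ct, m$set] <- -log10(q)
  }
  out
}

#' Ligand-receptor communication scores between two cell types
#'
#' Mass-action saturation model of cell-cell communication: with mean
#' normalized ligand expression \eqn{\bar L} in the sender type and mean
#' normalized receptor expression \eqn{\bar R} in the receiver type (the
#' geometric mean over subunits for multi-subunit receptors), the score is
#' \eqn{\bar L \bar R / (K_h + \bar L \bar R)} with half-saturation
#' constant `Kh` (default 0.5). The score lives in `[0, 1)` and is 0 iff
#' either side's mean expression is 0.
#'
#' @param ds A normalized [sc_dataset()].
#' @param pairs `data.frame` with columns `pair_id`, `ligand`, `receptor`
#'   (multi-subunit receptors separated by `";"`).
#' @param sender,receiver Cell-type labels.
#' @param Kh Half-saturation constant, must be > 0.
#' @return `data.frame`: `pair_id`, `ligand`, `receptor`, `sender`,
#'   `receiver`, `L`, `R`, `score`, sorted descending by score. Pairs whose
#'   genes are absent are skipped with a warning.
#' @export
ligand_receptor_score <- function(ds, pairs, sender, receiver, Kh = 0.5) {
  stopifnot(inherits(ds, "sc_dataset"), is.data.frame(pairs))
  if (Kh <= 0) stop2("'Kh' must be > 0")
  if (is.null(ds$normalized)) ds <- sc_normalize(ds)
  is_send <- ds$cell_type == sender
  is_recv <- ds$cell_type == receiver
  if (!any(is_send) || !any(is_recv))
    stop2("sender or receiver cell type not present")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[i]
    subunits <- strsplit(pairs$receptor[i], ";", fixed = TRUE)[[1L]]
    if (!lig %in% rownames(ds$normalized) ||
        !all(subunits %in% rownames(ds$normalized))) {
      warn2("pair '%s' skipped: gene(s) absent", pairs$pair_id[i])
      next
    }
    if (lig %in% subunits) stop2("pair '%s': ligand equals receptor", pairs$pair_id[i])
    L <- mean(ds$normalized[lig, is_send])
    Rsub <- vapply(subunits, function(s) mean(ds$normalized[s, is_recv]),
                   numeric(1))
    R <- exp(mean(log(pmax(Rsub, 0))))
    if (any(Rsub == 0)) R <- 0
    LR <- L * R
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = pairs$pair_id[i], ligand = lig, receptor = pairs$receptor[i],
      sender = sender, receiver = receiver, L = L, R = R,
      score = LR / (Kh + LR), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop2("no scorable ligand-receptor pair")
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$pair_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Permutation test for a ligand-receptor interaction
#'
#' Null distribution by permuting cell-type labels across all cells and
#' recomputing the communication score;
#' \eqn{p = (1 + \#\{score_{perm} \ge score_{obs}\}) / (1 + n_{perm})}.
#'
#' @param ds A normalized [sc_dataset()].
#' @param pair One-row `data.frame` with `pair_id`, `ligand`, `receptor`.
#' @param sender,receiver Cell-type labels.
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @param Kh Half-saturation constant.
#' @return List with `score`, `p`, `n_perm`.
#' @export
interaction_permutation_test <- function(ds, pair, sender, receiver,
                                         n_perm = 100L, seed = 1L, Kh = 0.5) {
  if (n_perm < 1L) stop2("'n_perm' must be >= 1")
  if (is.null(ds$normalized)) ds <- sc_normalize(ds)
  obs <- ligand_receptor_score(ds, pair, sender, receiver, Kh = Kh)$score
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shuffled <- ds
    shuffled$cell_type <- sample(ds$cell_type)
    ligand_receptor_score(shuffled, pair, sender, receiver, Kh = Kh)$score
  }, numeric(1)))
  list(score = obs, p = (1 + sum(perm >= obs)) / (1 + n_perm), n_perm = n_perm)
}
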