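#' Per-sample pathway activity
#'
#' Summarizes a gene set's expression into one score per sample, either as
#' the plain mean over member genes (`"mean"`, the convention used for the
#' ECM outcome) or as the eigengene: the first principal-component score of
#' the standardized member submatrix, sign-aligned so that its correlation
#' with the member mean is non-negative. Eigengene scores have zero mean by
#' construction.
#'
#' @param expr An [expr_matrix()].
#' @param set Character vector of member genes; at least 1 (`"mean"`) or 2
#'   (`"eigengene"`) must be present in `expr`.
#' @param method `"mean"` or `"eigengene"`.
#' @return Object of class `pathway_activity`: numeric vector (one score per
#'   sample, named) with attributes `method` and `genes_used`.
#' @export
pathway_activity <- function(expr, set, method = c("mean", "eigengene")) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  members <- intersect(set, rownames(expr$values))
  if (length(members) < 1L) stop2("no member gene present in the expression matrix")
  X <- expr$values[members, , drop = FALSE]
  if (method == "mean") {
    score <- colMeans(X)
  } else {
    if (length(members) < 2L) stop2("eigengene needs >=2 member genes present")
    Z <- t(scale(t(X)))           # standardize each gene across samples
    Z[is.na(Z)] <- 0              # zero-variance genes contribute nothing
    sv <- svd(t(Z), nu = 1, nv = 0)
    score <- sv$u[, 1L] * sv$d[1L]
    mn <- colMeans(X)
    if (stats::sd(mn) > 0 && stats::cor(score, mn) < 0) score <- -score
    score <- score - mean(score)
    names(score) <- colnames(X)
  }
  structure(score, method = method, genes_used = members,
            class = c("pathway_activity", "numeric"))
}

#' ECM pathway signature from a collection
#'
#' Matches pathway names against the tokens `"ECM"`, `"Extracellular"` and
#' `"Collagen"` (case-insensitive substrings) and returns both the matched
#' set names and the union of their member genes — the extracellular-matrix
#' signature used as the regression outcome.
#'
#' @param collection A [gene_set_collection()].
#' @param tokens Character tokens to match (defaults above).
#' @return List with `sets` (matched names) and `signature` (gene union).
#' @export
ecm_pathway_signature <- function(collection,
                                  tokens = c("ECM", "Extracellular", "Collagen")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  hit <- Reduce(`|`, lapply(tokens, function(tk)
    grepl(tk, nm, ignore.case = TRUE, fixed = FALSE)))
  if (!any(hit)) {
    warn2("no pathway name matches tokens %s", paste(tokens, collapse = "/"))
    return(list(sets = character(), signature = character()))
  }
  list(sets = nm[hit],
       signature = unique(unlist(collection$sets[hit], use.names = FALSE)))
}

#' PCA-regression association between a predictor pathway and an outcome
#'
#' Regresses a per-sample outcome (typically the ECM pathway activity) on
#' the first `n_pc` principal-component scores of the predictor set's
#' standardized expression submatrix and assesses the model F statistic by
#' permutation of the outcome across samples:
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#' Predictor genes that are also in `exclude` (the ECM signature) are
#' removed first so the association is not driven by shared genes.
#'
#' @param expr An [expr_matrix()].
#' @param outcome Numeric per-sample outcome, named by sample (e.g. a
#'   [pathway_activity()]).
#' @param predictor_set Character vector of predictor genes.
#' @param n_pc Number of PCs (default 1).
#' @param n_perm Number of outcome permutations (default 999).
#' @param seed Integer seed.
#' @param exclude Genes to drop from the predictor set (default none).
#' @return List with `p`, `f_obs`, `n_pc`, `n_samples`, `genes_used`.
#' @export
pca_regression_association <- function(expr, outcome, predictor_set, n_pc = 1L,
                                       n_perm = 999L, seed = 1L,
                                       exclude = character()) {
  stopifnot(inherits(expr, "expr_matrix"))
  samples <- colnames(expr$values)
  if (is.null(names(outcome))) {
    if (length(outcome) != length(samples))
      stop2("unnamed outcome must have one value per sample")
    names(outcome) <- samples
  }
  shared <- intersect(samples, names(outcome))
  if (length(shared) < n_pc + 2L)
    stop2("need at least n_pc + 2 = %d shared samples, got %d",
          n_pc + 2L, length(shared))
  members <- setdiff(intersect(predictor_set, rownames(expr$values)), exclude)
  if (length(members) < 1L) stop2("no usable predictor gene")
  X <- expr$values[members, shared, drop = FALSE]
  Z <- t(scale(t(X)))
  Z[is.na(Z)] <- 0
  n_pc <- min(n_pc, length(members), length(shared) - 2L)
  sv <- svd(t(Z), nu = n_pc, nv = 0)
  P <- sv$u[, seq_len(n_pc), drop = FALSE]          # orthonormal PC basis
  y <- as.numeric(outcome[shared])
  n <- length(y)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop2("outcome has zero variance")
  # PCs are orthonormal and centered, so R^2 = ||P'y||^2 / ||y - mean||^2
  Pc <- sweep(P, 2, colMeans(P))                    # center (already ~0)
  qrP <- qr(Pc)
  Q <- qr.Q(qrP)[, seq_len(qrP$rank), drop = FALSE]
  df1 <- ncol(Q); df2 <- n - df1 - 1L
  r2 <- min(1, colSums(crossprod(Q, matrix(yc, ncol = 1))^2) / ssy)
  f_obs <- (r2 / df1) / ((1 - r2) / df2)   # Inf for a perfect fit
  perm <- with_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
    Yp <- matrix(yc[idx], nrow = n)
    r2p <- pmin(1, colSums(crossprod(Q, Yp)^2) / ssy)
    (r2p / df1) / ((1 - r2p) / df2)
  })
  p <- (1 + sum(perm >= f_obs)) / (1 + n_perm)
  list(p = p, f_obs = unname(f_obs), n_pc = df1, n_samples = n,
       genes_used = members)
}

#' Fisher's method for combining independent p-values
#'
#' \eqn{X^2 = -2 \sum \ln p_i} compared against a chi-square distribution
#' with \eqn{2k} degrees of freedom. Zero p-values are clamped to the
#' smallest positive double with a warning.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return List with `x2`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop2("'p' must be non-empty")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop2("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn2("zero p-value(s) clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Pathway-wide ECM association scan with Fisher combination
#'
#' For every candidate pathway, runs [pca_regression_association()] against
#' the ECM outcome within each cohort x region stratum and combines the
#' per-stratum permutation p-values with Fisher's method. Strata with fewer
#' than `min_samples` samples are skipped with a warning.
#'
#' @param cohorts List of [expr_matrix()] objects.
#' @param collection A [gene_set_collection()] of candidate pathways.
#' @param ecm_tokens Tokens defining the ECM outcome signature.
#' @param n_pc,n_perm,seed Passed to [pca_regression_association()].
#' @param min_samples Minimum stratum size (default 10).
#' @return `data.frame`: `set`, `n_strata`, `x2`, `df`, `p_combined`,
#'   sorted ascending by `p_combined`.
#' @export
ecm_association_scan <- function(cohorts, collection,
                                 ecm_tokens = c("ECM", "Extracellular", "Collagen"),
                                 n_pc = 1L, n_perm = 999L, seed = 1L,
                                 min_samples = 10L) {
  if (inherits(cohorts, "expr_matrix")) cohorts <- list(cohorts)
  stopifnot(inherits(collection, "gene_set_collection"))
  ecm <- ecm_pathway_signature(collection, ecm_tokens)
  if (!length(ecm$signature)) stop2("empty ECM signature; nothing to associate")
  candidates <- setdiff(names(collection$sets), ecm$sets)
  strata <- unlist(lapply(cohorts, split_strata), recursive = FALSE)
  sizes <- vapply(strata, function(s) ncol(s$values), integer(1))
  small <- sizes < min_samples
  if (any(small)) {
    warn2("%d stratum(s) with < %d samples skipped", sum(small), min_samples)
    strata <- strata[!small]
  }
  if (!length(strata)) stop2("no stratum left after size filtering")
  rows <- lapply(seq_along(candidates), function(i) {
    nm <- candidates[i]
    ps <- numeric(0)
    for (j in seq_along(strata)) {
      st <- strata[[j]]
      out <- pathway_activity(st, ecm$signature, method = "mean")
      fit <- try(pca_regression_association(
        st, out, collection$sets[[nm]], n_pc = n_pc, n_perm = n_perm,
        seed = seed + i * 1000L + j, exclude = ecm$signature), silent = TRUE)
      if (!inherits(fit, "try-error")) ps <- c(ps, fit$p)
    }
    if (!length(ps)) return(NULL)
    fc <- fisher_combine(ps)
    data.frame(set = nm, n_strata = length(ps), x2 = fc$x2, df = fc$df,
               p_combined = fc$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_combined, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-stratum correlation of a gene with a partner gene or activity
#'
#' Pearson correlation (two-sided t-test p) between one gene's expression
#' and either another gene or a per-sample pathway activity, computed and
#' reported separately for every cohort x region stratum.
#'
#' @param expr An [expr_matrix()].
#' @param gene Gene symbol present in `expr`.
#' @param partner Either a second gene symbol or a named numeric per-sample
#'   vector (e.g. a [pathway_activity()]).
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return `data.frame`: `cohort`, `region`, `r`, `p`, `n`.
#' @export
gene_signature_correlation <- function(expr, gene, partner,
                                       method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  if (!gene %in% rownames(expr$values)) stop2("gene '%s' not found", gene)
  partner_vec <- if (is.character(partner) && length(partner) == 1L) {
    if (!partner %in% rownames(expr$values)) stop2("partner gene '%s' not found", partner)
    stats::setNames(expr$values[partner, ], colnames(expr$values))
  } else {
    if (is.null(names(partner))) stop2("a numeric partner must be named by sample")
    partner
  }
  rows <- lapply(split_strata(expr), function(st) {
    shared <- intersect(colnames(st$values), names(partner_vec))
    if (length(shared) < 3L) return(NULL)
    x <- st$values[gene, shared]
    y <- as.numeric(partner_vec[shared])
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop2("zero-variance vector in stratum %s/%s",
            st$meta$cohort[1L], st$meta$region[1L])
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    data.frame(cohort = st$meta$cohort[1L], region = st$meta$region[1L],
               r = unname(ct$estimate), p = ct$p.value, n = length(shared),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop2("no stratum with >=3 shared samples")
  rownames(res) <- NULL
  res
}

#' Per-stratum mean effect size of a gene signature
#'
#' Forest-plot input: for each cohort x region stratum, the arithmetic mean
#' of the signature genes' Hedges' g and a normal 95% CI
#' (mean +/- 1.96 sd / sqrt(m)). A stratum with a single signature gene
#' passes that gene's effect through with a CI from its own standard error.
#'
#' @param effects Long per-stratum effect table from [cohort_effects()].
#' @param signature Character vector of signature genes; must intersect the
#'   table.
#' @return `data.frame`: `cohort`, `region`, `m`, `estimate`, `lo`, `hi`.
#' @export
signature_effect_summary <- function(effects, signature) {
  stopifnot(is.data.frame(effects))
  sub <- effects[effects$gene %in% signature, , drop = FALSE]
  if (!nrow(sub)) stop2("signature is disjoint from the effect table")
  key <- interaction(sub$cohort, sub$region, drop = TRUE)
  rows <- lapply(split(sub, key), function(d) {
    m <- nrow(d)
    if (m >= 2L) {
      est <- mean(d$g); half <- 1.96 * stats::sd(d$g) / sqrt(m)
    } else {
      est <- d$g; half <- 1.96 * d$se
    }
    data.frame(cohort = d$cohort[1L], region = d$region[1L], m = m,
               estimate = est, lo = est - half, hi = est + half,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
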