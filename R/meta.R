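#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized mean difference between a case and a control
#' arm. With arm sizes \eqn{n_1, n_0}, Cohen's
#' \eqn{d = (\bar x_1 - \bar x_0)/s_p} uses the pooled SD from the unbiased
#' per-arm variances; the small-sample correction is
#' \eqn{J = 1 - 3/(4(n_1+n_0)-9)}, \eqn{g = J d}, and
#' \eqn{se^2(g) = J^2 [ (n_1+n_0)/(n_1 n_0) + d^2/(2(n_1+n_0)) ]}
#' (the Hedges–Olkin convention used by standard meta-analysis software).
#'
#' @param case,control Numeric vectors with at least 2 finite values each.
#' @param cohort,region Optional stratum labels carried through to the
#'   meta-analysis.
#' @return A one-row `data.frame`: `g`, `se`, `n_case`, `n_control`,
#'   `cohort`, `region`.
#' @export
hedges_g <- function(case, control, cohort = NA_character_, region = NA_character_) {
  case <- as.numeric(case); control <- as.numeric(control)
  if (length(case) < 2L || length(control) < 2L)
    stop2("each arm needs >=2 observations (got %d case, %d control)",
          length(case), length(control))
  if (any(!is.finite(case)) || any(!is.finite(control)))
    stop2("arms must contain only finite values")
  n1 <- length(case); n0 <- length(control)
  sp2 <- ((n1 - 1) * stats::var(case) + (n0 - 1) * stats::var(control)) /
    (n1 + n0 - 2)
  if (sp2 <= 0) stop2("degenerate input: pooled SD is zero")
  d <- (mean(case) - mean(control)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n0) - 9)
  g <- J * d
  se <- sqrt(J^2 * ((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))))
  data.frame(g = g, se = se, n_case = n1, n_control = n0,
             cohort = cohort, region = region, stringsAsFactors = FALSE)
}

# DerSimonian-Laird tau^2 (truncated at 0); y = effects, v = se^2
tau2_dl <- function(y, v) {
  k <- length(y)
  if (k < 2L) return(0)
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu)^2)
  c1 <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / c1)
}

# REML tau^2 by Fisher scoring; returns list(tau2, converged, iter)
tau2_reml <- function(y, v, max_iter = 100L, tol = 1e-8) {
  k <- length(y)
  if (k < 2L) return(list(tau2 = 0, converged = TRUE, iter = 0L))
  tau2 <- max(tau2_dl(y, v), 1e-4)
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    # restricted score and expected information in tau^2
    score <- 0.5 * (sum(w^2 * (y - mu)^2) - sum(w) + sum(w^2) / sum(w))
    info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sum(w) + (sum(w^2) / sum(w))^2)
    if (info <= 0) break
    new <- tau2 + score / info
    if (new < 0) new <- tau2 / 2   # damped step toward the boundary
    if (abs(new - tau2) < tol) {
      # converged; snap to the floor if the boundary attracts the score
      tau2 <- new
      if (tau2 < tol * 10) {
        w0 <- 1 / v
        mu0 <- sum(w0 * y) / sum(w0)
        score0 <- 0.5 * (sum(w0^2 * (y - mu0)^2) - sum(w0) + sum(w0^2) / sum(w0))
        if (score0 <= 0) tau2 <- 0
      }
      return(list(tau2 = max(tau2, 0), converged = TRUE, iter = it))
    }
    tau2 <- new
  }
  list(tau2 = max(tau2, 0), converged = FALSE, iter = max_iter)
}

#' Random-effects combination of per-stratum effect sizes
#'
#' Combines k standardized mean differences under the random-effects model
#' \eqn{g_i \sim N(\mu, se_i^2 + \tau^2)} with inverse-variance weights
#' \eqn{w_i = 1/(se_i^2 + \hat\tau^2)}:
#' \eqn{\hat\mu = \sum w_i g_i / \sum w_i},
#' \eqn{se(\hat\mu) = (\sum w_i)^{-1/2}}, z = \eqn{\hat\mu/se(\hat\mu)} with
#' a two-sided normal p-value. \eqn{\tau^2} is estimated by iterative REML
#' (Fisher scoring, at most 100 iterations, tolerance 1e-8, floored at 0) or
#' by DerSimonian–Laird with truncation at zero. A single stratum passes
#' through as a fixed-effect result with \eqn{\tau^2 = 0}; REML
#' non-convergence falls back to DerSimonian–Laird with a warning.
#'
#' @param effects `data.frame` with columns `g` and `se` (e.g. rows from
#'   [hedges_g()]), one row per stratum.
#' @param method `"REML"` (default) or `"DL"`.
#' @return One-row `data.frame`: `k`, `mu`, `se`, `tau2`, `Q`, `z`, `p`.
#' @export
combine_random_effects <- function(effects, method = c("REML", "DL")) {
  method <- match.arg(method)
  if (is.null(effects) || nrow(effects) == 0L)
    stop2("'effects' must contain at least one effect size")
  y <- as.numeric(effects$g); se <- as.numeric(effects$se)
  if (any(!is.finite(y)) || any(!is.finite(se)) || any(se <= 0))
    stop2("all effects need finite g and se > 0")
  k <- length(y)
  v <- se^2
  wf <- 1 / v
  muf <- sum(wf * y) / sum(wf)
  Q <- if (k > 1L) sum(wf * (y - muf)^2) else 0
  if (k == 1L) {
    tau2 <- 0
  } else if (method == "DL") {
    tau2 <- tau2_dl(y, v)
  } else {
    fit <- tau2_reml(y, v)
    if (!fit$converged) {
      warn2("REML did not converge in %d iterations; falling back to DL", fit$iter)
      tau2 <- tau2_dl(y, v)
    } else tau2 <- fit$tau2
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- 1 / sqrt(sum(w))
  z <- mu / se_mu
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(k = k, mu = mu, se = se_mu, tau2 = tau2, Q = Q, z = z, p = p)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# per-stratum Hedges' g for every gene of one expr_matrix stratum,
# vectorized across genes; returns data.frame or NULL if an arm is too small
stratum_effects <- function(stratum, min_per_arm = 2L) {
  ca <- stratum$meta$condition == "case"
  n1 <- sum(ca); n0 <- sum(!ca)
  if (n1 < min_per_arm || n0 < min_per_arm) return(NULL)
  X1 <- stratum$values[, ca, drop = FALSE]
  X0 <- stratum$values[, !ca, drop = FALSE]
  m1 <- rowMeans(X1); m0 <- rowMeans(X0)
  v1 <- row_vars(X1); v0 <- row_vars(X0)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  ok <- sp2 > 0
  d <- ifelse(ok, (m1 - m0) / sqrt(sp2), NA_real_)
  J <- 1 - 3 / (4 * (n1 + n0) - 9)
  g <- J * d
  se <- sqrt(J^2 * ((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0))))
  data.frame(gene = rownames(stratum$values), g = g, se = se,
             n_case = n1, n_control = n0,
             cohort = stratum$meta$cohort[1L], region = stratum$meta$region[1L],
             stringsAsFactors = FALSE)[ok, , drop = FALSE]
}

#' Per-gene effect sizes for every cohort x region stratum
#'
#' Computes one Hedges' g row per gene per stratum (cohort x region) in
#' which both arms have at least `min_per_arm` samples. This is the long
#' table that feeds [meta_differential_expression()] and the forest-plot
#' summaries.
#'
#' @param cohorts List of [expr_matrix()] objects (each may contain several
#'   regions).
#' @param min_per_arm Minimum samples per arm within a stratum (default 2).
#' @return `data.frame`: `gene`, `g`, `se`, `n_case`, `n_control`, `cohort`,
#'   `region`.
#' @export
cohort_effects <- function(cohorts, min_per_arm = 2L) {
  if (inherits(cohorts, "expr_matrix")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop2("need at least one cohort")
  rows <- list()
  for (co in cohorts) {
    for (st in split_strata(co)) {
      ef <- stratum_effects(st, min_per_arm)
      if (!is.null(ef)) rows[[length(rows) + 1L]] <- ef
    }
  }
  if (!length(rows)) stop2("no stratum had >=%d samples per arm", min_per_arm)
  do.call(rbind, rows)
}

#' Random-effects meta-analysis of differential expression
#'
#' For every gene, combines per-stratum (cohort x region) Hedges' g values
#' under a random-effects model and applies Benjamini-Hochberg correction
#' over all tested genes. When a glycogene table is supplied the analysis
#' (and therefore the BH universe) is restricted to the glycogenes, matching
#' a glycogene-focused screen; set `universe = "global"` to correct over all
#' genes instead and filter afterwards.
#'
#' @param cohorts List of [expr_matrix()] objects.
#' @param glycogenes Optional [glycogene_table()] restricting the analysis.
#' @param method `tau^2` estimator, `"REML"` (default) or `"DL"`.
#' @param fdr DEG flag threshold on q (default 0.05).
#' @param universe `"filtered"` (BH within the glycogene filter, default) or
#'   `"global"` (BH over all genes before filtering).
#' @param min_per_arm Minimum samples per arm within a stratum.
#' @return A `data.frame` of class `meta_result`: `gene`, `k`, `mu`, `se`,
#'   `tau2`, `Q`, `z`, `p`, `q`, `is_deg`, sorted by `p`.
#' @export
meta_differential_expression <- function(cohorts, glycogenes = NULL,
                                         method = c("REML", "DL"), fdr = 0.05,
                                         universe = c("filtered", "global"),
                                         min_per_arm = 2L) {
  method <- match.arg(method)
  universe <- match.arg(universe)
  eff <- cohort_effects(cohorts, min_per_arm)
  filter_genes <- NULL
  if (!is.null(glycogenes)) {
    stopifnot(inherits(glycogenes, "glycogene_table"))
    filter_genes <- glycogenes$gene
    absent <- setdiff(filter_genes, unique(eff$gene))
    if (length(absent))
      warn2("%d glycogene(s) absent from all cohorts were dropped", length(absent))
  }
  if (!is.null(filter_genes) && universe == "filtered")
    eff <- eff[eff$gene %in% filter_genes, , drop = FALSE]
  if (!nrow(eff)) stop2("no genes left to meta-analyze")
  by_gene <- split(eff, eff$gene)
  res <- do.call(rbind, lapply(by_gene, combine_random_effects, method = method))
  res <- cbind(data.frame(gene = names(by_gene), stringsAsFactors = FALSE), res)
  res$q <- bh_fdr(res$p)
  if (!is.null(filter_genes) && universe == "global")
    res <- res[res$gene %in% filter_genes, , drop = FALSE]
  res$is_deg <- res$q < fdr
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("meta_result", "data.frame")
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: %d genes, %d flagged as DEGs\n",
              nrow(x), sum(x$is_deg)))
  NextMethod()
}
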