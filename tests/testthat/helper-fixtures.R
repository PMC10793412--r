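# Shared fixtures and independent oracles, built in code at test time.

# tiny deterministic expression matrix: g genes x n samples, one stratum
tiny_expr <- function(n_genes = 10, n_per_arm = 5, seed = 1,
                      cohort = "cohort1", region = "region1") {
  set.seed(seed)
  n <- 2 * n_per_arm
  X <- matrix(rnorm(n_genes * n, 5, 1), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n))))
  meta <- data.frame(sample = colnames(X), cohort = cohort, region = region,
                     condition = rep(c("case", "control"), each = n_per_arm),
                     stringsAsFactors = FALSE)
  expr_matrix(X, meta)
}

# brute-force hypergeometric upper tail by enumeration over all C(N, n) draws
ora_enum_oracle <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- seq_len(K)                  # wlog the first K elements form the set
  overlaps <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(overlaps >= k)
}

# direct O(N) running-sum GSEA ES evaluation (independent of the package's
# position-based implementation)
gsea_es_oracle <- function(scores, set_mask) {
  stopifnot(length(scores) == length(set_mask))
  N <- length(scores)
  m <- sum(set_mask)
  hit_w <- abs(scores) * set_mask
  hit_w <- hit_w / sum(hit_w)
  miss <- (1 - set_mask) / (N - m)
  rs <- cumsum(hit_w - miss)
  hi <- max(rs); lo <- min(rs)
  unname(if (hi >= -lo) hi else lo)
}

# O(n^3) triple-loop TOM oracle
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  TOM <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(A[i, ] * A[, j])
    TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# dense linear-solve RWR oracle: p = r (I - (1-r) W)^{-1} p0
rwr_oracle <- function(W_raw, seeds_idx, r) {
  W <- W_raw
  diag(W) <- 0
  cs <- colSums(W)
  dangling <- cs == 0
  diag(W)[dangling] <- 1
  cs[dangling] <- 1
  W <- sweep(W, 2, cs, "/")
  n <- nrow(W)
  p0 <- numeric(n)
  p0[seeds_idx] <- 1 / length(seeds_idx)
  unname(solve(diag(n) - (1 - r) * W, r * p0))
}

# brute-force REML/DL criterion maximizer over a tau^2 grid
tau2_grid_oracle <- function(y, v, method = "REML", upper = 2, n_grid = 200001) {
  grid <- seq(0, upper, length.out = n_grid)
  if (method == "DL") {
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    Q <- sum(w * (y - mu)^2)
    return(max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w))))
  }
  ll <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * sum(log(v + t2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (y - mu)^2)
  }, numeric(1))
  grid[which.max(ll)]
}

# small GMT written to a temp file
write_tmp_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
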