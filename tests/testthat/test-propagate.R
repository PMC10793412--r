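test_that("soft adjacency honors the |cor|^beta definition", {
  set.seed(1)
  X <- matrix(rnorm(5 * 50), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  X[2, ] <- 3 * X[1, ] + 1      # perfectly correlated pair
  net1 <- soft_adjacency(X, beta = 1)
  expect_equal(net1$W["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(net1$W["g3", "g4"], abs(cor(X[3, ], X[4, ])), tolerance = 1e-12)
  net6 <- soft_adjacency(X, beta = 6)
  expect_equal(net6$W["g1", "g2"], 1, tolerance = 1e-10)   # |r|=1 fixed point
  expect_equal(diag(net6$W), setNames(rep(0, 5), rownames(X)))

  # independent noise at n = 500 cells is crushed by beta = 8
  set.seed(2)
  Y <- matrix(rnorm(20 * 500), nrow = 20,
              dimnames = list(sprintf("n%02d", 1:20), NULL))
  net8 <- soft_adjacency(Y, beta = 8)
  expect_lt(mean(net8$W[upper.tri(net8$W)]), 0.01)

  # zero-variance genes dropped with a warning
  Z <- rbind(X, const = 5)
  expect_warning(netz <- soft_adjacency(Z, beta = 2), "zero-variance")
  expect_false("const" %in% netz$genes)
  expect_error(soft_adjacency(X[, 1:2], beta = 2), "3 cells")
})

test_that("TOM matches the closed form on cliques and the triple-loop oracle", {
  # 3-node clique with all a = 1 -> TOM = (1+1)/(2+1-1) = 1
  A <- matrix(1, 3, 3) - diag(3)
  dimnames(A) <- list(letters[1:3], letters[1:3])
  tom <- tom_matrix(weighted_network(letters[1:3], A, "adjacency"))
  expect_true(all(abs(tom$W - 1) < 1e-12))

  # isolated pair -> TOM off-diagonal 0
  A0 <- matrix(0, 2, 2)
  dimnames(A0) <- list(c("x", "y"), c("x", "y"))
  tom0 <- tom_matrix(weighted_network(c("x", "y"), A0, "adjacency"))
  expect_equal(tom0$W["x", "y"], 0)

  # random adjacencies vs the O(n^3) oracle to 1e-12, and range [0, 1]
  set.seed(3)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    M <- matrix(runif(n * n), n)
    A <- (M + t(M)) / 2
    diag(A) <- 0
    g <- sprintf("g%02d", seq_len(n))
    dimnames(A) <- list(g, g)
    tom <- tom_matrix(weighted_network(g, A, "adjacency"))
    expect_equal(unname(tom$W), tom_oracle(A), tolerance = 1e-12)
    expect_true(all(tom$W >= 0 & tom$W <= 1 + 1e-12))
  }

  expect_error(tom_matrix(weighted_network(c("x", "y"), A0, "tom")))
})

test_that("percentile thresholding keeps exactly the strict upper tail", {
  # 100 distinct off-diagonal values at percentile 90 -> top 10 survive
  n <- 15   # upper triangle size won't be exactly 100; construct directly
  vals <- seq_len(105) / 105
  # build a symmetric matrix whose upper triangle holds 105 distinct values
  W <- matrix(0, 15, 15)
  W[upper.tri(W)] <- vals
  W <- W + t(W)
  g <- sprintf("g%02d", 1:15)
  dimnames(W) <- list(g, g)
  net <- weighted_network(g, W, "adjacency")
  thr <- threshold_edges(net, 90)
  # quantile(type 7) of 105 distinct values at 0.9, strict > keeps ~10%
  expected <- sum(vals > quantile(vals, 0.9))
  expect_equal(nrow(thr$edges), expected)

  # tiny percentile keeps every positive edge
  thr0 <- threshold_edges(net, 1e-9)
  expect_equal(nrow(thr0$edges), sum(vals > min(vals)))

  # relabeling nodes doesn't change which weights survive
  perm <- sample(15)
  W2 <- W[perm, perm]
  net2 <- weighted_network(g[perm], W2, "adjacency")
  thr2 <- threshold_edges(net2, 90)
  expect_setequal(round(thr2$edges$weight, 12), round(thr$edges$weight, 12))

  # all-equal weights -> empty edge set with warning
  We <- matrix(0.5, 4, 4); diag(We) <- 0
  dimnames(We) <- list(letters[1:4], letters[1:4])
  expect_warning(thre <- threshold_edges(weighted_network(letters[1:4], We,
                                                          "adjacency"), 90),
                 "no edge")
  expect_equal(nrow(thre$edges), 0L)
  expect_error(threshold_edges(net, 100), "percentile")
})

test_that("RWR solves the star-graph fixed point and matches the linear solve", {
  # K_{1,3}, unit weights, seed = center, r = 0.5 -> center 2/3, leaves 1/9
  g <- c("center", "l1", "l2", "l3")
  W <- matrix(0, 4, 4, dimnames = list(g, g))
  W["center", c("l1", "l2", "l3")] <- 1
  W[c("l1", "l2", "l3"), "center"] <- 1
  net <- weighted_network(g, W, "adjacency")
  res <- rwr(net, "center", r = 0.5)
  expect_equal(unname(res$p["center"]), 2 / 3, tolerance = 1e-8)
  expect_equal(unname(res$p[c("l1", "l2", "l3")]), rep(1 / 9, 3),
               tolerance = 1e-8)
  expect_equal(sum(res$p), 1, tolerance = 1e-9)

  # r = 1 -> restart-only limit: p = p0
  res1 <- rwr(net, c("center", "l1"), r = 1)
  expect_equal(unname(res1$p), c(0.5, 0.5, 0, 0), tolerance = 1e-12)

  # random networks (<= 50 nodes) vs the dense linear-algebra oracle to 1e-8
  set.seed(4)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    M <- matrix(runif(n * n) * (runif(n * n) < 0.2), n)
    A <- (M + t(M)) / 2; diag(A) <- 0
    gg <- sprintf("g%02d", seq_len(n))
    dimnames(A) <- list(gg, gg)
    netr <- weighted_network(gg, A, "adjacency")
    seeds <- sample(gg, 2)
    mine <- rwr(netr, seeds, r = 0.7)
    oracle <- rwr_oracle(A, match(seeds, gg), r = 0.7)
    expect_equal(unname(mine$p), oracle, tolerance = 1e-8)
  }

  expect_error(rwr(net, "missing"), "absent")
  expect_error(rwr(net, "center", r = 0), "'r'")
})

test_that("RWR seed mass grows with the restart probability and ignores initialization", {
  set.seed(5)
  n <- 20
  M <- matrix(runif(n * n), n)
  A <- (M + t(M)) / 2; diag(A) <- 0
  g <- sprintf("g%02d", 1:n)
  dimnames(A) <- list(g, g)
  net <- weighted_network(g, A, "adjacency")
  seeds <- c("g01", "g02")
  masses <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r)
    sum(rwr(net, seeds, r = r)$p[seeds]), numeric(1))
  expect_true(all(diff(masses) > 0))

  # fixed point does not depend on the start: compare with the direct solve
  direct <- rwr_oracle(A, 1:2, 0.7)
  expect_equal(unname(rwr(net, seeds, 0.7)$p), direct, tolerance = 1e-8)
})

test_that("top neighbors exclude seeds, truncate, and prioritize a planted module", {
  g <- c("s1", "s2", letters[1:5])
  W <- matrix(0.1, 7, 7); diag(W) <- 0
  dimnames(W) <- list(g, g)
  W["s1", "a"] <- W["a", "s1"] <- 0.9
  net <- weighted_network(g, W, "adjacency")
  res <- rwr(net, c("s1", "s2"), r = 0.5)
  nb <- top_neighbors(res, 100)
  expect_false(any(c("s1", "s2") %in% nb))
  expect_equal(sort(nb), letters[1:5])          # k > network -> all non-seeds
  expect_equal(top_neighbors(res, 1), "a")      # strongest neighbor first

  # planted module recovery through the full adjacency -> TOM -> RWR chain
  members <- sprintf("SG%03d", 11:40)
  spec <- sc_sim_spec(n_cells_per_type = 250, n_genes = 100,
                      module = list(seeds = c("SG009", "SG010"),
                                    members = members, loading = 0.8,
                                    cell_type = "astrocyte"),
                      lr_pair = NULL, seed = 101)
  sim <- simulate_single_cell(spec)
  ds <- sc_normalize(sim$dataset)
  astro <- ds$normalized[, ds$cell_type == "astrocyte"]
  net2 <- suppressWarnings(soft_adjacency(astro, beta = 8))
  tom <- tom_matrix(net2)
  thr <- threshold_edges(tom, 90)
  res2 <- rwr(thr, c("SG009", "SG010"), r = 0.7)
  top30 <- top_neighbors(res2, 30)
  expect_gte(length(intersect(top30, members)) / 30, 0.8)
})

test_that("neighbor enrichment ranks the annotated set first", {
  universe <- sprintf("u%03d", 1:100)
  stress <- universe[1:30]
  gsc <- gene_set_collection(list(STRESS_RESPONSE = stress,
                                  DECOY_1 = universe[31:60],
                                  DECOY_2 = universe[61:90]))
  res <- neighbor_enrichment(universe[1:20], gsc, universe)
  expect_equal(res$set[1], "STRESS_RESPONSE")
  expect_error(neighbor_enrichment(character(), gsc, universe), "empty")
})

test_that("the scale-free helper reports a fit per candidate beta", {
  set.seed(6)
  X <- matrix(rnorm(30 * 100), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  fit <- fit_scale_free_beta(X, betas = c(1, 4, 8), n_bins = 5)
  expect_equal(fit$beta, c(1, 4, 8))
  expect_true(all(fit$mean_connectivity > 0))
})
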