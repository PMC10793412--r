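make_ds <- function(counts, types, conds = NULL) {
  conds <- conds %||% rep("AD", ncol(counts))
  sc_dataset(counts, types, conds)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("log-normalization follows the counts-per-scale formula and its invariances", {
  counts <- matrix(c(10, 0, 5, 5), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ds <- sc_normalize(make_ds(counts, c("A", "A")), scale = 1e4)
  expect_equal(ds$normalized["g1", "c1"], log(1 + 1e4), tolerance = 1e-12)
  expect_equal(ds$normalized["g2", "c1"], 0)

  # doubling every count in a cell leaves its normalized vector unchanged
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 2
  ds2 <- sc_normalize(make_ds(counts2, c("A", "A")))
  expect_equal(ds2$normalized[, 1], ds$normalized[, 1], tolerance = 1e-12)

  # within-cell ordering is preserved
  set.seed(2)
  counts3 <- matrix(rpois(50, 3), nrow = 10,
                    dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:5)))
  counts3[1, ] <- counts3[1, ] + 1  # avoid all-zero cells
  ds3 <- sc_normalize(make_ds(counts3, rep("A", 5)))
  for (j in 1:5)
    expect_equal(order(ds3$normalized[, j]), order(counts3[, j]))

  # zero-total cell errors naming the barcode
  counts4 <- counts; counts4[, 2] <- 0
  expect_error(sc_normalize(make_ds(counts4, c("A", "A"))), "c2")
})

test_that("HVG selection is deterministic, skips constants, finds planted dispersion", {
  set.seed(5)
  n_cells <- 300
  mu <- runif(80, 1, 4)
  counts <- matrix(rnbinom(80 * n_cells, size = 5, mu = mu), nrow = 80)
  # plant 8 high-dispersion genes
  planted <- sprintf("g%02d", 1:8)
  counts[1:8, ] <- rnbinom(8 * n_cells, size = 0.3, mu = mu[1:8])
  counts[9, ] <- 3L  # constant gene
  dimnames(counts) <- list(sprintf("g%02d", 1:80), sprintf("c%03d", seq_len(n_cells)))
  ds <- make_ds(counts, rep("A", n_cells))
  top <- select_hvg(ds, 10)
  expect_identical(top, select_hvg(ds, 10))      # deterministic
  expect_false("g09" %in% top)                   # constant gene never selected
  expect_gte(length(intersect(planted, top)), ceiling(0.9 * 8))
  expect_error(select_hvg(ds, 500), "available")
})

test_that("cell-type profiles isolate type-specific expression", {
  counts <- matrix(0L, nrow = 2, ncol = 6,
                   dimnames = list(c("lig", "other"), sprintf("c%d", 1:6)))
  counts["lig", 1:3] <- c(4L, 2L, 3L)
  counts["other", ] <- 1L
  ds <- sc_normalize(make_ds(counts, rep(c("T", "U"), each = 3)))
  prof <- celltype_profile(ds, "lig")
  expect_gt(prof$mean_norm[prof$cell_type == "T"], 0)
  expect_equal(prof$mean_norm[prof$cell_type == "U"], 0)
  profo <- celltype_profile(ds, "other")
  expect_true(all(profo$frac_detected == 1))
  expect_error(celltype_profile(ds, "missing_gene"), "unknown gene")

  # planted sender-elevated ligand tops every other type (fold 5, 200 cells/type)
  spec <- sc_sim_spec(n_cells_per_type = 200, n_genes = 50, seed = 3)
  sim <- simulate_single_cell(spec)
  ds2 <- sc_normalize(sim$dataset)
  prof2 <- celltype_profile(ds2, "SG001")
  sender_mean <- prof2$mean_norm[prof2$cell_type == "oligodendrocyte"]
  expect_true(all(sender_mean > prof2$mean_norm[prof2$cell_type != "oligodendrocyte"]))
})

test_that("marker detection is symmetric, calibrated, and powered for planted effects", {
  set.seed(7)
  counts <- matrix(rnbinom(60 * 200, size = 2, mu = 2), nrow = 60,
                   dimnames = list(sprintf("g%02d", 1:60), sprintf("c%03d", 1:200)))
  counts[1, ] <- pmax(counts[1, ], 1L)
  types <- rep(c("A", "B"), each = 100)
  # plant a fold-4 gene in group A
  counts["g05", types == "A"] <- rnbinom(100, size = 2, mu = 8)
  ds <- sc_normalize(make_ds(counts, types))
  res <- find_markers(ds, "cell_type", "A", "B", min_frac = 0, min_lfc = 0)
  expect_lt(res$q[res$gene == "g05"], 0.05)

  # swap symmetry: lfc negates, p unchanged
  res_swap <- find_markers(ds, "cell_type", "B", "A", min_frac = 0, min_lfc = 0)
  m <- merge(res, res_swap, by = "gene")
  expect_equal(m$lfc.x, -m$lfc.y, tolerance = 1e-12)
  expect_equal(m$p.x, m$p.y, tolerance = 1e-12)

  # identical groups (same cells duplicated) -> all p = 1
  dup_counts <- cbind(counts[, 1:50], counts[, 1:50])
  colnames(dup_counts) <- sprintf("d%03d", 1:100)
  dup <- sc_normalize(make_ds(dup_counts, rep(c("X", "Y"), each = 50)))
  res_dup <- find_markers(dup, "cell_type", "X", "Y", min_frac = 0, min_lfc = 0)
  expect_true(all(res_dup$p == 1))
  expect_error(find_markers(ds, "cell_type", "A", "ZZ"), "empty group")

  # shares the Wilcoxon implementation exactly
  g <- "g07"
  manual <- wilcoxon_rank_sum(ds$normalized[g, types == "A"],
                              ds$normalized[g, types == "B"])$p
  expect_equal(res$p[res$gene == g], manual, tolerance = 1e-15)
})

test_that("the ECM score matrix is -log10(q) over token-matched pathways", {
  ora_a <- data.frame(set = c("NABA_ECM", "KEGG_OTHER"), q = c(0.01, 0.5),
                      p = c(0.001, 0.2))
  ora_b <- data.frame(set = c("NABA_ECM", "KEGG_OTHER"), q = c(1, 1),
                      p = c(1, 1))
  m <- ecm_score_matrix(list(astro = ora_a, micro = ora_b))
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(m["astro", "NABA_ECM"], 2)
  expect_equal(m["micro", "NABA_ECM"], 0)
  expect_true(all(m >= 0))
  expect_warning(m0 <- ecm_score_matrix(list(a = data.frame(set = "X", q = 1,
                                                            p = 1))),
                 "no pathway")
  expect_equal(ncol(m0), 0L)
})

test_that("ligand-receptor scores follow the saturation model", {
  # construct a dataset with known normalized means
  counts <- matrix(0L, nrow = 3, ncol = 4,
                   dimnames = list(c("L", "R", "house"), sprintf("c%d", 1:4)))
  counts["house", ] <- 10L
  counts["L", 1:2] <- 5L   # sender cells
  counts["R", 3:4] <- 5L   # receiver cells
  ds <- sc_normalize(make_ds(counts, c("S", "S", "T", "T")), scale = 1)
  pairs <- data.frame(pair_id = "p1", ligand = "L", receptor = "R",
                      stringsAsFactors = FALSE)
  res <- ligand_receptor_score(ds, pairs, "S", "T", Kh = 0.5)
  LR <- res$L * res$R
  expect_equal(res$score, LR / (0.5 + LR), tolerance = 1e-12)

  # absent ligand in sender -> score 0
  res_rev <- ligand_receptor_score(ds, pairs, "T", "S", Kh = 0.5)
  expect_equal(res_rev$score, 0)

  # L=1, R=1, Kh=0.5 -> 2/3 (mass-action check via the formula directly)
  expect_equal(1 * 1 / (0.5 + 1), 2 / 3)

  # monotone in L, bounded by 1
  s <- function(L, R, Kh = 0.5) L * R / (Kh + L * R)
  Ls <- seq(0.1, 10, length.out = 50)
  vals <- s(Ls, 1)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 1))

  expect_error(ligand_receptor_score(ds, pairs, "S", "T", Kh = 0), "Kh")
  pairs_bad <- data.frame(pair_id = "p2", ligand = "NOPE", receptor = "R")
  expect_warning(expect_error(
    ligand_receptor_score(ds, pairs_bad, "S", "T"), "no scorable"), "skipped")

  # multi-subunit receptor: geometric mean; zero subunit collapses the score
  counts2 <- rbind(counts, R2 = 0L)
  rownames(counts2)[4] <- "R2"
  ds2 <- sc_normalize(make_ds(counts2, c("S", "S", "T", "T")), scale = 1)
  pairs2 <- data.frame(pair_id = "p3", ligand = "L", receptor = "R;R2")
  res2 <- ligand_receptor_score(ds2, pairs2, "S", "T")
  expect_equal(res2$score, 0)
})

test_that("interaction permutation p-values respect the floor and detect planted pairs", {
  spec <- sc_sim_spec(n_cells_per_type = 200, n_genes = 40, seed = 13)
  sim <- simulate_single_cell(spec)
  ds <- sc_normalize(sim$dataset)
  pair <- data.frame(pair_id = "planted", ligand = "SG001", receptor = "SG002")
  res <- interaction_permutation_test(ds, pair, "oligodendrocyte", "astrocyte",
                                      n_perm = 100, seed = 2)
  expect_equal(res$p, 1 / 101, tolerance = 1e-12)
  expect_gte(res$p, 1 / (100 + 1))
  expect_error(interaction_permutation_test(ds, pair, "oligodendrocyte",
                                            "astrocyte", n_perm = 0), "n_perm")
})

test_that("normalization + profiling is invariant to per-cell depth rescaling", {
  set.seed(19)
  counts <- matrix(rpois(40 * 30, 2), nrow = 40,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:30)))
  counts[1, ] <- counts[1, ] + 1
  types <- rep(c("A", "B", "C"), each = 10)
  ds1 <- sc_normalize(make_ds(counts, types))
  # rescale sequencing depth per cell by integer factors
  factors <- sample(1:5, 30, replace = TRUE)
  counts2 <- sweep(counts, 2, factors, "*")
  ds2 <- sc_normalize(make_ds(counts2, types))
  p1 <- celltype_profile(ds1, "g05")
  p2 <- celltype_profile(ds2, "g05")
  expect_equal(p1$mean_norm, p2$mean_norm, tolerance = 1e-12)
  expect_equal(p1$frac_detected, p2$frac_detected)
})
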