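#' Bulk simulation specification
#'
#' Describes a multi-cohort case/control bulk expression simulation with
#' planted ground truth: per-gene Gaussian log-expression, differential
#' genes shifted by a true standardized mean difference delta in cases, an
#' optional correlated gene pair, a pathway collection with a planted hub
#' glycogene, and an optional pathway whose latent activity linearly drives
#' the ECM outcome. Defaults mirror a three-cohort brain study (one, four
#' and two regions respectively — seven strata) at desk scale.
#'
#' @param n_cohorts Number of cohorts (default 3).
#' @param regions_per_cohort Integer vector of regions per cohort
#'   (default `c(1, 4, 2)`).
#' @param n_genes Number of genes (default 500).
#' @param n_per_arm Samples per arm (case and control) per stratum
#'   (default 20).
#' @param n_glycogenes Number of genes annotated as glycogenes
#'   (default 40); glycogenes are the first `n_glycogenes` genes.
#' @param de_genes Character vector of planted DE genes (subset of the gene
#'   universe; default none).
#' @param delta True standardized mean difference for planted DE genes
#'   (scalar or one per DE gene; default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution of the
#'   Gaussian log-expression (defaults 5 and 1).
#' @param cor_pair Optional `list(genes = c(g1, g2), rho = r)` planting a
#'   bivariate-Gaussian correlation.
#' @param hub Optional `list(gene = g, n_sets = m)` planting a glycogene
#'   into exactly `m` enrichable pathways.
#' @param pathways `list(n_sets, size_range, n_enrichable, seed_fraction,
#'   decoys = list(genes, max_sets))` controlling [simulate_pathways()].
#' @param ecm_driver Optional `list(coefficient, noise_sd, n_ecm_genes,
#'   n_driver_genes, loading)` planting a pathway whose latent activity
#'   drives the ECM signature genes.
#' @param seed Integer seed.
#' @return Object of class `bulk_sim_spec`.
#' @export
bulk_sim_spec <- function(n_cohorts = 3L, regions_per_cohort = c(1L, 4L, 2L),
                          n_genes = 500L, n_per_arm = 20L, n_glycogenes = 40L,
                          de_genes = character(), delta = 1,
                          baseline_mean = 5, baseline_sd = 1,
                          cor_pair = NULL, hub = NULL,
                          pathways = list(n_sets = 40L, size_range = c(10L, 20L),
                                          n_enrichable = 10L, seed_fraction = 0.4,
                                          decoys = NULL),
                          ecm_driver = NULL, seed = 1L) {
  if (length(regions_per_cohort) != n_cohorts)
    stop2("'regions_per_cohort' needs one entry per cohort")
  if (any(c(n_cohorts, regions_per_cohort, n_genes, n_per_arm) < 1))
    stop2("all counts must be positive")
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (length(setdiff(de_genes, genes)))
    stop2("planted DE gene(s) outside the gene universe")
  if (!is.null(cor_pair)) {
    if (abs(cor_pair$rho) > 1) stop2("|rho| must be <= 1")
    if (length(setdiff(cor_pair$genes, genes)))
      stop2("correlated pair outside the gene universe")
  }
  delta <- rep_len(delta, length(de_genes))
  structure(list(n_cohorts = n_cohorts, regions_per_cohort = regions_per_cohort,
                 n_genes = n_genes, n_per_arm = n_per_arm,
                 n_glycogenes = n_glycogenes, genes = genes,
                 de_genes = de_genes, delta = delta,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 cor_pair = cor_pair, hub = hub, pathways = pathways,
                 ecm_driver = ecm_driver, seed = seed),
            class = "bulk_sim_spec")
}

#' Simulate multi-cohort bulk expression with planted effects
#'
#' Per cohort x region stratum, draws Gaussian log-expression with per-gene
#' baselines, shifts planted DE genes by `delta * SD` in the case arm,
#' draws the planted correlated pair from a bivariate Gaussian at the
#' requested rho, and (when an ECM driver is specified) gives the driver
#' pathway's genes a shared per-sample latent activity that linearly drives
#' the ECM signature genes at the stated coefficient and noise SD.
#'
#' @param spec A [bulk_sim_spec()].
#' @return List with `cohorts` (list of [expr_matrix()], one per cohort)
#'   and `truth` (record of all planted structure, including the gene names
#'   of the ECM signature and the driver pathway when present).
#' @export
simulate_bulk <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  with_seed(spec$seed, {
    genes <- spec$genes
    n_genes <- spec$n_genes
    base_mu <- stats::rnorm(n_genes, spec$baseline_mean, 0.5)
    base_sd <- rep_len(spec$baseline_sd, n_genes)
    names(base_mu) <- names(base_sd) <- genes
    drv <- spec$ecm_driver
    ecm_genes <- driver_genes <- character()
    if (!is.null(drv)) {
      pool <- setdiff(genes, c(spec$de_genes, spec$cor_pair$genes))
      ecm_genes <- pool[seq_len(drv$n_ecm_genes)]
      driver_genes <- pool[drv$n_ecm_genes + seq_len(drv$n_driver_genes)]
    }
    cohorts <- vector("list", spec$n_cohorts)
    for (co in seq_len(spec$n_cohorts)) {
      mats <- list()
      for (re in seq_len(spec$regions_per_cohort[co])) {
        n1 <- spec$n_per_arm; n0 <- spec$n_per_arm
        n <- n1 + n0
        condition <- c(rep("case", n1), rep("control", n0))
        X <- matrix(stats::rnorm(n_genes * n, base_mu, base_sd),
                    nrow = n_genes, ncol = n)
        rownames(X) <- genes
        if (length(spec$de_genes)) {
          shift <- spec$delta * base_sd[spec$de_genes]
          X[spec$de_genes, condition == "case"] <-
            X[spec$de_genes, condition == "case"] + shift
        }
        if (!is.null(spec$cor_pair)) {
          rho <- spec$cor_pair$rho
          gpair <- spec$cor_pair$genes
          z1 <- stats::rnorm(n)
          z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
          X[gpair[1L], ] <- base_mu[gpair[1L]] + base_sd[gpair[1L]] * z1
          X[gpair[2L], ] <- base_mu[gpair[2L]] + base_sd[gpair[2L]] * z2
        }
        if (!is.null(drv)) {
          act <- stats::rnorm(n)                       # latent driver activity
          load <- drv$loading %||% 1
          X[driver_genes, ] <- X[driver_genes, ] + load *
            matrix(act, nrow = length(driver_genes), ncol = n, byrow = TRUE)
          ecm_act <- drv$coefficient * act + stats::rnorm(n, 0, drv$noise_sd)
          X[ecm_genes, ] <- X[ecm_genes, ] +
            matrix(ecm_act, nrow = length(ecm_genes), ncol = n, byrow = TRUE)
        }
        samples <- sprintf("C%d_R%d_S%03d", co, re, seq_len(n))
        colnames(X) <- samples
        meta <- data.frame(sample = samples, cohort = sprintf("cohort%d", co),
                           region = sprintf("region%d", re),
                           condition = condition, stringsAsFactors = FALSE)
        mats[[re]] <- list(values = X, meta = meta)
      }
      values <- do.call(cbind, lapply(mats, `[[`, "values"))
      meta <- do.call(rbind, lapply(mats, `[[`, "meta"))
      cohorts[[co]] <- expr_matrix(values, meta)
    }
    truth <- list(de_genes = spec$de_genes, delta = spec$delta,
                  glycogenes = genes[seq_len(spec$n_glycogenes)],
                  cor_pair = spec$cor_pair, hub = spec$hub,
                  ecm_genes = ecm_genes, driver_genes = driver_genes,
                  seed = spec$seed)
    list(cohorts = cohorts, truth = truth)
  })
}

#' Simulate a pathway collection with planted hub structure
#'
#' Builds `n_sets` gene sets: the first `n_enrichable` sets are "enrichable"
#' — each is seeded with `seed_fraction` of its members drawn from the
#' planted DE genes (so preranked enrichment can find them); the planted
#' hub glycogene is placed into exactly `hub$n_sets` of them and decoy
#' glycogenes into at most `decoys$max_sets` each. Remaining sets are
#' background. When an ECM driver is planted, one extra set named
#' `"ECM_ORGANIZATION_SIGNATURE"` holds the ECM signature genes and one
#' (`"DRIVER_PATHWAY"`) the driver genes.
#'
#' @param spec A [bulk_sim_spec()].
#' @param truth The truth record from [simulate_bulk()] (supplies ECM and
#'   driver gene identities); optional when no driver is planted.
#' @return A [gene_set_collection()].
#' @export
simulate_pathways <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  pw <- spec$pathways
  hub <- spec$hub
  if (!is.null(hub) && hub$n_sets > pw$n_enrichable)
    stop2("hub membership (%d) exceeds the number of enrichable sets (%d)",
          hub$n_sets, pw$n_enrichable)
  with_seed(spec$seed + 104729L, {
    genes <- spec$genes
    glyco <- genes[seq_len(spec$n_glycogenes)]
    decoys <- pw$decoys
    # hub and decoy genes enter sets only through their explicit assignments
    reserved <- c(hub$gene, decoys$genes)
    de_pool <- setdiff(spec$de_genes, reserved)
    filler_pool <- setdiff(genes, c(spec$de_genes, glyco))
    sets <- vector("list", pw$n_sets)
    names(sets) <- sprintf("SET_%03d", seq_len(pw$n_sets))
    sizes <- sample(seq(pw$size_range[1L], pw$size_range[2L]),
                    pw$n_sets, replace = TRUE)
    decoy_assign <- list()
    if (!is.null(decoys)) {
      for (g in decoys$genes) {
        m <- sample.int(decoys$max_sets, 1L)
        decoy_assign[[g]] <- sample.int(pw$n_enrichable, min(m, pw$n_enrichable))
      }
    }
    for (i in seq_len(pw$n_sets)) {
      size <- sizes[i]
      members <- character()
      if (i <= pw$n_enrichable && length(de_pool)) {
        n_seed <- max(1L, round(pw$seed_fraction * size))
        members <- sample(de_pool, min(n_seed, length(de_pool)))
      }
      if (!is.null(hub) && i <= pw$n_enrichable) {
        in_hub <- i <= hub$n_sets
        if (in_hub) members <- union(members, hub$gene)
      }
      for (g in names(decoy_assign))
        if (i %in% decoy_assign[[g]]) members <- union(members, g)
      n_fill <- max(0L, size - length(members))
      members <- c(members, sample(filler_pool, n_fill))
      sets[[i]] <- unique(members)
    }
    if (!is.null(truth) && length(truth$ecm_genes)) {
      sets[["ECM_ORGANIZATION_SIGNATURE"]] <- truth$ecm_genes
      sets[["DRIVER_PATHWAY"]] <- truth$driver_genes
    }
    gene_set_collection(sets, rep("synthetic pathway", length(sets)))
  })
}

#' Single-cell simulation specification
#'
#' Describes a labeled single-cell count simulation: negative-binomial
#' counts with gene-specific means and a common dispersion, a planted
#' ligand-receptor pair whose ligand mean is multiplied by `fold_up` in the
#' sender type and receptor in the receiver type, and a planted
#' co-expression module whose members share a latent factor within one cell
#' type. Defaults mirror a small cerebrovascular-style dataset with four
#' cell types under two conditions.
#'
#' @param n_cells_per_type Cells per type (default 200).
#' @param cell_types Character labels (default oligodendrocyte, astrocyte,
#'   pericyte, endothelial).
#' @param conditions Condition labels assigned alternately (default
#'   `c("NCI", "AD")`).
#' @param n_genes Number of genes (default 150).
#' @param mean_range Range of per-gene NB means (default `c(0.5, 5)`).
#' @param dispersion NB size parameter, must be > 0 (default 2).
#' @param lr_pair `list(ligand, receptor, sender, receiver, fold_up)`;
#'   `fold_up = 1` plants nothing. Default: gene L001 -> R001 from the
#'   first to the second cell type at fold 5.
#' @param module Optional `list(seeds, members, loading, cell_type)`
#'   planting a latent-factor co-expression module.
#' @param seed Integer seed.
#' @return Object of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(n_cells_per_type = 200L,
                        cell_types = c("oligodendrocyte", "astrocyte",
                                       "pericyte", "endothelial"),
                        conditions = c("NCI", "AD"),
                        n_genes = 150L, mean_range = c(0.5, 5),
                        dispersion = 2,
                        lr_pair = list(ligand = "SG001", receptor = "SG002",
                                       sender = "oligodendrocyte",
                                       receiver = "astrocyte", fold_up = 5),
                        module = NULL, seed = 1L) {
  if (dispersion <= 0) stop2("'dispersion' must be > 0")
  genes <- sprintf("SG%03d", seq_len(n_genes))
  if (!is.null(lr_pair)) {
    if (lr_pair$fold_up < 1) stop2("'fold_up' must be >= 1")
    if (!all(c(lr_pair$sender, lr_pair$receiver) %in% cell_types))
      stop2("sender/receiver must be among the cell types")
    if (!all(c(lr_pair$ligand, lr_pair$receptor) %in% genes))
      stop2("ligand/receptor must be in the gene universe")
  }
  if (!is.null(module)) {
    if (length(setdiff(c(module$seeds, module$members), genes)))
      stop2("module genes outside the gene universe")
    if (!module$cell_type %in% cell_types)
      stop2("module cell type must be among the cell types")
  }
  structure(list(n_cells_per_type = n_cells_per_type, cell_types = cell_types,
                 conditions = conditions, n_genes = n_genes, genes = genes,
                 mean_range = mean_range, dispersion = dispersion,
                 lr_pair = lr_pair, module = module, seed = seed),
            class = "sc_sim_spec")
}

#' Simulate a labeled single-cell count dataset
#'
#' Negative-binomial counts per gene and cell. The planted ligand's mean is
#' multiplied by `fold_up` in sender cells and the receptor's in receiver
#' cells; planted module genes (and seeds) get their log-mean shifted by a
#' shared per-cell latent factor scaled by `loading` within the module's
#' cell type, so their pairwise correlations exceed background there.
#'
#' @param spec An [sc_sim_spec()].
#' @return List with `dataset` (an [sc_dataset()]) and `truth`.
#' @export
simulate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  with_seed(spec$seed, {
    n_types <- length(spec$cell_types)
    n_cells <- spec$n_cells_per_type * n_types
    cell_type <- rep(spec$cell_types, each = spec$n_cells_per_type)
    condition <- rep_len(spec$conditions, n_cells)
    genes <- spec$genes
    base_mu <- stats::runif(spec$n_genes, spec$mean_range[1L], spec$mean_range[2L])
    names(base_mu) <- genes
    lr0 <- spec$lr_pair
    if (!is.null(lr0))   # planted pair starts from a mid-range baseline
      base_mu[c(lr0$ligand, lr0$receptor)] <- mean(spec$mean_range)
    M <- matrix(base_mu, nrow = spec$n_genes, ncol = n_cells)
    rownames(M) <- genes
    lr <- spec$lr_pair
    if (!is.null(lr) && lr$fold_up > 1) {
      M[lr$ligand, cell_type == lr$sender] <-
        M[lr$ligand, cell_type == lr$sender] * lr$fold_up
      M[lr$receptor, cell_type == lr$receiver] <-
        M[lr$receptor, cell_type == lr$receiver] * lr$fold_up
    }
    mod <- spec$module
    if (!is.null(mod) && (mod$loading %||% 0) > 0) {
      in_type <- cell_type == mod$cell_type
      z <- stats::rnorm(sum(in_type))
      mod_genes <- unique(c(mod$seeds, mod$members))
      shift <- exp(mod$loading * matrix(z, nrow = length(mod_genes),
                                        ncol = sum(in_type), byrow = TRUE) -
                   mod$loading^2 / 2)
      M[mod_genes, in_type] <- M[mod_genes, in_type] * shift
    }
    counts <- matrix(stats::rnbinom(length(M), size = spec$dispersion,
                                    mu = as.numeric(M)),
                     nrow = nrow(M))
    dimnames(counts) <- list(genes, sprintf("cell%05d", seq_len(n_cells)))
    # guard against all-zero cells at tiny sizes: give them one count
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1L, zero] <- 1L
    ds <- sc_dataset(counts, cell_type, condition)
    truth <- list(lr_pair = lr, module = mod, base_mu = base_mu,
                  seed = spec$seed)
    list(dataset = ds, truth = truth)
  })
}

#' Write a truth record as JSON
#'
#' Truth records from the simulators are plain lists; this serializes them
#' to a machine-readable JSON file for use as a language-agnostic fixture.
#'
#' @param truth Truth record list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop2("writing truth records requires the 'jsonlite' package")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
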