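#' Configuration for the synthetic chimera experiment
#'
#' The generator emulates the moving parts of a chimera perturbation
#' experiment: (i) cell-group composition with per-group true odds ratios on
#' the marker-positive fraction of the target chimeras, followed by
#' fixed-quota sampling per fraction (the sorting step that creates the
#' compositional bias); (ii) NB counts following the interaction expression
#' model with gene-wise dispersion, lognormal size factors and pool-level
#' random intercepts; (iii) a 1-D latent developmental time per cell with
#' optional delay of the marker-positive target cells in chosen lineages,
#' Dirichlet fate rows centred on the true lineage, and temporal genes that
#' are monotone (sigmoid) functions of latent time.
#'
#' Defaults describe a desk-scale experiment: 10 equally sized groups, 1000
#' latent cells per group and fraction with half of each fraction sampled
#' (roughly 500 observed cells per group and fraction), 3 pools per dataset,
#' pool intercept SD 0.3 on the log scale, 100 genes with lognormal
#' dispersions around 0.5, fate concentration 20, and no true effects
#' (`or = 1`, `b3 = 0`, `delta = 0`) unless requested.
#'
#' @param n_groups Number of cell groups.
#' @param group_props Baseline group proportions (recycled, normalized).
#' @param or Per-group true odds ratio applied to the marker-positive
#'   fraction of the target dataset (length `n_groups`; 1 = no effect).
#' @param latent_per_fraction Latent cells generated per dataset x marker
#'   fraction before quota sampling.
#' @param quota_frac Fraction of each latent pool kept by the fixed quota.
#' @param n_pools Pools (batches) per dataset.
#' @param sigma_pool SD of the per-gene pool random intercept (log scale).
#' @param n_genes Genes for [simulate_counts()].
#' @param b1,b2 Marker and condition fixed effects (scalar or per gene).
#' @param b3 Interaction effect per gene (scalar or length `n_genes`).
#' @param phi_meanlog,phi_sdlog Lognormal parameters of gene dispersions.
#' @param alpha_meanlog,alpha_sdlog Lognormal parameters of baseline means.
#' @param sf_sdlog Size-factor lognormal SD.
#' @param stage_levels Stage vocabulary (subset of a ladder).
#' @param delta Developmental shift of marker-positive target cells in
#'   `shifted_lineages`, in units of the within-lineage latent-time SD
#'   (positive = delayed, i.e. earlier latent time).
#' @param shifted_lineages Lineages (= groups) receiving the shift.
#' @param fate_conc Dirichlet concentration on the true lineage (`Inf` =
#'   one-hot fates).
#' @param n_temporal,n_batch_genes,n_noise_genes Gene counts for
#'   [simulate_fates_and_time()] expression output.
#' @return A `cosicc_sim_config` list.
#' @export
sim_config <- function(n_groups = 10,
                       group_props = rep(1, n_groups),
                       or = rep(1, n_groups),
                       latent_per_fraction = n_groups * 1000,
                       quota_frac = 0.5,
                       n_pools = 3,
                       sigma_pool = 0.3,
                       n_genes = 100,
                       b1 = 0, b2 = 0, b3 = 0,
                       phi_meanlog = log(0.5), phi_sdlog = 0.4,
                       alpha_meanlog = log(5), alpha_sdlog = 0.7,
                       sf_sdlog = 0.2,
                       stage_levels = default_stage_order()[5:12],
                       delta = 0,
                       shifted_lineages = character(0),
                       fate_conc = 20,
                       n_temporal = 30, n_batch_genes = 5,
                       n_noise_genes = 15) {
  group_props <- rep_len(group_props, n_groups)
  group_props <- group_props / sum(group_props)
  or <- rep_len(or, n_groups)
  if (any(or <= 0)) stop_cosicc("true odds ratios must be positive",
                                "config")
  if (quota_frac <= 0 || quota_frac > 1)
    stop_cosicc("quota_frac must be in (0, 1]", "config")
  structure(as.list(environment()), class = "cosicc_sim_config")
}

#' Simulate the cell composition of a chimera experiment
#'
#' For each dataset (target/control) and marker fraction (pos/neg), latent
#' cells are drawn multinomially over groups; the marker-positive fraction
#' of the target dataset uses proportions reweighted by the per-group true
#' odds ratios. Each fraction is then subsampled without replacement to its
#' fixed quota -- reproducing the sorting step in which a predetermined
#' number of cells per fraction is collected, which converts a true
#' depletion of one group into apparent enrichment of all others. Pools are
#' assigned uniformly within dataset; stages uniformly over the vocabulary.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A [cell_table()] with attribute `truth` (per-group true OR).
#' @export
simulate_composition <- function(cfg, seed = 1) {
  groups <- sprintf("group%02d", seq_len(cfg$n_groups))
  quota <- round(cfg$latent_per_fraction * cfg$quota_frac)
  if (quota > cfg$latent_per_fraction)
    stop_cosicc("quota exceeds the latent pool", "config")
  frames <- list()
  with_seed(seed, {
    for (ds in c("target", "control")) {
      for (mk in c("pos", "neg")) {
        props <- cfg$group_props
        if (ds == "target" && mk == "pos") {
          props <- props * cfg$or
          props <- props / sum(props)
        }
        latent <- as.vector(rmultinom(1, cfg$latent_per_fraction, props))
        pool_of_cells <- rep.int(seq_len(cfg$n_groups), latent)
        take <- sample.int(length(pool_of_cells), quota)
        glab <- groups[pool_of_cells[take]]
        frames[[paste(ds, mk)]] <- data.frame(
          dataset = ds, marker = mk, group = glab,
          stage = sample(cfg$stage_levels, quota, replace = TRUE),
          pool_id = paste0(ifelse(ds == "target", "TP", "CP"),
                           sample.int(cfg$n_pools, quota, replace = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
  })
  df <- do.call(rbind, frames)
  df$cell_id <- sprintf("cell%06d", seq_len(nrow(df)))
  tab <- cell_table(df, stage_order = default_stage_order())
  attr(tab, "truth") <- data.frame(group = groups, true_or = cfg$or,
                                   prop = cfg$group_props, row.names = NULL)
  tab
}

#' Simulate NB counts under the interaction expression model
#'
#' Counts follow `y ~ NB(mu, phi_i)` with
#' `mu = pi_j exp(alpha_i + b1 m + b2 t + b3 m t + w_{i,pool})`,
#' `w_{i,pool} ~ N(0, sigma_pool^2)` independently per gene and pool, and
#' lognormal size factors normalized to mean 1.
#'
#' @param cfg A [sim_config()].
#' @param table A [cell_table()] (e.g. from [simulate_composition()]).
#' @param seed Integer seed.
#' @return A [count_matrix()] whose size factors are the true simulated
#'   ones, with attribute `truth` (gene-level data.frame: `alpha`, `b1`,
#'   `b2`, `b3`, `phi`).
#' @export
simulate_counts <- function(cfg, table, seed = 1) {
  n <- nrow(table)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  m <- as.numeric(table$marker == "pos")
  t_ <- as.numeric(table$dataset == "target")
  pools <- factor(table$pool_id)
  with_seed(seed, {
    alpha <- rnorm(cfg$n_genes, cfg$alpha_meanlog, cfg$alpha_sdlog)
    phi <- rlnorm(cfg$n_genes, cfg$phi_meanlog, cfg$phi_sdlog)
    b1 <- rep_len(cfg$b1, cfg$n_genes)
    b2 <- rep_len(cfg$b2, cfg$n_genes)
    b3 <- rep_len(cfg$b3, cfg$n_genes)
    sf <- rlnorm(n, 0, cfg$sf_sdlog)
    sf <- sf / mean(sf)
    w <- matrix(rnorm(cfg$n_genes * nlevels(pools), 0, cfg$sigma_pool),
                cfg$n_genes, nlevels(pools))
    counts <- matrix(0L, cfg$n_genes, n)
    pool_idx <- as.integer(pools)
    for (i in seq_len(cfg$n_genes)) {
      mu <- sf * exp(alpha[i] + b1[i] * m + b2[i] * t_ + b3[i] * m * t_ +
                       w[i, pool_idx])
      counts[i, ] <- rnbinom(n, mu = mu, size = 1 / phi[i])
    }
  })
  dimnames(counts) <- list(genes, table$cell_id)
  cm <- count_matrix(counts, size_factors = sf)
  attr(cm, "truth") <- data.frame(gene = genes, alpha = alpha, b1 = b1,
                                  b2 = b2, b3 = b3, phi = phi,
                                  row.names = NULL)
  attr(cm, "pool_effects") <- w
  cm
}

#' Simulate fate matrices, latent developmental time and temporal genes
#'
#' Lineages coincide with groups (each group is a terminal type). Latent
#' time is uniform within the cell's stage band (stages tile `[0, 1]`);
#' marker-positive target cells of the configured lineages are shifted
#' earlier by `delta` within-lineage SDs (a developmental delay). Fate rows
#' are Dirichlet draws concentrated on the true lineage. Expression output
#' contains temporal genes (gene-specific sigmoid functions of latent
#' time), batch genes (functions of the pool), and pure-noise genes, as NB
#' counts with unit-mean size factors.
#'
#' @param cfg A [sim_config()].
#' @param table A [cell_table()].
#' @param seed Integer seed.
#' @param gene_meta Optional gene metadata from a previous call (e.g. on
#'   reference cells) so that query and reference share link functions.
#' @return List: `fates` ([fate_matrix()]), `time` (named true latent
#'   times), `counts` ([count_matrix()]), `gene_meta`.
#' @export
simulate_fates_and_time <- function(cfg, table, seed = 1, gene_meta = NULL) {
  n <- nrow(table)
  lineages <- sort(unique(table$group))
  stage_idx <- match(as.character(table$stage), cfg$stage_levels)
  if (anyNA(stage_idx))
    stop_cosicc("table stages outside cfg$stage_levels", "config")
  ns <- length(cfg$stage_levels)
  with_seed(seed, {
    time <- (stage_idx - 1 + runif(n)) / ns
    # developmental delay of perturbed cells
    if (cfg$delta != 0 && length(cfg$shifted_lineages) > 0) {
      for (l in cfg$shifted_lineages) {
        in_l <- table$group == l
        sdt <- sd(time[in_l])
        hit <- in_l & table$dataset == "target" & table$marker == "pos"
        time[hit] <- time[hit] - cfg$delta * sdt
      }
    }
    # Dirichlet fate rows centred on the true lineage
    L <- length(lineages)
    truth_idx <- match(table$group, lineages)
    if (is.infinite(cfg$fate_conc)) {
      fates <- matrix(0, n, L)
      fates[cbind(seq_len(n), truth_idx)] <- 1
    } else {
      shape <- matrix(1, n, L)
      shape[cbind(seq_len(n), truth_idx)] <- cfg$fate_conc
      g <- matrix(rgamma(n * L, shape = shape), n, L)
      fates <- g / rowSums(g)
    }
    dimnames(fates) <- list(table$cell_id, lineages)

    if (is.null(gene_meta)) {
      gene_meta <- data.frame(
        gene = c(sprintf("tgene%03d", seq_len(cfg$n_temporal)),
                 sprintf("bgene%03d", seq_len(cfg$n_batch_genes)),
                 sprintf("ngene%03d", seq_len(cfg$n_noise_genes))),
        kind = rep(c("temporal", "batch", "noise"),
                   c(cfg$n_temporal, cfg$n_batch_genes,
                     cfg$n_noise_genes)),
        midpoint = c(runif(cfg$n_temporal, 0.15, 0.85),
                     rep(NA, cfg$n_batch_genes + cfg$n_noise_genes)),
        slope = c(sample(c(-1, 1), cfg$n_temporal, TRUE) *
                    runif(cfg$n_temporal, 6, 14),
                  rep(NA, cfg$n_batch_genes + cfg$n_noise_genes)),
        amplitude = c(runif(cfg$n_temporal, 1.5, 3),
                      rep(NA, cfg$n_batch_genes + cfg$n_noise_genes)),
        row.names = NULL)
    }
    pools <- factor(table$pool_id)
    ng <- nrow(gene_meta)
    counts <- matrix(0L, ng, n)
    base <- log(10)
    for (i in seq_len(ng)) {
      eta <- switch(gene_meta$kind[i],
        temporal = base + gene_meta$amplitude[i] *
          plogis(gene_meta$slope[i] * (time - gene_meta$midpoint[i])),
        batch = base + 1.5 * (as.integer(pools) %% 2),
        noise = base)
      counts[i, ] <- rnbinom(n, mu = exp(eta), size = 1 / 0.1)
    }
  })
  dimnames(counts) <- list(gene_meta$gene, table$cell_id)
  cm <- count_matrix(counts, size_factors = rep(1, n))
  list(fates = fate_matrix(fates, tol = 1e-6),
       time = setNames(time, table$cell_id),
       counts = cm, gene_meta = gene_meta)
}

#' Simulate a stand-alone reference atlas
#'
#' Reference cells (no chimera structure) spanning the configured stages,
#' with batch labels and the same temporal/batch/noise gene links as
#' [simulate_fates_and_time()], for pseudotime anchoring.
#'
#' @param cfg A [sim_config()].
#' @param n_cells Reference cells.
#' @param n_batches Reference batches.
#' @param seed Integer seed.
#' @return List: `counts`, `stages`, `batches`, `time`, `gene_meta`.
#' @export
simulate_reference <- function(cfg, n_cells = 400, n_batches = 2, seed = 1) {
  with_seed(substream_seed(seed, 77L), {
    stages <- sample(cfg$stage_levels, n_cells, replace = TRUE)
    batch <- paste0("ref_b", sample.int(n_batches, n_cells, replace = TRUE))
  })
  df <- data.frame(cell_id = sprintf("ref%05d", seq_len(n_cells)),
                   dataset = "control", marker = "neg", group = "ref",
                   stage = stages, pool_id = batch,
                   stringsAsFactors = FALSE)
  tab <- cell_table(df, stage_order = default_stage_order())
  sim <- simulate_fates_and_time(cfg, tab, seed = substream_seed(seed, 78L))
  list(counts = sim$counts, stages = stages, batches = batch,
       time = sim$time, gene_meta = sim$gene_meta)
}

#' Write a full synthetic experiment to disk
#'
#' Writes `cells.tsv`, `counts.mtx` (+ `genes.tsv`, `cells_barcodes.tsv`,
#' `size_factors.tsv`), `fates.csv` and ground-truth tables under `truth/`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @return `dir`, invisibly.
#' @export
simulate_experiment <- function(cfg, dir, seed = 1) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  tab <- simulate_composition(cfg, seed = substream_seed(seed, 1L))
  cm <- simulate_counts(cfg, tab, seed = substream_seed(seed, 2L))
  ft <- simulate_fates_and_time(cfg, tab, seed = substream_seed(seed, 3L))
  write_cell_table(tab, file.path(dir, "cells.tsv"))
  write_counts(cm, file.path(dir, "counts.mtx"),
               file.path(dir, "genes.tsv"),
               file.path(dir, "cells_barcodes.tsv"),
               file.path(dir, "size_factors.tsv"))
  write_fate_matrix(ft$fates, file.path(dir, "fates.csv"))
  write.table(attr(tab, "truth"), file.path(dir, "truth", "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(attr(cm, "truth"), file.path(dir, "truth", "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = names(ft$time), time = unname(ft$time)),
              file.path(dir, "truth", "latent_time.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
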