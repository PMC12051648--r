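test_that("null composition has matched fractions and fixed quotas", {
  cfg <- sim_config(n_groups = 6, latent_per_fraction = 3000,
                    quota_frac = 0.5)
  tab <- simulate_composition(cfg, seed = 5)
  # every dataset x marker fraction honours the quota exactly
  expect_true(all(table(tab$dataset, tab$marker) == 1500))
  # per-group target-pos fraction ~ control-pos fraction (null)
  for (g in unique(tab$group)) {
    f_t <- mean(tab$group[tab$dataset == "target" &
                            tab$marker == "pos"] == g)
    f_c <- mean(tab$group[tab$dataset == "control" &
                            tab$marker == "pos"] == g)
    expect_lt(abs(f_t - f_c), 4 * sqrt(1 / 6 * 5 / 6 / 1500) * sqrt(2))
  }
})

test_that("a depleted group inflates the others' naive ratios (quota artifact)", {
  cfg <- sim_config(n_groups = 10, latent_per_fraction = 20000,
                    quota_frac = 0.5, or = c(0.1, rep(1, 9)))
  ratios <- vapply(1:20, function(s) {
    tab <- simulate_composition(cfg, seed = s)
    gr <- compute_ratios(tab, "target")
    mean(gr$ratios$ratio[gr$ratios$group != "group01"])
  }, numeric(1))
  # unaffected groups' pos/neg ratio sits near 10/9, not 1
  expect_gt(mean(ratios), 1.05)
  expect_lt(mean(ratios), 1.18)
})

test_that("generation is deterministic given a seed", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 600,
                    quota_frac = 0.5, n_genes = 15)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_experiment(cfg, dir1, seed = 9)
  simulate_experiment(cfg, dir2, seed = 9)
  for (f in c("cells.tsv", "counts.mtx", "fates.csv",
              file.path("truth", "genes.tsv")))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("counts follow the interaction model moments", {
  # near-Poisson limit: tiny dispersion makes variance track the mean
  cfg <- sim_config(n_groups = 1, latent_per_fraction = 6000,
                    quota_frac = 0.5, n_genes = 6,
                    phi_meanlog = log(1e-6), phi_sdlog = 0,
                    alpha_meanlog = log(20), alpha_sdlog = 0,
                    sigma_pool = 0, sf_sdlog = 0)
  tab <- simulate_composition(cfg, seed = 3)
  cm <- simulate_counts(cfg, tab, seed = 4)
  x <- as.matrix(cm$counts)
  ratio <- apply(x, 1, var) / rowMeans(x)
  expect_true(all(abs(ratio - 1) < 0.06))

  # b3 = 1 multiplies the target-pos mean by e
  cfg2 <- sim_config(n_groups = 1, latent_per_fraction = 12000,
                     quota_frac = 0.5, n_genes = 4, b3 = 1,
                     phi_meanlog = log(0.2), phi_sdlog = 0,
                     alpha_meanlog = log(20), alpha_sdlog = 0,
                     sigma_pool = 0, sf_sdlog = 0)
  tab2 <- simulate_composition(cfg2, seed = 5)
  cm2 <- simulate_counts(cfg2, tab2, seed = 6)
  x2 <- as.matrix(cm2$counts)
  tp <- tab2$dataset == "target" & tab2$marker == "pos"
  fold <- rowMeans(x2[, tp]) / rowMeans(x2[, !tp])
  expect_true(all(abs(fold - exp(1)) < 0.25))
})

test_that("fate sharpness controls concentration; infinite gives one-hot", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 300,
                    quota_frac = 0.5, fate_conc = Inf)
  tab <- simulate_composition(cfg, seed = 7)
  ft <- simulate_fates_and_time(cfg, tab, seed = 8)
  probs <- unclass(ft$fates)
  expect_true(all(probs %in% c(0, 1)))
  hard <- colnames(probs)[max.col(probs)]
  expect_equal(hard, tab$group)

  cfg$fate_conc <- 20
  soft <- unclass(simulate_fates_and_time(cfg, tab, seed = 8)$fates)
  expect_true(all(soft > 0 & soft < 1))
  expect_true(all(abs(rowSums(soft) - 1) < 1e-12))
  # mass still concentrates on the true lineage
  expect_gt(mean(soft[cbind(seq_len(nrow(soft)),
                            match(tab$group, colnames(soft)))]), 0.7)
})

test_that("the configured delay shifts only marker-positive target cells", {
  cfg <- sim_config(n_groups = 2, latent_per_fraction = 2000,
                    quota_frac = 0.5, delta = 0.5,
                    shifted_lineages = "group01")
  tab <- simulate_composition(cfg, seed = 9)
  ft <- simulate_fates_and_time(cfg, tab, seed = 10)
  cfg0 <- cfg; cfg0$delta <- 0
  ft0 <- simulate_fates_and_time(cfg0, tab, seed = 10)
  d <- ft$time - ft0$time[names(ft$time)]
  hit <- tab$dataset == "target" & tab$marker == "pos" &
    tab$group == "group01"
  expect_true(all(d[hit] < 0))
  expect_true(all(d[!hit] == 0))
  sd0 <- sd(ft0$time[tab$group == "group01"])
  expect_equal(unique(round(d[hit] / sd0, 10)), -0.5)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(or = c(0, 1)), class = "cosicc_config")
  expect_error(sim_config(quota_frac = 1.5), class = "cosicc_config")
})
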