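test_that("fate propagation: identity chain reproduces the terminal indicator", {
  ids1 <- c("s1", "s2", "s3", "s4")
  ids2 <- c("f1", "f2", "f3", "f4")
  tr <- diag(4)
  dimnames(tr) <- list(ids1, ids2)
  tg <- setNames(c("A", "A", "B", "B"), ids2)
  fates <- propagate_fates(list(transition_matrix(tr)), tg,
                           min_terminal = 1)
  expect_equal(unclass(fates)[ids1, "A"], setNames(c(1, 1, 0, 0), ids1))
  expect_equal(unclass(fates)[ids2, "B"], setNames(c(0, 0, 1, 1), ids2))
})

test_that("uniform transitions spread fates to terminal group frequencies", {
  t1 <- matrix(0.5, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  t2 <- matrix(0.5, 2, 2, dimnames = list(c("b1", "b2"), c("f1", "f2")))
  tg <- setNames(c("A", "B"), c("f1", "f2"))
  fates <- propagate_fates(list(transition_matrix(t1),
                                transition_matrix(t2)), tg,
                           min_terminal = 0)
  # every early cell ends in each terminal group with its frequency (1/2)
  expect_equal(unname(unclass(fates)["a1", ]), c(0.5, 0.5))
  expect_equal(unname(unclass(fates)["b2", ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(unclass(fates)) - 1) < 1e-8))
})

test_that("terminal retention is strict and chaining is checked", {
  n_final <- 201
  ids1 <- sprintf("s%03d", 1:10)
  idsf <- sprintf("f%03d", seq_len(n_final))
  tr <- matrix(1 / n_final, 10, n_final, dimnames = list(ids1, idsf))
  tg <- setNames(rep(c("A", "B"), c(100, 101)), idsf)
  # A has exactly 100 terminal cells: "more than 100" is strict -> dropped,
  # and the A-terminal cells (zero mass on B) are dropped with a warning
  expect_warning(
    fates <- propagate_fates(list(transition_matrix(tr)), tg,
                             min_terminal = 100),
    class = "cosicc_dropped_cells")
  expect_equal(colnames(fates), "B")
  expect_true(all(abs(rowSums(unclass(fates)) - 1) < 1e-12))

  t1 <- matrix(0.5, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  t2 <- matrix(0.5, 2, 2, dimnames = list(c("x1", "x2"), c("f1", "f2")))
  expect_error(propagate_fates(list(transition_matrix(t1),
                                    transition_matrix(t2)),
                               setNames(c("A", "B"), c("f1", "f2"))),
               class = "cosicc_chaining")
})

test_that("lineage sampling is categorical, deterministic under a seed", {
  f <- fate_matrix(matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE,
                          dimnames = list(c("c1", "c2"), c("L1", "L2"))))
  draws <- sample_lineages(f, seed = 5)
  expect_equal(unname(draws["c1"]), "L1")
  expect_identical(draws, sample_lineages(f, seed = 5))

  big <- fate_matrix(matrix(0.5, 10000, 2,
                            dimnames = list(sprintf("c%05d", 1:10000),
                                            c("L1", "L2"))))
  freq <- mean(sample_lineages(big, seed = 6) == "L1")
  expect_gt(freq, 0.48)   # binomial 99.9% interval at n = 1e4
  expect_lt(freq, 0.52)
})

test_that("one-hot fates make lineage DA equal group DA up to subsampling noise", {
  cfg <- sim_config(n_groups = 5, latent_per_fraction = 4000,
                    quota_frac = 0.5, or = c(0.2, rep(1, 4)),
                    fate_conc = Inf)
  tab <- simulate_composition(cfg, seed = 7)
  ft <- simulate_fates_and_time(cfg, tab, seed = 8)
  rl <- run_da_lineage(tab, ft$fates, seed = 9)
  rg <- run_da_group(tab, n_repeats = 100, seed = 10)
  m <- merge(rl, rg, by.x = "lineage", by.y = "group",
             suffixes = c("_lin", "_grp"))
  expect_equal(nrow(m), 5)
  expect_true(all(abs(log(m$odds_ratio_median_lin) -
                        log(m$odds_ratio_median_grp)) < 0.1))
  expect_identical(m$verdict_lin, m$verdict_grp)
})

test_that("a single fate draw reduces to one group-DA run on sampled labels", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 1800,
                    quota_frac = 0.5, fate_conc = 5)
  tab <- simulate_composition(cfg, seed = 17)
  ft <- simulate_fates_and_time(cfg, tab, seed = 18)
  rl <- run_da_lineage(tab, ft$fates, n_fate_draws = 1, n_subsample = 10,
                       seed = 4)
  labels <- sample_lineages(ft$fates, cosicc:::substream_seed(4, 10001L))
  tab2 <- tab
  tab2$group <- unname(labels[tab$cell_id])
  rg <- run_da_group(tab2, n_repeats = 10,
                     seed = cosicc:::substream_seed(4, 20001L))
  expect_equal(rl$odds_ratio_median,
               rg$odds_ratio_median[match(rl$lineage, rg$group)])
  expect_equal(rl$fdr_q, rg$fdr_q[match(rl$lineage, rg$group)])
})

test_that("cells without fate rows are dropped with a message", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 1200,
                    quota_frac = 0.5, fate_conc = Inf)
  tab <- simulate_composition(cfg, seed = 27)
  ft <- simulate_fates_and_time(cfg, tab, seed = 28)
  partial <- unclass(ft$fates)[-(1:10), , drop = FALSE]
  expect_message(run_da_lineage(tab, fate_matrix(partial), n_fate_draws = 1,
                                n_subsample = 2, seed = 1),
                 "10 cell")
})
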