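test_that("per-group ratios, undefined guards and medians", {
  tab <- make_cells(list(
    target = list(pos = c(A = 10, B = 20, C = 40, D = 5),
                  neg = c(A = 20, B = 20, C = 20, D = 0)),
    control = list(pos = c(A = 30, B = 30, C = 30, D = 30),
                   neg = c(A = 30, B = 30, C = 30, D = 30))))
  gr <- compute_ratios(tab, "target")
  r <- setNames(gr$ratios$ratio, gr$ratios$group)
  expect_equal(unname(r["A"]), 0.5)
  expect_false(gr$ratios$defined[gr$ratios$group == "D"])
  # median over defined ratios {0.5, 1, 2}
  expect_equal(gr$median, 1)
})

test_that("group retention threshold is >= min_control_pos", {
  tab <- make_cells(list(
    target = list(pos = c(A = 10, B = 10), neg = c(A = 10, B = 10)),
    control = list(pos = c(A = 29, B = 30), neg = c(A = 10, B = 10))))
  expect_equal(filter_groups(tab), "B")
  expect_setequal(filter_groups(tab, min_control_pos = 0), c("A", "B"))
})

test_that("bias-corrected subsample draws min(N_pos, N_neg/m) and n*m", {
  tab <- make_cells(list(
    target = list(pos = c(A = 200), neg = c(A = 50)),
    control = list(pos = c(A = 100), neg = c(A = 100))))
  st <- bias_corrected_subsample(tab, "target", m = 0.5, seed = 1)
  expect_equal(sum(st$marker == "pos"), 100)  # min(200, 50/0.5)
  expect_equal(sum(st$marker == "neg"), 50)

  sc <- bias_corrected_subsample(tab, "control", m = 1, seed = 1)
  expect_equal(sum(sc$marker == "pos"), 100)  # identity case
  expect_equal(sum(sc$marker == "neg"), 100)

  # determinism
  st2 <- bias_corrected_subsample(tab, "target", m = 0.5, seed = 1)
  expect_identical(st$cell_id, st2$cell_id)

  expect_error(bias_corrected_subsample(tab, "target", m = 1e6, seed = 1),
               class = "cosicc_degenerate_design")
})

test_that("Fisher 2x2 matches enumeration, fisher.test and the Haldane OR", {
  sym <- fisher_test_2x2(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  res <- fisher_test_2x2(8, 2, 1, 9)
  expect_equal(res$p_value, enum_fisher_p(8, 2, 1, 9), tolerance = 1e-13)

  ext <- fisher_test_2x2(0, 10, 10, 0)
  expect_equal(ext$odds_ratio, 0.25 / 110.25, tolerance = 1e-12)
  expect_lt(ext$p_value, 0.001)
  expect_equal(ext$p_value, enum_fisher_p(0, 10, 10, 0), tolerance = 1e-13)

  # random tables against both independent routes
  set.seed(11)
  for (i in 1:100) {
    t4 <- rpois(4, sample(3:40, 1))
    mine <- fisher_test_2x2(t4[1], t4[2], t4[3], t4[4])$p_value
    expect_equal(mine, enum_fisher_p(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-12)
    expect_equal(mine,
                 fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }

  expect_true(is.na(fisher_test_2x2(0, 0, 0, 0)$p_value))
})

test_that("one repeat equals a single subsample-and-test pass", {
  cfg <- sim_config(n_groups = 4, latent_per_fraction = 1600,
                    quota_frac = 0.5)
  tab <- simulate_composition(cfg, seed = 21)
  res <- run_da_group(tab, n_repeats = 1, seed = 7)

  retained <- filter_groups(tab)
  m_t <- compute_ratios(tab, "target", groups = retained)$median
  m_c <- compute_ratios(tab, "control", groups = retained)$median
  st <- bias_corrected_subsample(tab, "target", m_t,
                                 cosicc:::substream_seed(7, 2L))
  sc <- bias_corrected_subsample(tab, "control", m_c,
                                 cosicc:::substream_seed(7, 3L))
  for (g in retained) {
    manual <- fisher_group_test(st, sc, g)
    i <- which(res$group == g)
    expect_equal(res$odds_ratio_median[i], manual$odds_ratio)
    expect_equal(res$p_median[i], manual$p_value)
  }
})

test_that("results are invariant to joint relabeling of groups", {
  cfg <- sim_config(n_groups = 5, latent_per_fraction = 2500,
                    quota_frac = 0.5, or = c(0.3, rep(1, 4)))
  tab <- simulate_composition(cfg, seed = 31)
  res1 <- run_da_group(tab, n_repeats = 20, seed = 5)
  relabel <- setNames(paste0("x", 5:1), sort(unique(tab$group)))
  tab2 <- tab
  tab2$group <- unname(relabel[tab$group])
  res2 <- run_da_group(tab2, n_repeats = 20, seed = 5)
  res2$group <- names(relabel)[match(res2$group, relabel)]
  res2 <- res2[order(res2$group), ]
  expect_equal(res2$odds_ratio_median, res1$odds_ratio_median)
  expect_equal(res2$p_median, res1$p_median)
})

test_that("stage-resolved DA refines labels and applies the filter to composites", {
  so <- default_stage_order()
  df <- rbind(
    data.frame(cell_id = sprintf("a%03d", 1:200), dataset = "target",
               marker = rep(c("pos", "neg"), 100), group = "A",
               stage = "E7.50", pool_id = "p1"),
    data.frame(cell_id = sprintf("b%03d", 1:200), dataset = "control",
               marker = rep(c("pos", "neg"), 100), group = "A",
               stage = "E7.50", pool_id = "p2"),
    # group B is split across two stages; only one passes the filter
    data.frame(cell_id = sprintf("c%03d", 1:120), dataset = "control",
               marker = rep(c("pos", "neg"), 60), group = "B",
               stage = rep(c("E7.50", "E8.00"), c(80, 40)),
               pool_id = "p2"),
    data.frame(cell_id = sprintf("d%03d", 1:120), dataset = "target",
               marker = rep(c("pos", "neg"), 60), group = "B",
               stage = rep(c("E7.50", "E8.00"), c(80, 40)),
               pool_id = "p1"))
  tab <- cell_table(df, stage_order = so)
  res <- run_da_group_by_stage(tab, n_repeats = 5, seed = 3)
  expect_true(all(c("group", "stage") %in% names(res)))
  # B@E8.00 has 20 control-pos cells -> dropped although B overall has 60
  expect_false(any(res$group == "B" & res$stage == "E8.00"))
  expect_true(any(res$group == "B" & res$stage == "E7.50"))

  # a group present at a single stage matches the unstratified run
  res_flat <- run_da_group(tab, n_repeats = 5, seed = 3, groups = "A")
  ra <- res[res$group == "A", ]
  expect_equal(nrow(ra), 1)
})
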