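test_that("temporal-gene selection keeps stage genes, drops batch genes", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 600,
                    quota_frac = 0.5)
  ref <- simulate_reference(cfg, n_cells = 300, n_batches = 2, seed = 3)
  tg <- select_temporal_genes(ref$counts, ref$stages, ref$batches)
  retained <- attr(tg, "genes")
  kinds <- ref$gene_meta$kind[match(retained, ref$gene_meta$gene)]
  expect_true(all(kinds == "temporal"))
  expect_gt(length(retained), 0.8 * sum(ref$gene_meta$kind == "temporal"))
  # batch genes never pass
  bgenes <- ref$gene_meta$gene[ref$gene_meta$kind == "batch"]
  expect_false(any(bgenes %in% retained))
})

test_that("gene exclusion lists and degenerate designs are handled", {
  cfg <- sim_config(n_groups = 2, latent_per_fraction = 300,
                    quota_frac = 0.5)
  ref <- simulate_reference(cfg, n_cells = 200, seed = 5)
  drop1 <- ref$gene_meta$gene[1]
  tg <- select_temporal_genes(ref$counts, ref$stages, ref$batches,
                              exclude_genes = drop1)
  expect_false(drop1 %in% tg$gene)
  expect_error(select_temporal_genes(ref$counts,
                                     rep("E7.50", 200), ref$batches),
               class = "cosicc_design")
})

test_that("reference pseudotime tracks the latent time on a clean trajectory", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 600,
                    quota_frac = 0.5)
  ref <- simulate_reference(cfg, n_cells = 350, n_batches = 2, seed = 7)
  tg <- select_temporal_genes(ref$counts, ref$stages, ref$batches)
  rpt <- reference_pseudotime(ref$counts, tg, ref$stages)
  rho <- cor(rpt$pseudotime, ref$time[names(rpt$pseudotime)],
             method = "spearman")
  expect_gt(rho, 0.95)
  # alignment convention: correlation with stage rank is nonnegative
  expect_gte(rpt$correlation, 0)
  sr <- cosicc:::stage_rank(ref$stages)
  expect_gte(cor(rpt$pseudotime, sr, method = "spearman"), 0)
})

test_that("identical cells give a degenerate-kernel error", {
  counts <- matrix(5L, 10, 20,
                   dimnames = list(sprintf("g%d", 1:10),
                                   sprintf("c%d", 1:20)))
  cm <- count_matrix(counts)
  expect_error(cosicc:::diffusion_components(t(logcounts(cm))),
               class = "cosicc_numerical")
})

test_that("query mapping: self-match at k = 1 and direct oracle at k = 10", {
  cfg <- sim_config(n_groups = 3, latent_per_fraction = 600,
                    quota_frac = 0.5)
  ref <- simulate_reference(cfg, n_cells = 120, seed = 9)
  tg <- select_temporal_genes(ref$counts, ref$stages, ref$batches)
  rpt <- reference_pseudotime(ref$counts, tg, ref$stages)

  q <- subset_counts(ref$counts, cells = ref$counts$cells[1:5])
  pt1 <- map_query_pseudotime(q, ref$counts, tg, rpt, k = 1)
  expect_equal(unname(pt1), unname(rpt$pseudotime[1:5]))

  # oracle: recompute the top-10 mean by hand for one query cell
  genes <- attr(tg, "genes")
  xr <- apply(logcounts(subset_counts(ref$counts, genes = genes)), 2, rank)
  xq <- xr[, 1]
  cors <- apply(xr, 2, function(v) cor(xq, v))
  top10 <- order(-cors, seq_along(cors))[1:10]
  expected <- mean(rpt$pseudotime[top10])
  pt10 <- map_query_pseudotime(q, ref$counts, tg, rpt, k = 10)
  expect_equal(unname(pt10[1]), expected)

  # permuting gene order changes nothing
  qperm <- subset_counts(q, genes = rev(q$genes))
  ptp <- map_query_pseudotime(qperm, ref$counts, tg, rpt, k = 10)
  expect_equal(ptp, pt10)
})

test_that("skew-t density normalizes and the sampler matches it", {
  for (p in list(c(0, 1, 3, 5), c(2, 0.5, -2, 10))) {
    int <- integrate(function(x) dskewt(x, p[1], p[2], p[3], p[4]),
                     -Inf, Inf)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
  set.seed(2)
  x <- rskewt(20000, 1, 2, 4, 8)
  # compare empirical and analytic CDF at a few quantiles
  for (qq in c(0, 2, 5)) {
    pa <- integrate(function(z) dskewt(z, 1, 2, 4, 8), -Inf, qq)$value
    expect_equal(mean(x <= qq), pa, tolerance = 0.02)
  }
})

test_that("mixture fitting recovers well-separated components and BIC picks K", {
  set.seed(101)
  x <- c(rskewt(1300, 0, 1, 3, 5), rskewt(700, 5, 1, 3, 5))
  truth <- rep(1:2, c(1300, 700))
  fit <- select_skewt_mixture(x, seed = 11)
  expect_equal(fit$K, 2)
  top <- fit$cluster == fit$top_component
  agree <- max(mean(top == (truth == 2)), mean(top == (truth == 1)))
  expect_gt(agree, 0.95)
  expect_false(fit$downgraded)
})

test_that("lineage membership: preselection boundary and type filters", {
  # all fates exactly at 1/N_stage -> strict inequality empties preselection
  n <- 50
  f <- matrix(c(rep(1 / n, n), rep(1 - 1 / n, n)), n, 2,
              dimnames = list(sprintf("c%03d", 1:n), c("L", "other")))
  tab <- data.frame(cell_id = sprintf("c%03d", 1:n), group = "L",
                    stage = "E7.50")
  expect_error(
    suppressMessages(assign_cells_to_lineage(fate_matrix(f), tab, "L")),
    class = "cosicc_empty_design")

  # a cell type below 10% of members is removed at that stage
  set.seed(3)
  n2 <- 400
  p_hi <- plogis(rnorm(n2, 3, 0.5))     # clearly above 1/N
  f2 <- cbind(L = p_hi, other = 1 - p_hi)
  rownames(f2) <- sprintf("d%04d", 1:n2)
  grp <- rep(c("L", "rare"), c(370, 30))  # rare = 7.5% of cells
  tab2 <- data.frame(cell_id = rownames(f2), group = grp, stage = "E7.50")
  mem <- assign_cells_to_lineage(fate_matrix(f2), tab2, "L", seed = 5)
  mtypes <- grp[match(mem$members, rownames(f2))]
  expect_false("rare" %in% mtypes)
  expect_gt(length(mem$members), 0)
})

test_that("kinetics verdicts follow the CI rule", {
  set.seed(41)
  n <- 150
  mk_tab <- function() {
    ids <- sprintf("k%04d", 1:(4 * n))
    data.frame(cell_id = ids,
               dataset = rep(c("target", "control"), each = 2 * n),
               marker = rep(c("pos", "neg", "pos", "neg"), each = n),
               group = "L", stage = "E7.50",
               pool_id = rep(c("tp", "cp"), each = 2 * n))
  }
  tab <- cell_table(mk_tab())

  # exchangeable null: all four classes identically distributed
  pt0 <- setNames(rnorm(4 * n), tab$cell_id)
  r0 <- test_kinetics(pt0, tab, tab$cell_id)
  expect_equal(r0$verdict, "none")

  # strong delay of target-positive cells only
  shift <- ifelse(tab$dataset == "target" & tab$marker == "pos", -1, 0)
  pt1 <- setNames(rnorm(4 * n) + shift, tab$cell_id)
  r1 <- test_kinetics(pt1, tab, tab$cell_id)
  expect_equal(r1$verdict, "delayed")
  expect_lt(r1$ci_hi_target, r1$ci_lo_control)

  # acceleration is the mirror image
  pt2 <- setNames(rnorm(4 * n) - shift, tab$cell_id)
  expect_equal(test_kinetics(pt2, tab, tab$cell_id)$verdict, "accelerated")
})

test_that("kinetics refuses depleted or undersized trajectories", {
  ids <- sprintf("m%04d", 1:460)
  tab <- cell_table(data.frame(
    cell_id = ids,
    dataset = rep(c("target", "control"), c(160, 300)),
    marker = c(rep(c("pos", "neg"), c(5, 155)),
               rep(c("pos", "neg"), each = 150)),
    group = "L", stage = "E7.50",
    pool_id = rep(c("tp", "cp"), c(160, 300))))
  pt <- setNames(rnorm(460), ids)
  # ratio of ratios = (5/155)/(150/150) = 0.032 < 0.05
  r <- test_kinetics(pt, tab, ids)
  expect_equal(r$verdict, "none")
  expect_equal(r$reason, "depletion_filter")
  expect_lt(r$or_filter, 0.05)

  # passes the OR filter but a class is under min_cells
  r2 <- test_kinetics(pt, tab, ids, min_or = 0.01)
  expect_equal(r2$reason, "insufficient_cells")
})
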