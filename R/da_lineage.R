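#' Lineage-trajectory differential abundance
#'
#' Extends [run_da_group()] from observed cell types to lineage trajectories.
#' Because trajectory membership is probabilistic (a fate matrix row per
#' cell), a hard lineage label is sampled per cell from its fate
#' distribution; the bias-corrected group DA is run on the sampled labels
#' (with `n_subsample` subsampling repeats and FDR across lineages within the
#' draw); the whole procedure is repeated for `n_fate_draws` independent fate
#' samplings and per-lineage medians of the odds ratios and of the
#' FDR-corrected p-values across draws are reported.
#'
#' @param table A [cell_table()] of chimera cells.
#' @param fates A [fate_matrix()] covering the chimera cells; cells without a
#'   fate row are dropped (their number is reported via a message).
#' @param n_fate_draws Number of independent lineage samplings.
#' @param n_subsample Bias-correction subsample repeats per draw.
#' @param min_control_pos Retention threshold on control marker-positive
#'   cells per lineage.
#' @param fdr_threshold FDR level for the verdict call.
#' @param seed Integer seed.
#' @return A `cosicc_da` data.frame keyed by `lineage`: median (across
#'   draws) of per-draw median odds ratios (`odds_ratio_median`), of per-draw
#'   median p-values (`p_median`) and of per-draw FDR q-values (`fdr_q`);
#'   pre-subsampling counts are medians across draws; `n_fate_draws` gives
#'   the number of draws in which the lineage was retained.
#' @export
run_da_lineage <- function(table, fates, n_fate_draws = 10, n_subsample = 30,
                           min_control_pos = 30, fdr_threshold = 0.1,
                           seed = 1) {
  have <- table$cell_id %in% rownames(fates)
  if (!all(have)) {
    message(sum(!have), " cell(s) without fate rows dropped")
    table <- table[have, , drop = FALSE]
  }
  if (nrow(table) == 0)
    stop_cosicc("no cells with fate information", "empty_design")

  per_draw <- vector("list", n_fate_draws)
  for (d in seq_len(n_fate_draws)) {
    labels <- sample_lineages(fates, substream_seed(seed, 10000L + d))
    tab_d <- table
    tab_d$group <- unname(labels[table$cell_id])
    res <- run_da_group(tab_d, n_repeats = n_subsample,
                        min_control_pos = min_control_pos,
                        fdr_threshold = fdr_threshold,
                        seed = substream_seed(seed, 20000L + d))
    res$draw <- d
    per_draw[[d]] <- as.data.frame(res)
  }
  all_draws <- do.call(rbind, per_draw)
  lineages <- sort(unique(all_draws$group))

  med_by <- function(col) vapply(lineages, function(l)
    median(all_draws[[col]][all_draws$group == l]), numeric(1))
  out <- data.frame(
    lineage = lineages,
    n_target_pos = med_by("n_target_pos"),
    n_target_neg = med_by("n_target_neg"),
    n_control_pos = med_by("n_control_pos"),
    n_control_neg = med_by("n_control_neg"),
    odds_ratio_median = med_by("odds_ratio_median"),
    p_median = med_by("p_median"),
    fdr_q = med_by("fdr_q"),
    n_fate_draws = vapply(lineages, function(l)
      sum(all_draws$group == l), integer(1)),
    row.names = NULL)
  out$verdict <- "ns"
  out$verdict[out$fdr_q < fdr_threshold & out$odds_ratio_median < 1] <-
    "depleted"
  out$verdict[out$fdr_q < fdr_threshold & out$odds_ratio_median > 1] <-
    "enriched"
  class(out) <- c("cosicc_da", "data.frame")
  out
}
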