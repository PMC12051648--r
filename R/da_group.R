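#' Per-group marker ratios and their median
#'
#' For one dataset, computes per group the ratio `r_c` = (marker-positive
#' cells in group c) / (marker-negative cells in group c) and the median `m`
#' of the defined ratios across groups. `m` is the pivot of the sampling-bias
#' correction: under the assumption that most groups are unaffected by the
#' knockout, `m` estimates the pos/neg ratio imposed by the fixed sorting
#' quota rather than by biology.
#'
#' @param table A [cell_table()].
#' @param dataset `"target"` or `"control"`.
#' @param groups Optional group subset over which to compute (and take the
#'   median); defaults to all groups present in the dataset.
#' @return A `cosicc_group_ratios` list: `dataset`, `ratios` data.frame
#'   (group, n_pos, n_neg, ratio, defined) and `median` over defined ratios.
#'   Groups with zero marker-negative count are flagged undefined and
#'   excluded from the median (but not from downstream testing).
#' @export
compute_ratios <- function(table, dataset = c("target", "control"),
                           groups = NULL) {
  dataset <- match.arg(dataset)
  sub <- table[table$dataset == dataset, , drop = FALSE]
  groups <- groups %||% sort(unique(sub$group))
  n_pos <- vapply(groups, function(g)
    sum(sub$group == g & sub$marker == "pos"), integer(1))
  n_neg <- vapply(groups, function(g)
    sum(sub$group == g & sub$marker == "neg"), integer(1))
  defined <- n_neg > 0
  ratio <- ifelse(defined, n_pos / n_neg, NA_real_)
  if (!any(defined))
    stop_cosicc("no group has a defined pos/neg ratio in this dataset",
                "empty_design")
  structure(list(dataset = dataset,
                 ratios = data.frame(group = groups, n_pos = n_pos,
                                     n_neg = n_neg, ratio = ratio,
                                     defined = defined, row.names = NULL),
                 median = median(ratio[defined])),
            class = "cosicc_group_ratios")
}

#' Groups retained for DA testing
#'
#' Keeps groups with at least `min_control_pos` marker-positive cells in the
#' control (wild-type chimera) dataset; smaller groups carry too little
#' information in the external control to anchor the contrast.
#'
#' @param table A [cell_table()].
#' @param min_control_pos Minimum control marker-positive count (kept iff
#'   `>=` this value).
#' @return Character vector of retained group labels.
#' @export
filter_groups <- function(table, min_control_pos = 30) {
  ctrl_pos <- table[table$dataset == "control" & table$marker == "pos", ,
                    drop = FALSE]
  groups <- sort(unique(table$group))
  counts <- vapply(groups, function(g) sum(ctrl_pos$group == g), integer(1))
  groups[counts >= min_control_pos]
}

#' Bias-corrected subsample of one dataset
#'
#' Draws, without replacement and pooled across groups,
#' `n = min(N_pos, N_neg / m)` marker-positive cells and `round(n * m)`
#' marker-negative cells, where `N_pos`/`N_neg` are the dataset's fraction
#' totals and `m` is the median per-group pos/neg ratio from
#' [compute_ratios()]. This undoes the fixed-quota sorting artifact: after
#' subsampling, an unaffected group's expected pos/neg ratio matches the
#' dataset-wide median ratio instead of being inflated by depletion
#' elsewhere. Rounding is to the nearest integer, ties to even.
#'
#' @param table A [cell_table()].
#' @param dataset `"target"` or `"control"`.
#' @param m Positive median ratio for this dataset.
#' @param seed Integer seed.
#' @return A [cell_table()] containing the sampled cells.
#' @export
bias_corrected_subsample <- function(table, dataset = c("target", "control"),
                                     m, seed) {
  dataset <- match.arg(dataset)
  if (!is.finite(m) || m <= 0)
    stop_cosicc("median ratio m must be positive", "validation")
  sub <- table[table$dataset == dataset, , drop = FALSE]
  take <- subsample_indices(which(sub$marker == "pos"),
                            which(sub$marker == "neg"), m, seed)
  sub[sort(c(take$pos, take$neg)), , drop = FALSE]
}

# Core of the bias correction: draw n = min(N_pos, N_neg/m) positives and
# round(n m) negatives (ties to even) without replacement.
#' @noRd
subsample_indices <- function(pos_idx, neg_idx, m, seed) {
  n <- floor(min(length(pos_idx), length(neg_idx) / m) + 1e-9)
  if (n < 1)
    stop_cosicc("degenerate design: no cells left after bias correction",
                "degenerate_design")
  n_neg <- min(round(n * m), length(neg_idx))
  with_seed(seed, {
    list(pos = pos_idx[sample.int(length(pos_idx), n)],
         neg = neg_idx[sample.int(length(neg_idx), n_neg)])
  })
}

#' Group-level differential abundance with sampling-bias correction
#'
#' For every retained group, tests whether marker-positive cells are depleted
#' or enriched in the target (knockout) chimeras relative to the external
#' wild-type control. Both datasets are first subsampled to undo the
#' fixed-quota sorting bias ([bias_corrected_subsample()] with each dataset's
#' own median ratio); a Fisher exact test of marker x dataset is then applied
#' per group. Subsampling and testing are repeated `n_repeats` times and the
#' per-group median odds ratio and median p-value are carried forward;
#' Benjamini-Hochberg FDR is applied across groups to the median p-values.
#'
#' @param table A [cell_table()].
#' @param n_repeats Number of independent subsample/test repeats.
#' @param min_control_pos Group retention threshold, see [filter_groups()].
#' @param fdr_threshold FDR level for the verdict call.
#' @param seed Integer seed; repeat r uses a substream derived from
#'   `(seed, r)`.
#' @param correct_bias If `FALSE`, skip the subsampling correction and run a
#'   single Fisher test per group on the raw counts (the naive procedure;
#'   useful to see the artifact the correction removes).
#' @param groups Optional explicit group set (still filtered).
#' @return A `cosicc_da` data.frame with columns `group`, `n_target_pos`,
#'   `n_target_neg`, `n_control_pos`, `n_control_neg` (pre-subsampling
#'   counts), `odds_ratio_median`, `p_median`, `fdr_q`, `verdict`
#'   (`depleted` / `enriched` / `ns`).
#' @export
run_da_group <- function(table, n_repeats = 100, min_control_pos = 30,
                         fdr_threshold = 0.1, seed = 1, correct_bias = TRUE,
                         groups = NULL) {
  for (ds in c("target", "control")) {
    sub <- table[table$dataset == ds, , drop = FALSE]
    if (nrow(sub) == 0 || length(unique(sub$marker)) < 2)
      stop_cosicc(paste0("dataset '", ds,
                         "' must contain both marker classes"),
                  "empty_design")
  }
  retained <- filter_groups(table, min_control_pos)
  if (!is.null(groups)) retained <- intersect(retained, groups)
  if (length(retained) == 0)
    stop_cosicc("no group passes the control marker-positive filter",
                "empty_design")

  counts <- da_group_counts(table, retained)

  if (!correct_bias) {
    or <- p <- numeric(length(retained))
    for (i in seq_along(retained)) {
      res <- fisher_test_2x2(counts$n_target_pos[i], counts$n_control_pos[i],
                             counts$n_target_neg[i], counts$n_control_neg[i])
      or[i] <- res$odds_ratio
      p[i] <- res$p_value
    }
    return(finish_da(counts, or, p, fdr_threshold))
  }

  m_target <- compute_ratios(table, "target", groups = retained)$median
  m_control <- compute_ratios(table, "control", groups = retained)$median

  # index-based fast path; draws match bias_corrected_subsample exactly
  G <- length(retained)
  gi <- list(); pos <- list(); neg <- list()
  for (ds in c("target", "control")) {
    in_ds <- table$dataset == ds
    gi[[ds]] <- match(table$group[in_ds], retained)
    mk <- table$marker[in_ds]
    pos[[ds]] <- which(mk == "pos")
    neg[[ds]] <- which(mk == "neg")
  }
  or_mat <- p_mat <- matrix(NA_real_, G, n_repeats)
  for (r in seq_len(n_repeats)) {
    tt <- subsample_indices(pos$target, neg$target, m_target,
                            substream_seed(seed, 2L * r))
    tc <- subsample_indices(pos$control, neg$control, m_control,
                            substream_seed(seed, 2L * r + 1L))
    tp <- tabulate(gi$target[tt$pos], G)
    tn <- tabulate(gi$target[tt$neg], G)
    cp <- tabulate(gi$control[tc$pos], G)
    cn <- tabulate(gi$control[tc$neg], G)
    for (i in seq_len(G)) {
      res <- fisher_test_2x2(tp[i], cp[i], tn[i], cn[i])
      or_mat[i, r] <- res$odds_ratio
      p_mat[i, r] <- res$p_value
    }
  }
  finish_da(counts,
            apply(or_mat, 1, median, na.rm = TRUE),
            apply(p_mat, 1, median, na.rm = TRUE),
            fdr_threshold)
}

#' @noRd
da_group_counts <- function(table, groups) {
  cnt <- function(ds, mk) vapply(groups, function(g)
    sum(table$dataset == ds & table$marker == mk & table$group == g),
    integer(1))
  data.frame(group = groups,
             n_target_pos = cnt("target", "pos"),
             n_target_neg = cnt("target", "neg"),
             n_control_pos = cnt("control", "pos"),
             n_control_neg = cnt("control", "neg"),
             row.names = NULL)
}

#' @noRd
finish_da <- function(counts, or, p, fdr_threshold) {
  q <- bh_adjust(p)
  verdict <- rep("ns", length(or))
  verdict[!is.na(q) & q < fdr_threshold & or < 1] <- "depleted"
  verdict[!is.na(q) & q < fdr_threshold & or > 1] <- "enriched"
  out <- counts
  out$odds_ratio_median <- or
  out$p_median <- p
  out$fdr_q <- q
  out$verdict <- verdict
  class(out) <- c("cosicc_da", "data.frame")
  out
}

#' Differential abundance per (group, stage) combination
#'
#' Identical to [run_da_group()] with composite `(group, stage)` labels
#' replacing groups, resolving time-dependent abundance changes; composite
#' labels below the control-positive threshold are dropped even when their
#' parent group passes.
#'
#' @inheritParams run_da_group
#' @return A `cosicc_da` data.frame keyed by `group` and `stage`.
#' @export
run_da_group_by_stage <- function(table, n_repeats = 100,
                                  min_control_pos = 30, fdr_threshold = 0.1,
                                  seed = 1, correct_bias = TRUE) {
  sep <- "\r"  # not expected inside labels
  tab2 <- table
  tab2$group <- paste(table$group, as.character(table$stage), sep = sep)
  res <- run_da_group(tab2, n_repeats = n_repeats,
                      min_control_pos = min_control_pos,
                      fdr_threshold = fdr_threshold, seed = seed,
                      correct_bias = correct_bias)
  parts <- strsplit(res$group, sep, fixed = TRUE)
  res$stage <- vapply(parts, `[`, character(1), 2)
  res$group <- vapply(parts, `[`, character(1), 1)
  res <- res[, c("group", "stage",
                 setdiff(names(res), c("group", "stage"))), drop = FALSE]
  class(res) <- c("cosicc_da", "data.frame")
  res
}

#' Write DA results as TSV (stable column order)
#' @param res A `cosicc_da` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_da_results <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
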