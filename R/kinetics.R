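#' Assign cells to a lineage trajectory via skew-t mixture modelling
#'
#' Works stage by stage. At each stage, cells whose fate probability for the
#' lineage exceeds the uniform-random level `1/N_stage` (strictly; `N_stage`
#' = total cells at that stage) are preselected; a skew-t mixture with 2 or 3
#' components (chosen by BIC) is fitted to their log10 fate probabilities,
#' and the cells assigned (by maximum posterior) to the component with the
#' largest location are the stage's members. Two cleanup filters follow:
#' within each stage, cell types making up less than `min_type_frac` of the
#' members are removed; and from the first stage at which the lineage's
#' final cell type is the most frequent member type onward, all other cell
#' types are excluded.
#'
#' @param fates A [fate_matrix()] with a column for `lineage`.
#' @param table A [cell_table()] (or any data.frame with `cell_id`, `group`,
#'   `stage`) covering the fate-matrix cells; supplies stage and cell-type
#'   labels.
#' @param lineage Lineage (fate column) to assign.
#' @param final_group The terminal cell type of the lineage; defaults to the
#'   lineage name itself.
#' @param min_type_frac Per-stage minimum cell-type share among members.
#' @param min_stage_cells Stages with fewer preselected cells are skipped.
#' @param start_stage Optional first stage of the trajectory; earlier
#'   stages are ignored. All stages are used when `NULL`.
#' @param mixture_scale Fit the mixture on `"log10"` fate probabilities
#'   (default) or on the `"raw"` probabilities.
#' @param n_restarts,seed Passed to [select_skewt_mixture()].
#' @return A `cosicc_membership` list: `lineage`, `members` (cell ids),
#'   `per_stage` data.frame (stage, n_stage, threshold, n_preselected, K,
#'   bic, downgraded, n_members), `skipped_stages`.
#' @export
assign_cells_to_lineage <- function(fates, table, lineage,
                                    final_group = lineage,
                                    min_type_frac = 0.10,
                                    min_stage_cells = 20,
                                    start_stage = NULL,
                                    mixture_scale = c("log10", "raw"),
                                    n_restarts = 10, seed = 1) {
  mixture_scale <- match.arg(mixture_scale)
  if (!(lineage %in% colnames(fates)))
    stop_cosicc(paste0("no fate column for lineage '", lineage, "'"),
                "schema")
  tab <- as.data.frame(table)
  tab <- tab[tab$cell_id %in% rownames(fates), , drop = FALSE]
  if (!is.null(start_stage)) {
    lv <- if (is.factor(tab$stage)) levels(tab$stage) else
      sort(unique(as.character(tab$stage)))
    if (!(start_stage %in% lv))
      stop_cosicc(paste0("start_stage '", start_stage,
                         "' not among the table's stages"), "validation")
    keep <- match(as.character(tab$stage), lv) >= match(start_stage, lv)
    tab <- tab[keep, , drop = FALSE]
  }
  tab$stage <- droplevels(as.factor(tab$stage))
  stages <- levels(tab$stage)

  members <- character(0)
  rows <- list()
  skipped <- character(0)
  stage_members <- list()
  for (si in seq_along(stages)) {
    s <- stages[si]
    cells_s <- tab$cell_id[tab$stage == s]
    n_stage <- length(cells_s)
    thr <- 1 / n_stage
    p <- unclass(fates)[cells_s, lineage]
    pre <- cells_s[p > thr]
    if (length(pre) < min_stage_cells) {
      skipped <- c(skipped, s)
      message("stage ", s, " skipped: ", length(pre),
              " preselected cell(s)")
      next
    }
    x <- unclass(fates)[pre, lineage]
    if (mixture_scale == "log10") x <- log10(x)
    fit <- select_skewt_mixture(x, n_restarts = n_restarts,
                                seed = substream_seed(seed, si))
    mem_s <- pre[fit$cluster == fit$top_component]

    # per-stage cell-type share filter
    types <- tab$group[match(mem_s, tab$cell_id)]
    keep_types <- names(which(table(types) / length(types) >= min_type_frac))
    mem_s <- mem_s[types %in% keep_types]

    stage_members[[s]] <- mem_s
    rows[[s]] <- data.frame(stage = s, n_stage = n_stage, threshold = thr,
                            n_preselected = length(pre), K = fit$K %||% 2,
                            bic = fit$bic, downgraded = fit$downgraded,
                            n_members = length(mem_s), row.names = NULL)
  }
  if (length(stage_members) == 0)
    stop_cosicc("no stage yielded lineage members", "empty_design")

  # final-type dominance: from the first stage where the terminal type is
  # the modal member type onward, keep only the terminal type
  used_stages <- names(stage_members)
  dominant_from <- NA_integer_
  for (si in seq_along(used_stages)) {
    types <- tab$group[match(stage_members[[si]], tab$cell_id)]
    tt <- table(types)
    if (length(tt) > 0 && names(which.max(tt))[1] == final_group) {
      dominant_from <- si
      break
    }
  }
  if (!is.na(dominant_from)) {
    for (si in seq(dominant_from, length(used_stages))) {
      types <- tab$group[match(stage_members[[si]], tab$cell_id)]
      stage_members[[si]] <- stage_members[[si]][types == final_group]
    }
  }
  members <- unlist(stage_members, use.names = FALSE)
  per_stage <- do.call(rbind, rows)
  per_stage$n_members <- vapply(stage_members, length,
                                integer(1))[per_stage$stage]
  structure(list(lineage = lineage, members = members,
                 per_stage = per_stage, skipped_stages = skipped),
            class = "cosicc_membership")
}

#' Test for developmental delay or acceleration along a trajectory
#'
#' Within each dataset, the pseudotimes of marker-positive member cells are
#' compared to marker-negative ones by a Wilcoxon rank-sum test with a
#' Hodges-Lehmann location-shift estimate and confidence interval (exact
#' when both classes have fewer than 50 cells and no ties, normal
#' approximation with continuity correction otherwise). The verdict is
#' `delayed` or `accelerated` only when the target CI excludes 0 *and* is
#' disjoint from the control CI (closed intervals: touching endpoints count
#' as overlap); a negative shift of positive vs negative cells means the
#' knockout cells sit earlier in pseudotime, i.e. are delayed.
#'
#' Trajectories severely depleted of knockout cells cannot be assessed: the
#' test is only run when the ratio-of-ratios odds ratio
#' `(target pos/neg) / (control pos/neg)` over member cells exceeds
#' `min_or`, and every dataset x marker class must have at least
#' `min_cells` members.
#'
#' @param pt Named numeric vector of per-cell pseudotimes (target and
#'   control chimera cells).
#' @param table A [cell_table()].
#' @param membership A [assign_cells_to_lineage()] result, or a character
#'   vector of member cell ids.
#' @param min_or Depletion filter on the ratio-of-ratios odds ratio.
#' @param conf Confidence level.
#' @param min_cells Minimum members per (dataset x marker) class.
#' @return A `cosicc_kinetics` one-row data.frame: `lineage`, class sizes,
#'   `shift_target`, `ci_lo_target`, `ci_hi_target`, `shift_control`,
#'   `ci_lo_control`, `ci_hi_control`, `or_filter`, `verdict`
#'   (`delayed`/`accelerated`/`none`), `reason`.
#' @export
test_kinetics <- function(pt, table, membership, min_or = 0.05,
                          conf = 0.95, min_cells = 10) {
  lineage <- if (inherits(membership, "cosicc_membership"))
    membership$lineage else NA_character_
  members <- if (inherits(membership, "cosicc_membership"))
    membership$members else as.character(membership)
  tab <- as.data.frame(table)
  tab <- tab[tab$cell_id %in% members, , drop = FALSE]
  tab$pt <- pt[tab$cell_id]
  tab <- tab[!is.na(tab$pt), , drop = FALSE]

  n_of <- function(ds, mk) sum(tab$dataset == ds & tab$marker == mk)
  ns <- c(n_target_pos = n_of("target", "pos"),
          n_target_neg = n_of("target", "neg"),
          n_control_pos = n_of("control", "pos"),
          n_control_neg = n_of("control", "neg"))
  or_filter <- (ns[["n_target_pos"]] / ns[["n_target_neg"]]) /
    (ns[["n_control_pos"]] / ns[["n_control_neg"]])

  empty <- kinetics_row(lineage, ns, or_filter)
  if (!is.finite(or_filter) || or_filter <= min_or) {
    empty$reason <- "depletion_filter"
    return(empty)
  }
  if (any(ns < min_cells)) {
    empty$reason <- "insufficient_cells"
    return(empty)
  }

  shift_ci <- function(ds) {
    w <- wilcox.test(tab$pt[tab$dataset == ds & tab$marker == "pos"],
                     tab$pt[tab$dataset == ds & tab$marker == "neg"],
                     conf.int = TRUE, conf.level = conf)
    c(est = unname(w$estimate), lo = w$conf.int[1], hi = w$conf.int[2])
  }
  st <- suppressWarnings(shift_ci("target"))
  sc <- suppressWarnings(shift_ci("control"))

  verdict <- "none"
  if (st[["hi"]] < 0 && st[["hi"]] < sc[["lo"]]) verdict <- "delayed"
  if (st[["lo"]] > 0 && st[["lo"]] > sc[["hi"]]) verdict <- "accelerated"

  out <- empty
  out$shift_target <- st[["est"]]
  out$ci_lo_target <- st[["lo"]]
  out$ci_hi_target <- st[["hi"]]
  out$shift_control <- sc[["est"]]
  out$ci_lo_control <- sc[["lo"]]
  out$ci_hi_control <- sc[["hi"]]
  out$verdict <- verdict
  out$reason <- "tested"
  out
}

#' @noRd
kinetics_row <- function(lineage, ns, or_filter) {
  out <- data.frame(lineage = lineage,
                    n_target_pos = ns[["n_target_pos"]],
                    n_target_neg = ns[["n_target_neg"]],
                    n_control_pos = ns[["n_control_pos"]],
                    n_control_neg = ns[["n_control_neg"]],
                    shift_target = NA_real_, ci_lo_target = NA_real_,
                    ci_hi_target = NA_real_, shift_control = NA_real_,
                    ci_lo_control = NA_real_, ci_hi_control = NA_real_,
                    or_filter = or_filter, verdict = "none",
                    reason = NA_character_, row.names = NULL)
  class(out) <- c("cosicc_kinetics", "data.frame")
  out
}
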