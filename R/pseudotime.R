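#' Select temporal genes in the reference atlas
#'
#' A gene is temporal when its log-normalized expression is associated with
#' embryonic stage (one-way ANOVA across stages, Benjamini-Hochberg FDR
#' `q < q_time`) and the residuals of that stage fit are *not* associated
#' with batch (residual ANOVA on batch, genes with `q < q_batch` dropped).
#' The second filter removes genes whose apparent temporal signal differs
#' between batches, which would otherwise leak batch structure into
#' pseudotime.
#'
#' @param ref_counts Reference [count_matrix()].
#' @param stages Per-reference-cell stage labels (factor or character).
#' @param batches Per-reference-cell batch labels.
#' @param q_time FDR threshold for the stage association.
#' @param q_batch FDR threshold above which a gene's residual batch
#'   association is tolerated.
#' @param exclude_genes Optional gene ids removed up front (e.g. sex-linked
#'   genes).
#' @return A `cosicc_temporal_genes` data.frame: `gene`, `f_time`, `q_time`,
#'   `f_batch`, `q_batch`, `batch_flag`, `retained`. The retained gene ids
#'   are in `attr(, "genes")`.
#' @export
select_temporal_genes <- function(ref_counts, stages, batches,
                                  q_time = 0.05, q_batch = 0.05,
                                  exclude_genes = NULL) {
  stages <- droplevels(as.factor(stages))
  batches <- droplevels(as.factor(batches))
  if (nlevels(stages) < 2)
    stop_cosicc("need at least two stages to select temporal genes",
                "design")
  if (nlevels(batches) < 2)
    stop_cosicc("need at least two batches for the batch-residual filter",
                "design")
  x <- logcounts(ref_counts)
  if (!is.null(exclude_genes))
    x <- x[!(rownames(x) %in% exclude_genes), , drop = FALSE]

  at <- row_anova(x, stages)
  qt <- bh_adjust(at$p)

  # residuals from the stage model
  res <- x - at$group_means[, as.integer(stages), drop = FALSE]
  ab <- row_anova(res, batches)
  qb <- bh_adjust(ab$p)

  out <- data.frame(gene = rownames(x), f_time = at$f, q_time = qt,
                    f_batch = ab$f, q_batch = qb,
                    batch_flag = qb < q_batch,
                    retained = qt < q_time & !(qb < q_batch),
                    row.names = NULL)
  if (!any(out$retained))
    warn_cosicc("no temporal genes retained; downstream pseudotime will refuse to run",
                "empty_set")
  structure(out, genes = out$gene[out$retained],
            class = c("cosicc_temporal_genes", "data.frame"))
}

# Density-normalized Gaussian-kernel diffusion map. Returns the nontrivial
# diffusion components (columns), ordered by eigenvalue.
#' @noRd
diffusion_components <- function(x, n_components = 10) {
  n <- nrow(x)
  if (n < 3) stop_cosicc("need at least three cells for a diffusion map",
                         "design")
  d <- as.matrix(dist(x))
  sigma <- median(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0)
    stop_cosicc(paste0("degenerate kernel: cells are identical; ",
                       "check gene selection and normalization"),
                "numerical")
  k <- exp(-d^2 / (2 * sigma^2))
  diag(k) <- 0
  # anticipate density variation (alpha = 1 normalization)
  q <- rowSums(k)
  k <- k / outer(q, q)
  dd <- rowSums(k)
  s <- k / sqrt(outer(dd, dd))
  eig <- eigen(s, symmetric = TRUE)
  n_keep <- min(n_components, n - 2)
  phi <- eig$vectors[, 2:(n_keep + 1), drop = FALSE] / sqrt(dd)
  list(components = phi, eigenvalues = eig$values[2:(n_keep + 1)])
}

#' Reference pseudotime from a diffusion map
#'
#' Computes a diffusion map of the reference cells over the temporal genes
#' and takes as pseudotime the diffusion component whose Spearman
#' correlation with stage rank is largest in magnitude, sign-flipped so the
#' correlation is positive (later stages get larger pseudotime).
#'
#' @param ref_counts Reference [count_matrix()].
#' @param temporal_genes Character vector of gene ids (or the object from
#'   [select_temporal_genes()]).
#' @param stages Per-reference-cell stage labels, ordered factor or
#'   character interpretable through `stage_order`.
#' @param n_components Number of diffusion components to compute before
#'   picking.
#' @param stage_order Optional explicit stage order (defaults to factor
#'   levels or sorted unique labels).
#' @param method Correlation used to pick the component: `"spearman"`
#'   (default, rank-robust) or `"pearson"`.
#' @return A `cosicc_pseudotime` list: `pseudotime` (named per cell),
#'   `component` (chosen index), `sign`, `correlation` (Spearman with stage
#'   rank after alignment), `components` (all computed components).
#' @export
reference_pseudotime <- function(ref_counts, temporal_genes, stages,
                                 n_components = 10, stage_order = NULL,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- if (inherits(temporal_genes, "cosicc_temporal_genes"))
    attr(temporal_genes, "genes") else as.character(temporal_genes)
  if (length(genes) == 0)
    stop_cosicc("empty temporal gene set", "empty_set")
  cm <- subset_counts(ref_counts, genes = intersect(genes, ref_counts$genes))
  if (length(cm$genes) == 0)
    stop_cosicc("no temporal genes present in the reference matrix",
                "empty_set")
  x <- Matrix::t(logcounts(cm, dense = FALSE))
  x <- as.matrix(x)
  dc <- diffusion_components(x, n_components)

  rank_of <- stage_rank(stages, stage_order)
  cors <- apply(dc$components, 2, function(v)
    suppressWarnings(cor(v, rank_of, method = method)))
  cors[is.na(cors)] <- 0
  j <- which.max(abs(cors))
  sgn <- if (cors[j] < 0) -1 else 1
  pt_ <- sgn * dc$components[, j]
  names(pt_) <- cm$cells
  structure(list(pseudotime = pt_, component = j, sign = sgn,
                 correlation = abs(cors[j]), components = dc$components,
                 eigenvalues = dc$eigenvalues),
            class = "cosicc_pseudotime")
}

#' @noRd
stage_rank <- function(stages, stage_order = NULL) {
  if (is.factor(stages) && is.null(stage_order))
    return(as.integer(stages))
  stage_order <- stage_order %||% sort(unique(as.character(stages)))
  r <- match(as.character(stages), stage_order)
  if (anyNA(r)) stop_cosicc("stage label outside the declared order",
                            "validation")
  r
}

#' Map chimera (query) cells onto reference pseudotime
#'
#' Each query cell receives the unweighted mean pseudotime of the `k`
#' reference cells to which it is most correlated (Spearman over the
#' temporal genes; rank-robust, so differences in normalization between
#' experiments do not matter). Ties at rank `k` are broken by smallest
#' reference-cell index.
#'
#' @param query_counts,ref_counts [count_matrix()] objects sharing the
#'   temporal genes.
#' @param temporal_genes Gene ids (or [select_temporal_genes()] output).
#' @param ref_pt A [reference_pseudotime()] object (or named numeric vector
#'   of reference pseudotimes).
#' @param k Number of reference neighbours to average.
#' @param method Correlation flavour; `"spearman"` (default) or
#'   `"pearson"`.
#' @return Named numeric vector of query pseudotimes; query cells with zero
#'   variance over the temporal genes get `NA` (their count is messaged).
#' @export
map_query_pseudotime <- function(query_counts, ref_counts, temporal_genes,
                                 ref_pt, k = 10,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- if (inherits(temporal_genes, "cosicc_temporal_genes"))
    attr(temporal_genes, "genes") else as.character(temporal_genes)
  genes <- Reduce(intersect, list(genes, query_counts$genes,
                                  ref_counts$genes))
  if (length(genes) < 2)
    stop_cosicc("fewer than two shared temporal genes", "empty_set")
  pt_ref <- if (inherits(ref_pt, "cosicc_pseudotime"))
    ref_pt$pseudotime else ref_pt
  if (k > length(pt_ref))
    stop_cosicc("k exceeds the number of reference cells", "validation")

  xq <- logcounts(subset_counts(query_counts, genes = genes))
  xr <- logcounts(subset_counts(ref_counts, genes = genes))
  xr <- xr[, names(pt_ref), drop = FALSE]
  if (method == "spearman") {
    xq <- apply(xq, 2, rank)
    xr <- apply(xr, 2, rank)
  }
  sdq <- apply(xq, 2, sd)
  sdr <- apply(xr, 2, sd)
  if (any(sdr == 0))
    stop_cosicc("reference cell(s) with zero variance over temporal genes",
                "numerical")
  zero_var <- sdq == 0
  if (any(zero_var))
    message(sum(zero_var),
            " query cell(s) with zero variance over temporal genes -> NA")
  cq <- scale(xq)   # genes x cells, columns standardized
  cr <- scale(xr)
  cors <- crossprod(cq, cr) / (length(genes) - 1)   # query x ref

  out <- rep(NA_real_, ncol(xq))
  names(out) <- colnames(xq)
  for (i in which(!zero_var)) {
    o <- order(-cors[i, ], seq_len(ncol(cors)))[seq_len(k)]
    out[i] <- mean(pt_ref[o])
  }
  out
}
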