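#' Half-sample sub-clustering with classifier label transfer
#'
#' Sub-structure within a cell type is found by Louvain community detection
#' on a k-nearest-neighbour graph (Euclidean distances in the top principal
#' components of log-normalized highly variable genes). To keep downstream
#' tests on the sub-clusters honest (labels not overfitted to every cell),
#' only a `train_frac` half-sample is clustered; the remaining cells are
#' assigned to the discovered clusters by a linear support-vector machine
#' trained on the clustered half's principal-component coordinates.
#'
#' @param counts A [count_matrix()] restricted to one parent group's cells.
#' @param k_neighbors Neighbours for the kNN graph.
#' @param train_frac Fraction of cells clustered directly (the rest are
#'   classified); `1` disables the split.
#' @param n_pcs Number of principal components (capped by the data).
#' @param n_hvg Number of highly variable genes (by log-expression
#'   variance).
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (half-sample split, Louvain, SVM internals).
#' @return A `cosicc_subclusters` data.frame (`cell_id`, `cluster`,
#'   `provenance` in `clustered`/`classified`) with attributes
#'   `classifier_accuracy` (on a held-out slice of the clustered half) and
#'   `n_clusters`.
#' @export
subcluster <- function(counts, k_neighbors = 20, train_frac = 0.5,
                       n_pcs = 50, n_hvg = 500, resolution = 1, seed = 1) {
  n <- length(counts$cells)
  if (n < 2 * k_neighbors)
    stop_cosicc("need at least 2 * k_neighbors cells", "design")
  x <- logcounts(counts)
  vars <- apply(x, 1, var)
  hvg <- order(vars, decreasing = TRUE)[seq_len(min(n_hvg, nrow(x)))]
  x <- x[hvg, , drop = FALSE]
  pc_rank <- min(n_pcs, nrow(x), n - 1)
  pcs <- prcomp(Matrix::t(x), center = TRUE, scale. = FALSE,
                rank. = pc_rank)$x

  n_train <- if (train_frac >= 1) n else max(2 * k_neighbors,
                                             round(n * train_frac))
  train <- with_seed(substream_seed(seed, 1L),
                     sort(sample.int(n, n_train)))
  holdout <- setdiff(seq_len(n), train)
  ptrain <- pcs[train, , drop = FALSE]

  g <- knn_graph(ptrain, k_neighbors)
  comm <- with_seed(substream_seed(seed, 2L),
                    igraph::cluster_louvain(g, resolution = resolution))
  labels_train <- as.integer(igraph::membership(comm))
  if (length(unique(labels_train)) == 1)
    warn_cosicc("Louvain found a single community; all cells in one cluster",
                "single_cluster")

  out <- data.frame(cell_id = counts$cells, cluster = NA_integer_,
                    provenance = NA_character_, row.names = NULL)
  out$cluster[train] <- labels_train
  out$provenance[train] <- "clustered"
  acc <- NA_real_
  if (length(holdout) > 0 && length(unique(labels_train)) > 1) {
    fit <- with_seed(substream_seed(seed, 3L),
                     e1071::svm(x = ptrain, y = factor(labels_train),
                                kernel = "linear", scale = FALSE))
    out$cluster[holdout] <- as.integer(as.character(
      stats::predict(fit, pcs[holdout, , drop = FALSE])))
    out$provenance[holdout] <- "classified"
    # internal validation: refit on 80% of the clustered half
    acc <- with_seed(substream_seed(seed, 4L), {
      idx <- sample.int(length(train), max(2, round(0.8 * length(train))))
      if (length(unique(labels_train[idx])) > 1) {
        f2 <- e1071::svm(x = ptrain[idx, , drop = FALSE],
                         y = factor(labels_train[idx]),
                         kernel = "linear", scale = FALSE)
        pred <- stats::predict(f2, ptrain[-idx, , drop = FALSE])
        mean(as.character(pred) == as.character(labels_train[-idx]))
      } else NA_real_
    })
  } else if (length(holdout) > 0) {
    out$cluster[holdout] <- 1L
    out$provenance[holdout] <- "classified"
  }
  structure(out, classifier_accuracy = acc,
            n_clusters = length(unique(out$cluster)),
            class = c("cosicc_subclusters", "data.frame"))
}

#' @noRd
knn_graph <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Differential abundance over sub-clusters of one parent group
#'
#' Replaces exactly one parent group's labels by its sub-cluster labels and
#' reruns the bias-corrected group DA over the full modified label set, so
#' that the normalization medians are computed across all cell groups (not
#' just the sub-clusters).
#'
#' @param table A [cell_table()].
#' @param labels A [subcluster()] result or named vector (cell id ->
#'   sub-cluster label); the labelled cells must all belong to one parent
#'   group.
#' @param prefix Prefix for the sub-cluster group names (defaults to the
#'   parent group).
#' @param ... Passed to [run_da_group()].
#' @return A `cosicc_da` data.frame over the modified label set.
#' @export
subcluster_da <- function(table, labels, prefix = NULL, ...) {
  if (inherits(labels, "cosicc_subclusters") || is.data.frame(labels))
    labels <- setNames(labels$cluster, labels$cell_id)
  ids <- names(labels)
  miss <- setdiff(ids, table$cell_id)
  if (length(miss) > 0)
    stop_cosicc(paste0("label(s) for unknown cell(s): ",
                       paste(head(miss, 5), collapse = ", ")), "validation")
  parents <- unique(table$group[match(ids, table$cell_id)])
  if (length(parents) != 1)
    stop_cosicc(paste0("sub-cluster labels must cover exactly one parent ",
                       "group; found: ", paste(parents, collapse = ", ")),
                "precondition")
  prefix <- prefix %||% parents
  tab2 <- table
  idx <- match(ids, tab2$cell_id)
  tab2$group[idx] <- paste0(prefix, "_", labels)
  run_da_group(tab2, ...)
}
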