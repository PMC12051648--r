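#' Construct a fate matrix
#'
#' A fate matrix assigns to each cell and each lineage trajectory the
#' probability that the cell belongs to that trajectory (rows are probability
#' vectors, e.g. from Waddington-style optimal-transport analysis).
#'
#' @param probs Numeric matrix, cells x lineages, with cell-id rownames and
#'   lineage-name colnames. Rows must be nonnegative and sum to 1 within
#'   `tol`; rows within tolerance are renormalized to sum exactly 1.
#' @param tol Tolerance on row sums.
#' @return A `cosicc_fates` matrix.
#' @export
fate_matrix <- function(probs, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs)) || is.null(colnames(probs)))
    stop_cosicc("fate matrix needs cell rownames and lineage colnames",
                "schema")
  if (any(probs < 0))
    stop_cosicc("fate probabilities must be nonnegative", "format")
  rs <- rowSums(probs)
  bad <- abs(rs - 1) > tol
  if (any(bad))
    stop_cosicc(paste0("fate row(s) not summing to 1 (tol ", tol, "): ",
                       paste(head(rownames(probs)[bad], 5), collapse = ", ")),
                "normalization")
  probs <- probs / rs
  structure(probs, class = c("cosicc_fates", "matrix", "array"))
}

#' Read a fate matrix from CSV
#'
#' @param path CSV with cell ids in the first column and lineage names in the
#'   header.
#' @param tol Row-sum tolerance, see [fate_matrix()].
#' @return A [fate_matrix()].
#' @export
load_fate_matrix <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop_cosicc(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  fate_matrix(as.matrix(df), tol = tol)
}

#' Write a fate matrix as CSV
#' @param fates A [fate_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fate_matrix <- function(fates, path) {
  df <- data.frame(cell_id = rownames(fates), unclass(fates),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct / read a stage-to-stage transition matrix
#'
#' Rows are cells at one stage, columns cells at the next stage; each row is
#' the transition probability distribution of the source cell.
#'
#' @param probs Numeric matrix with source-cell rownames and destination-cell
#'   colnames; rows must sum to 1 within `tol`.
#' @param tol Row-stochasticity tolerance.
#' @return A `cosicc_transitions` matrix.
#' @export
transition_matrix <- function(probs, tol = 1e-8) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs)) || is.null(colnames(probs)))
    stop_cosicc("transition matrix needs source rownames and dest colnames",
                "schema")
  if (any(probs < 0))
    stop_cosicc("transition probabilities must be nonnegative", "format")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop_cosicc("transition matrix rows must sum to 1", "normalization")
  probs <- probs / rs
  structure(probs, class = c("cosicc_transitions", "matrix", "array"))
}

#' @rdname transition_matrix
#' @param path CSV with source-cell row index and destination-cell header.
#' @export
load_transition_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop_cosicc(paste0("file not found: ", path), "io")
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  transition_matrix(as.matrix(df), tol = tol)
}

#' Propagate transition matrices into a fate matrix
#'
#' Chains stage-to-stage transition matrices forward to the final stage and
#' reads off, for every cell at every stage, the probability that its chain
#' of transitions ends in a final-stage cell of each terminal group. Lineages
#' are retained only when their terminal group has strictly more than
#' `min_terminal` cells at the final stage; rows are then renormalized over
#' the retained lineages.
#'
#' @param transitions List of [transition_matrix()] in stage order; the
#'   destination cells of each must equal the source cells of the next.
#' @param terminal_groups Named character vector mapping every final-stage
#'   cell id to its group (terminal cell type).
#' @param min_terminal Strict lower bound on terminal-group size.
#' @return A [fate_matrix()] whose rows are all cells of all stages
#'   (including the final stage, which gets its one-hot group indicator).
#' @export
propagate_fates <- function(transitions, terminal_groups, min_terminal = 100) {
  if (length(transitions) < 1)
    stop_cosicc("need at least one transition matrix", "design")
  for (k in seq_along(transitions)[-1]) {
    prev_dest <- colnames(transitions[[k - 1]])
    src <- rownames(transitions[[k]])
    if (!setequal(prev_dest, src))
      stop_cosicc(sprintf(
        "transition matrices %d and %d do not chain: destination and source cells differ",
        k - 1, k), "chaining")
    transitions[[k]] <- transitions[[k]][prev_dest, , drop = FALSE]
  }
  final_cells <- colnames(transitions[[length(transitions)]])
  miss <- setdiff(final_cells, names(terminal_groups))
  if (length(miss) > 0)
    stop_cosicc(paste0("terminal_groups missing final-stage cell(s): ",
                       paste(head(miss, 5), collapse = ", ")), "schema")
  tg <- terminal_groups[final_cells]
  groups <- sort(unique(unname(tg)))
  z <- outer(unname(tg), groups, "==") * 1.0   # final cells x groups
  dimnames(z) <- list(final_cells, groups)

  blocks <- vector("list", length(transitions) + 1L)
  blocks[[length(transitions) + 1L]] <- z
  m <- z
  for (k in rev(seq_along(transitions))) {
    m <- unclass(transitions[[k]]) %*% m
    bad <- abs(rowSums(m) - 1) > 1e-8
    if (any(bad))
      stop_cosicc("propagated fate row deviates from stochasticity by > 1e-8",
                  "numerical")
    blocks[[k]] <- m
  }
  fates <- do.call(rbind, blocks)
  fates <- fates[!duplicated(rownames(fates)), , drop = FALSE]

  keep <- groups[tabulate(match(tg, groups), length(groups)) > min_terminal]
  if (length(keep) == 0)
    stop_cosicc("no lineage passes the terminal-size filter", "design")
  fates <- fates[, keep, drop = FALSE]
  rs <- rowSums(fates)
  dropped <- rs <= 0
  if (any(dropped)) {
    warn_cosicc(sprintf(
      "%d cell(s) have zero mass on retained lineages and were dropped",
      sum(dropped)), "dropped_cells")
    fates <- fates[!dropped, , drop = FALSE]
    rs <- rs[!dropped]
  }
  fate_matrix(fates / rs, tol = 1e-6)
}

#' Sample a hard lineage label per cell from a fate matrix
#'
#' @param fates A [fate_matrix()].
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return Named character vector of lineage labels (names = cell ids).
#' @export
sample_lineages <- function(fates, seed) {
  probs <- unclass(fates)
  n <- nrow(probs)
  with_seed(seed, {
    u <- runif(n)
    cs <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
    idx <- rowSums(cs < u) + 1L
    idx[idx > ncol(probs)] <- ncol(probs)
    setNames(colnames(probs)[idx], rownames(probs))
  })
}
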