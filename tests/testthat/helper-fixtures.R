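# Fixture builders shared across test files. Everything is generated in
# code; no fixture is stored on disk.

# A small hand-written cell table: counts per (dataset, marker, group) given
# as a named list, e.g. list(target = list(pos = c(A = 10), neg = c(A = 20))).
make_cells <- function(spec, stage = "E7.50", pool = NULL) {
  rows <- list()
  i <- 0
  for (ds in names(spec)) for (mk in names(spec[[ds]])) {
    cnt <- spec[[ds]][[mk]]
    for (g in names(cnt)) {
      n <- cnt[[g]]
      if (n == 0) next
      ids <- sprintf("c%06d", i + seq_len(n))
      i <- i + n
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = ids, dataset = ds, marker = mk, group = g,
        stage = stage,
        pool_id = pool %||% paste0(substr(ds, 1, 1), "pool",
                                   1 + (seq_len(n) %% 2)),
        stringsAsFactors = FALSE)
    }
  }
  cell_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two well-separated expression blobs: first half of cells high in the
# first half of genes, second half high in the rest.
two_blob_counts <- function(n = 500, n_genes = 30, seed = 9) {
  set.seed(seed)
  counts <- matrix(0L, n_genes, n)
  half_g <- n_genes %/% 2
  half_c <- n %/% 2
  for (i in seq_len(n_genes)) {
    mu <- ifelse((i <= half_g) == (seq_len(n) <= half_c), exp(4), exp(2))
    counts[i, ] <- rnbinom(n, mu = mu, size = 10)
  }
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("cell%05d", seq_len(n)))
  count_matrix(counts)
}

# Exhaustive two-sided Fisher p by direct enumeration with choose()
# products -- the independent oracle for the package's hypergeometric path.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  if (lo == hi) return(1)
  ks <- lo:hi
  pr <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
}

# Write a small cell table TSV and return its path.
write_cells_tsv <- function(df, dir = withr::local_tempdir(.local_envir =
                                                        parent.frame())) {
  path <- file.path(dir, "cells.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
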