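# Internal helpers shared across modules.

#' @noRd
stop_cosicc <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("cosicc_", class), "cosicc_error",
                                     "error", "condition")))
}

#' @noRd
warn_cosicc <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("cosicc_", class),
                                          "cosicc_warning",
                                          "warning", "condition")))
}

# Deterministic substream seed from a user seed and an index; kept within
# 32-bit integer range so set.seed() accepts it on every platform.
#' @noRd
substream_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 69069 + as.double(i) * 104729 + 1) %% 2147483647)
}

# Evaluate expr under a given seed without clobbering the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Benjamini-Hochberg with NA passthrough (non-tested entries keep NA).
#' @noRd
bh_adjust <- function(p) p.adjust(p, method = "BH")

# Vectorized one-way ANOVA of the rows of a matrix on a factor.
# Returns F statistics and p-values; constant rows get F = 0, p = 1.
#' @noRd
row_anova <- function(x, f) {
  f <- droplevels(as.factor(f))
  n <- ncol(x)
  g <- nlevels(f)
  if (g < 2L) stop_cosicc("need at least two levels for ANOVA", "design")
  ind <- stats::model.matrix(~ 0 + f)           # cells x groups
  ng <- colSums(ind)
  gm <- (x %*% ind) / rep(ng, each = nrow(x))   # genes x groups group means
  rm_ <- rowMeans(x)
  ssb <- rowSums(sweep(gm, 1, rm_)^2 %*% diag(ng, g, g))
  sst <- rowSums((x - rm_)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- g - 1L
  df2 <- n - g
  fstat <- (ssb / df1) / pmax(ssw / df2, 1e-300)  # perfect fits -> huge F
  p <- pf(fstat, df1, df2, lower.tail = FALSE)
  constant <- ssb <= 1e-12 * pmax(sst, 1)
  fstat[constant] <- 0
  p[constant] <- 1
  list(f = fstat, p = p, group_means = gm, groups = levels(f))
}
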