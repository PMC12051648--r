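#' Exact two-sided Fisher test for a 2x2 table
#'
#' The table is laid out marker x dataset:
#' \preformatted{
#'              target   control
#'   marker+       a        b
#'   marker-       c        d
#' }
#' The two-sided p-value is the sum of hypergeometric point masses (over the
#' support of `a` given fixed margins) that do not exceed the observed mass,
#' with the customary `1 + 1e-7` relative slack absorbing floating-point ties.
#' The odds ratio is the sample cross-product ratio `(a d)/(b c)`, with the
#' Haldane-Anscombe correction (0.5 added to every cell) whenever any cell is
#' zero -- a deterministic, monotone estimator, deliberately not the
#' conditional MLE.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return List with `odds_ratio` and `p_value` (`p_value = NA` for an empty
#'   table).
#' @export
#' @examples
#' fisher_test_2x2(5, 5, 5, 5)   # symmetric: OR 1, p 1
fisher_test_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_cosicc("table cells must be nonnegative integers", "validation")
  n <- a + b + c + d
  if (n == 0) return(list(odds_ratio = NA_real_, p_value = NA_real_))
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p_value = hypergeom_two_sided(a, b, c, d))
}

# Two-sided hypergeometric p for observed a with fixed margins: the sum of
# all point masses not exceeding the observed one (relative slack 1 + 1e-7
# for floating-point ties). The density is unimodal over the support, so
# instead of scanning the whole support the crossing point on the opposite
# tail is located by binary search and the tails are read off phyper();
# the result is identical to the full enumeration.
#' @noRd
hypergeom_two_sided <- function(a, b, c, d) {
  r1 <- a + b            # marker-positive cells
  c1 <- a + c            # target cells
  n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  if (lo == hi) return(1)
  dens <- function(k) dhyper(k, c1, n - c1, r1)
  mode_ <- floor((r1 + 1) * (c1 + 1) / (n + 2))
  mode_ <- min(max(mode_, lo), hi)
  if (dens(mode_ + (mode_ < hi)) > dens(mode_)) mode_ <- mode_ + 1
  thr <- dens(a) * (1 + 1e-7)
  if (dens(mode_) <= thr) return(1)
  if (a <= mode_) {
    left <- phyper(a, c1, n - c1, r1)
    # first k in (mode_, hi] with mass <= thr (density decreasing there)
    if (dens(hi) > thr) return(min(left, 1))
    l_ <- mode_; r_ <- hi
    while (r_ - l_ > 1) {
      mid <- (l_ + r_) %/% 2
      if (dens(mid) <= thr) r_ <- mid else l_ <- mid
    }
    min(left + phyper(r_ - 1, c1, n - c1, r1, lower.tail = FALSE), 1)
  } else {
    right <- phyper(a - 1, c1, n - c1, r1, lower.tail = FALSE)
    if (dens(lo) > thr) return(min(right, 1))
    l_ <- lo; r_ <- mode_
    while (r_ - l_ > 1) {
      mid <- (l_ + r_) %/% 2
      if (dens(mid) <= thr) l_ <- mid else r_ <- mid
    }
    min(right + phyper(l_, c1, n - c1, r1), 1)
  }
}

#' Fisher test of marker status against dataset for one group
#'
#' Builds the 2x2 contingency table of marker status (rows) by dataset
#' (columns) for cells of one group, taken from the bias-corrected subsamples
#' of the target and control experiments, and applies [fisher_test_2x2()].
#'
#' @param target_table,control_table [cell_table()]s (typically outputs of
#'   [bias_corrected_subsample()]).
#' @param group Group label to test.
#' @return List with `odds_ratio`, `p_value` and `counts`
#'   (`a`, `b`, `c`, `d`).
#' @export
fisher_group_test <- function(target_table, control_table, group) {
  a <- sum(target_table$group == group & target_table$marker == "pos")
  c_ <- sum(target_table$group == group & target_table$marker == "neg")
  b <- sum(control_table$group == group & control_table$marker == "pos")
  d <- sum(control_table$group == group & control_table$marker == "neg")
  res <- fisher_test_2x2(a, b, c_, d)
  c(res, list(counts = c(a = a, b = b, c = c_, d = d)))
}
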