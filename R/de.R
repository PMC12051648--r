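# Interaction differential expression: per gene i and cell j,
#   y_ij ~ NB(mu_ij, phi_i),
#   mu_ij = pi_j * exp(a_i + b1_i m_j + b2_i t_j + b3_i m_j t_j + w_i|pool_j)
# with marker m, condition t, per-cell size factor pi and a Gaussian random
# intercept w per embryo pool. b3 is the quantity of interest: a nonzero
# interaction means the marker effect differs between knockout and control
# chimeras, i.e. a knockout-specific expression change.

#' Per-cell model offsets from size factors
#'
#' @param counts A [count_matrix()].
#' @param method `"libsize"` uses the size factors stored in `counts`
#'   (library size over mean by default); `"supplied"` reads a two-column
#'   TSV (`cell_id`, `size_factor`), e.g. externally computed
#'   pooled-deconvolution factors.
#' @param path TSV path for `method = "supplied"`.
#' @return Named numeric vector of offsets `log(pi_j)`.
#' @export
compute_offsets <- function(counts, method = c("libsize", "supplied"),
                            path = NULL) {
  method <- match.arg(method)
  if (method == "libsize") {
    sf <- counts$size_factors
  } else {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("cell_id", "size_factor") %in% names(df)))
      stop_cosicc("supplied size-factor file needs cell_id and size_factor columns",
                  "schema")
    miss <- setdiff(counts$cells, df$cell_id)
    if (length(miss) > 0)
      stop_cosicc(paste0("size factors missing for cell(s): ",
                         paste(head(miss, 5), collapse = ", ")),
                  "alignment")
    sf <- setNames(df$size_factor, df$cell_id)[counts$cells]
  }
  bad <- !is.finite(sf) | sf <= 0
  if (any(bad))
    stop_cosicc(paste0("non-positive size factor for cell(s): ",
                       paste(head(names(sf)[bad], 5), collapse = ", ")),
                "validation")
  log(sf)
}

#' Fit the NB interaction mixed model for one gene
#'
#' Laplace-approximate maximum likelihood (via glmmTMB) of a
#' negative-binomial regression with log link, offset, fixed effects
#' (intercept, marker, condition, marker:condition) and a Gaussian random
#' intercept per pool. The Wald test on the interaction coefficient is
#' reported; a likelihood-ratio test against the `b3 = 0` null is available
#' with `test = "lrt"`.
#'
#' @param y Integer counts for one gene.
#' @param marker,condition 0/1 indicators per cell (marker-positive;
#'   target dataset).
#' @param pool Pool (batch) labels per cell.
#' @param offsets Per-cell `log(pi_j)` offsets.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return One-row data.frame: `alpha`, `b1`, `b2`, `b3`, `se`, `z`, `p`,
#'   `phi` (NB dispersion, variance `mu + phi mu^2`), `sigma2_pool`,
#'   `loglik`, `converged`.
#' @export
fit_nb_glmm <- function(y, marker, condition, pool, offsets,
                        test = c("wald", "lrt")) {
  test <- match.arg(test)
  pool <- droplevels(as.factor(pool))
  if (nlevels(pool) < 2)
    stop_cosicc("need at least two pools for the random intercept", "design")
  d <- data.frame(y = as.numeric(y), m = as.numeric(marker),
                  t_ = as.numeric(condition), pool = pool,
                  off = as.numeric(offsets))
  xmat <- cbind(1, d$m, d$t_, d$m * d$t_)
  if (qr(xmat)$rank < 4)
    stop_cosicc("design matrix (1, m, t, m:t) is rank deficient on these cells",
                "design")
  fit <- tryCatch(
    suppressWarnings(
      glmmTMB::glmmTMB(y ~ m * t_ + (1 | pool), offset = off,
                       family = glmmTMB::nbinom2, data = d,
                       control = glmmTMB::glmmTMBControl(profile = TRUE))),
    error = function(e) NULL)
  bad_row <- data.frame(alpha = NA_real_, b1 = NA_real_, b2 = NA_real_,
                        b3 = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, phi = NA_real_,
                        sigma2_pool = NA_real_, loglik = NA_real_,
                        converged = FALSE)
  if (is.null(fit)) return(bad_row)
  sm <- tryCatch(summary(fit)$coefficients$cond, error = function(e) NULL)
  if (is.null(sm) || !("m:t_" %in% rownames(sm)) ||
      anyNA(sm[, "Std. Error"]))
    return(bad_row)
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  b <- glmmTMB::fixef(fit)$cond
  p_wald <- sm["m:t_", "Pr(>|z|)"]
  p <- p_wald
  if (test == "lrt") {
    fit0 <- tryCatch(
      suppressWarnings(
        glmmTMB::glmmTMB(y ~ m + t_ + (1 | pool), offset = off,
                         family = glmmTMB::nbinom2, data = d,
                         control = glmmTMB::glmmTMBControl(profile = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit0)) {
      lr <- 2 * (as.numeric(stats::logLik(fit)) -
                   as.numeric(stats::logLik(fit0)))
      p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }
  }
  vc <- glmmTMB::VarCorr(fit)$cond$pool
  data.frame(alpha = unname(b["(Intercept)"]), b1 = unname(b["m"]),
             b2 = unname(b["t_"]), b3 = unname(b["m:t_"]),
             se = sm["m:t_", "Std. Error"], z = sm["m:t_", "z value"],
             p = p, phi = 1 / glmmTMB::sigma(fit),
             sigma2_pool = as.numeric(vc[1, 1]),
             loglik = as.numeric(stats::logLik(fit)), converged = conv)
}

#' Interaction DE for one cell group
#'
#' Filters to the group's cells, requires at least `min_cells_per_class`
#' cells in each dataset x marker class, keeps genes detected in at least
#' `min_detect_frac` of the group's cells, fits [fit_nb_glmm()] per gene and
#' applies Benjamini-Hochberg FDR across the converged fits.
#'
#' @param counts A [count_matrix()].
#' @param table A [cell_table()].
#' @param group Group (cell type) to test; `NULL` tests every group,
#'   skipping (with a message) groups that fail the class-count
#'   precondition.
#' @param min_cells_per_class Per-class cell minimum.
#' @param min_detect_frac Minimum detection fraction per gene.
#' @param offsets Optional per-cell offsets (defaults to
#'   [compute_offsets()] on `counts`).
#' @param test Passed to [fit_nb_glmm()].
#' @return A `cosicc_de` data.frame, one row per tested gene: `gene`, `b3`,
#'   `se`, `z`, `p`, `q`, `log2fc_interaction` (`b3 / ln 2`), `phi`,
#'   `sigma2_pool`, `converged`. Non-converged genes keep `q = NA`.
#' @export
run_de <- function(counts, table, group = NULL, min_cells_per_class = 10,
                   min_detect_frac = 0.05, offsets = NULL,
                   test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (is.null(group)) {
    out <- list()
    for (g in sort(unique(table$group))) {
      res <- tryCatch(
        run_de(counts, table, g, min_cells_per_class = min_cells_per_class,
               min_detect_frac = min_detect_frac, offsets = offsets,
               test = test),
        cosicc_design = function(e) {
          message("group '", g, "' skipped: ", conditionMessage(e))
          NULL
        },
        cosicc_empty_set = function(e) {
          message("group '", g, "' skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(res)) {
        res <- cbind(group = g, res)
        out[[g]] <- as.data.frame(res)
      }
    }
    if (length(out) == 0)
      stop_cosicc("no group passes the DE preconditions", "design")
    all_res <- do.call(rbind, out)
    rownames(all_res) <- NULL
    class(all_res) <- c("cosicc_de", "data.frame")
    return(all_res)
  }
  tab <- as.data.frame(table)
  tab <- tab[tab$group == group & tab$cell_id %in% counts$cells, ,
             drop = FALSE]
  ncls <- table(tab$dataset, tab$marker)
  if (nrow(tab) == 0 || any(dim(ncls) < 2) || any(ncls < min_cells_per_class))
    stop_cosicc(paste0(
      "group '", group, "' lacks ", min_cells_per_class,
      " cells in some dataset x marker class"), "design")
  cm <- subset_counts(counts, cells = tab$cell_id)
  off <- offsets %||% compute_offsets(cm)
  if (!is.null(offsets)) off <- offsets[cm$cells]

  detect <- Matrix::rowSums(cm$counts > 0) / length(cm$cells)
  genes <- cm$genes[detect >= min_detect_frac]
  if (length(genes) == 0)
    stop_cosicc("no gene passes the detection filter", "empty_set")

  m <- as.numeric(tab$marker == "pos")
  t_ <- as.numeric(tab$dataset == "target")
  dense <- as.matrix(cm$counts[genes, , drop = FALSE])
  rows <- lapply(genes, function(g)
    fit_nb_glmm(dense[g, ], m, t_, tab$pool_id, off, test = test))
  out <- do.call(rbind, rows)
  out <- cbind(gene = genes, out)
  out$q <- NA_real_
  out$q[out$converged] <- bh_adjust(out$p[out$converged])
  out$log2fc_interaction <- out$b3 / log(2)
  out <- out[, c("gene", "b3", "se", "z", "p", "q", "log2fc_interaction",
                 "phi", "sigma2_pool", "alpha", "b1", "b2", "loglik",
                 "converged")]
  class(out) <- c("cosicc_de", "data.frame")
  out
}
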