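#' Read a gene set (plain text or GMT)
#'
#' @param path One-gene-per-line text file, or a GMT file (tab-separated:
#'   set name, description, genes...). GMT is detected by the `.gmt`
#'   extension or by tabs in the first line; only the first set of a GMT is
#'   returned unless `set` names one.
#' @param set Optional set name to extract from a GMT file.
#' @return Character vector of gene ids, named by the set (GMT) or the file
#'   base name.
#' @export
read_gene_set <- function(path, set = NULL) {
  if (!file.exists(path)) stop_cosicc(paste0("file not found: ", path), "io")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
    any(grepl("\t", lines))
  if (!is_gmt) {
    genes <- trimws(lines)
    attr(genes, "set") <- sub("\\.[^.]*$", "", basename(path))
    return(genes)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names(parts) <- vapply(parts, `[`, character(1), 1)
  pick <- set %||% names(parts)[1]
  if (!(pick %in% names(parts)))
    stop_cosicc(paste0("gene set '", pick, "' not in file"), "validation")
  genes <- parts[[pick]][-(1:2)]
  genes <- trimws(genes[nzchar(genes)])
  attr(genes, "set") <- pick
  genes
}

#' Per-cell signature score
#'
#' The score of a cell is the unweighted mean of its log-normalized
#' expression over the gene-set genes present in the matrix (e.g. the
#' juxta-cardiac-field score when given JCF marker genes). Missing set genes
#' are counted and reported, never silently ignored.
#'
#' @param counts A [count_matrix()].
#' @param gene_set Character vector of gene ids (see [read_gene_set()]).
#' @return A `cosicc_scores` data.frame (`cell_id`, `score`) with
#'   attributes `set`, `n_used`, `missing_genes`.
#' @export
score_signature <- function(counts, gene_set) {
  if (length(gene_set) == 0) stop_cosicc("empty gene set", "empty_set")
  present <- intersect(gene_set, counts$genes)
  missing <- setdiff(gene_set, counts$genes)
  if (length(present) == 0)
    stop_cosicc("no gene of the set is present in the matrix", "empty_set")
  if (length(missing) > 0)
    message(length(missing), " gene(s) of the set absent from the matrix")
  x <- logcounts(subset_counts(counts, genes = present))
  out <- data.frame(cell_id = counts$cells, score = colMeans(x),
                    row.names = NULL)
  structure(out, set = attr(gene_set, "set"), n_used = length(present),
            missing_genes = missing,
            class = c("cosicc_scores", "data.frame"))
}

#' Compare signature scores between conditions within a group
#'
#' Default contrast (`"condition"`): marker-positive cells of the target
#' (knockout) chimeras vs marker-positive cells of the control chimeras --
#' the knockout-vs-wild-type comparison. `"marker"` contrasts pos vs neg
#' cells within the target chimeras instead.
#'
#' @param scores A [score_signature()] result (or data.frame with `cell_id`,
#'   `score`).
#' @param table A [cell_table()].
#' @param group Group to restrict to; `NULL` uses all cells.
#' @param contrast `"condition"` or `"marker"`.
#' @return List: `shift` (Hodges-Lehmann location difference, first class
#'   minus second), `conf_int`, `p_value`, `n` (per class).
#' @export
compare_scores <- function(scores, table, group = NULL,
                           contrast = c("condition", "marker")) {
  contrast <- match.arg(contrast)
  tab <- as.data.frame(table)
  if (!is.null(group)) tab <- tab[tab$group == group, , drop = FALSE]
  s <- setNames(scores$score, scores$cell_id)
  if (contrast == "condition") {
    x <- s[tab$cell_id[tab$dataset == "target" & tab$marker == "pos"]]
    y <- s[tab$cell_id[tab$dataset == "control" & tab$marker == "pos"]]
  } else {
    x <- s[tab$cell_id[tab$dataset == "target" & tab$marker == "pos"]]
    y <- s[tab$cell_id[tab$dataset == "target" & tab$marker == "neg"]]
  }
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_cosicc("both compared classes need at least two scored cells",
                "design")
  if (sd(c(x, y)) == 0)
    return(list(shift = 0, conf_int = c(0, 0), p_value = 1,
                n = c(length(x), length(y))))
  w <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE))
  list(shift = unname(w$estimate), conf_int = as.numeric(w$conf.int),
       p_value = w$p.value, n = c(length(x), length(y)))
}
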