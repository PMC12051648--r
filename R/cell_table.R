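#' Default embryonic-stage ladder
#'
#' The ordered stage vocabulary used by default throughout the package: the
#' mouse gastrulation window from E6.5 to E9.25 in quarter-day steps. The
#' vocabulary is configuration, not a hard constraint: every reader and
#' simulator accepts an arbitrary ordered character vector of stage labels.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
#' @examples
#' default_stage_order()
default_stage_order <- function() {
  paste0("E", sprintf("%.2f", seq(6.5, 9.25, by = 0.25)))
}

required_cell_columns <- c("cell_id", "dataset", "marker", "group", "stage",
                           "pool_id")

#' Construct a chimera cell-annotation table
#'
#' Validates and normalizes a per-cell annotation data frame. Each row is one
#' cell; `dataset` says which experiment the cell comes from (`"target"` =
#' knockout chimeras, `"control"` = wild-type chimeras, the external control),
#' `marker` whether the cell descends from the injected, fluorescently marked
#' population (`"pos"`) or the host (`"neg"`), `group` is any cell grouping
#' (cell type, sub-cluster, lineage label), `stage` the mapped embryonic
#' stage, and `pool_id` the embryo pool (batch) the cell was processed in.
#'
#' The condition indicator `t_j` used by the interaction model is derived as
#' `1` iff `dataset == "target"`; the marker indicator `m_j` as `1` iff
#' `marker == "pos"`.
#'
#' @param df data.frame with columns `cell_id`, `dataset`, `marker`, `group`,
#'   `stage`, `pool_id`.
#' @param stage_order Ordered character vector of admissible stage labels.
#' @return A `cosicc_cell_table`: a data.frame with normalized `dataset`
#'   (`target`/`control`) and `marker` (`pos`/`neg`) factors, `stage` as an
#'   ordered factor over `stage_order`, and the `stage_order` attribute.
#' @export
cell_table <- function(df, stage_order = default_stage_order()) {
  miss <- setdiff(required_cell_columns, names(df))
  if (length(miss) > 0)
    stop_cosicc(paste0("missing required column(s): ",
                       paste(miss, collapse = ", ")), "schema")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$cell_id <- as.character(df$cell_id)
  dup <- unique(df$cell_id[duplicated(df$cell_id)])
  if (length(dup) > 0)
    stop_cosicc(paste0("duplicated cell_id: ",
                       paste(head(dup, 10), collapse = ", ")), "validation")
  if (anyNA(df$dataset) || anyNA(df$marker))
    stop_cosicc("dataset and marker must be non-missing for every cell",
                "validation")

  df$dataset <- normalize_enum(df$dataset,
    canon = c("target", "control"),
    synonyms = list(target = c("target", "ko", "knockout", "mutant"),
                    control = c("control", "wt", "wildtype", "wild-type")))
  df$marker <- normalize_enum(df$marker,
    canon = c("pos", "neg"),
    synonyms = list(pos = c("pos", "+", "tdtom+", "tdtompos", "positive", "1",
                            "true"),
                    neg = c("neg", "-", "tdtom-", "tdtomneg", "negative", "0",
                            "false")))

  bad_stage <- setdiff(unique(as.character(df$stage)), stage_order)
  if (length(bad_stage) > 0)
    stop_cosicc(paste0("stage label(s) outside the declared vocabulary: ",
                       paste(bad_stage, collapse = ", ")), "validation")
  df$stage <- factor(as.character(df$stage), levels = stage_order,
                     ordered = TRUE)
  df$group <- as.character(df$group)
  df$pool_id <- as.character(df$pool_id)
  for (ds in c("target", "control")) {
    if (any(df$dataset == ds) && !any(nzchar(df$pool_id[df$dataset == ds])))
      stop_cosicc(paste0("dataset '", ds, "' has no pool ids"), "validation")
  }
  df <- df[, c(required_cell_columns,
               setdiff(names(df), required_cell_columns)), drop = FALSE]
  rownames(df) <- NULL
  structure(df, stage_order = stage_order,
            class = c("cosicc_cell_table", "data.frame"))
}

#' @noRd
normalize_enum <- function(x, canon, synonyms) {
  xl <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(xl))
  for (c_ in canon) out[xl %in% synonyms[[c_]]] <- c_
  bad <- unique(x[is.na(out)])
  if (length(bad) > 0)
    stop_cosicc(paste0("unrecognized value(s) '",
                       paste(bad, collapse = "', '"), "'; expected one of: ",
                       paste(canon, collapse = "/")), "validation")
  factor(out, levels = canon)
}

#' Read a chimera cell table from TSV
#'
#' @param path TSV file with header `cell_id`, `dataset`, `marker`, `group`,
#'   `stage`, `pool_id`. Additional columns are carried through.
#' @param stage_order Ordered character vector of admissible stage labels.
#' @param col_map Optional named character vector renaming file columns to the
#'   schema, e.g. `c(marker = "tomato_status")`.
#' @return A [cell_table()].
#' @export
load_cell_table <- function(path, stage_order = default_stage_order(),
                            col_map = NULL) {
  if (!file.exists(path))
    stop_cosicc(paste0("file not found: ", path), "io")
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      j <- match(col_map[[schema_name]], names(df))
      if (!is.na(j)) names(df)[j] <- schema_name
    }
  }
  cell_table(df, stage_order = stage_order)
}

#' Write a chimera cell table as TSV
#'
#' @param table A [cell_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  df <- as.data.frame(table)
  df$dataset <- as.character(df$dataset)
  df$marker <- as.character(df$marker)
  df$stage <- as.character(df$stage)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Condition and marker indicators
#'
#' @param table A [cell_table()].
#' @return Integer vector: 1 for target-dataset (resp. marker-positive) cells.
#' @export
condition_indicator <- function(table) as.integer(table$dataset == "target")

#' @rdname condition_indicator
#' @export
marker_indicator <- function(table) as.integer(table$marker == "pos")

#' @export
print.cosicc_cell_table <- function(x, ...) {
  cat("<cosicc_cell_table> ", nrow(x), " cells; ",
      length(unique(x$group)), " groups; stages ",
      paste(range(as.character(x$stage[!is.na(x$stage)])), collapse = ".."),
      "\n", sep = "")
  print(table(dataset = x$dataset, marker = x$marker))
  invisible(x)
}
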