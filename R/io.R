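# File IO: count matrices (matrix-market or CSV, auto-detected by
# extension), coordinate tables, labels/groupings, proportion tables.
#
# Matrix-market layout: <base>.mtx stores the numeric matrix (rows = spots
# or cells), with row ids in <base>_rows.tsv and column (gene) ids in
# <base>_cols.tsv, one id per line -- a 10x-style triplet of files.

.sidecar_paths <- function(path_matrix) {
  base <- sub("\\.mtx$", "", path_matrix)
  list(rows = paste0(base, "_rows.tsv"), cols = paste0(base, "_cols.tsv"))
}

.read_matrix_auto <- function(path_matrix) {
  ext <- tolower(tools::file_ext(path_matrix))
  if (ext == "mtx") {
    side <- .sidecar_paths(path_matrix)
    for (p in c(path_matrix, side$rows, side$cols))
      if (!file.exists(p)) .stopf("missing matrix file: %s", p)
    m <- as.matrix(Matrix::readMM(path_matrix))
    rownames(m) <- readLines(side$rows)
    colnames(m) <- readLines(side$cols)
    m
  } else if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- utils::read.table(path_matrix, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    as.matrix(df)
  } else {
    .stopf("unsupported matrix format '%s' (expected .mtx, .csv or .tsv)", ext)
  }
}

.write_matrix_auto <- function(m, path_matrix) {
  ext <- tolower(tools::file_ext(path_matrix))
  if (ext == "mtx") {
    side <- .sidecar_paths(path_matrix)
    Matrix::writeMM(Matrix::Matrix(unname(as.matrix(m)), sparse = TRUE),
                    path_matrix)
    writeLines(rownames(m), side$rows)
    writeLines(colnames(m), side$cols)
  } else if (ext %in% c("csv", "tsv")) {
    sep <- if (ext == "csv") "," else "\t"
    df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path_matrix, sep = sep, quote = FALSE,
                       row.names = FALSE)
  } else {
    .stopf("unsupported matrix format '%s'", ext)
  }
  invisible(path_matrix)
}

#' Read and write spatial counts
#'
#' The count matrix (spots in rows) is read from matrix-market (`.mtx` plus
#' `_rows.tsv` / `_cols.tsv` id files) or CSV/TSV with gene-id header and
#' spot-id first column; the format is chosen by file extension. The
#' coordinate table is a TSV with columns `spot_id`, `row`, `col`.
#'
#' @param path_matrix path to the count matrix file.
#' @param path_coords path to the coordinate TSV.
#' @return [read_spatial_counts()] returns a validated [spatial_counts()]
#'   object with file ordering preserved.
#' @export
read_spatial_counts <- function(path_matrix, path_coords) {
  m <- .read_matrix_auto(path_matrix)
  coords <- utils::read.table(path_coords, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (nrow(coords) != nrow(m))
    .stopf("dimension mismatch: %s has %d spots but %s has %d coordinate rows",
           path_matrix, nrow(m), path_coords, nrow(coords))
  ord <- match(rownames(m), coords$spot_id)
  if (anyNA(ord))
    .stopf("spots missing from coordinate table: %s",
           paste(utils::head(setdiff(rownames(m), coords$spot_id), 5),
                 collapse = ", "))
  spatial_counts(m, coords[ord, , drop = FALSE])
}

#' @rdname read_spatial_counts
#' @param x a `spatial_counts` object.
#' @export
write_spatial_counts <- function(x, path_matrix, path_coords) {
  .write_matrix_auto(x$counts, path_matrix)
  utils::write.table(x$coords, path_coords, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_coords))
}

#' Read and write a single-cell reference
#'
#' The matrix holds cells in rows; the labels file is a TSV mapping
#' `cell_id` to `fine_type`; the grouping file is a TSV mapping `fine_type`
#' to `region_type`.
#'
#' @param path_matrix path to the cell-by-gene count matrix (.mtx/.csv/.tsv).
#' @param path_labels path to the cell label TSV (`cell_id`, `fine_type`).
#' @param path_grouping path to the grouping TSV (`fine_type`,
#'   `region_type`).
#' @return [read_reference()] returns a validated [single_cell_reference()].
#' @export
read_reference <- function(path_matrix, path_labels, path_grouping) {
  m <- .read_matrix_auto(path_matrix)
  labels <- utils::read.table(path_labels, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  grouping <- utils::read.table(path_grouping, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ord <- match(rownames(m), labels$cell_id)
  if (anyNA(ord))
    .stopf("cells missing from label table: %s",
           paste(utils::head(setdiff(rownames(m), labels$cell_id), 5),
                 collapse = ", "))
  fine <- labels$fine_type[ord]
  map <- stats::setNames(grouping$region_type, grouping$fine_type)
  single_cell_reference(m, fine, map)
}

#' @rdname read_reference
#' @param ref a `single_cell_reference` object.
#' @export
write_reference <- function(ref, path_matrix, path_labels, path_grouping) {
  .write_matrix_auto(ref$counts, path_matrix)
  utils::write.table(data.frame(cell_id = ref$cell_ids,
                                fine_type = ref$fine_type),
                     path_labels, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(fine_type = names(ref$region_type_of),
                                region_type = unname(ref$region_type_of)),
                     path_grouping, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_matrix, path_labels, path_grouping))
}

#' Read and write proportion tables
#'
#' CSV with `spot_id` as first column and one column per cell type.
#'
#' @param path CSV path.
#' @param level proportion level recorded on read (`"region"` or `"fine"`).
#' @return [read_proportions()] returns a [proportion_matrix()].
#' @export
read_proportions <- function(path, level = c("region", "fine")) {
  level <- match.arg(level)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  proportion_matrix(as.matrix(df), level = level, tol = 1e-6)
}

#' @rdname read_proportions
#' @param p a `proportion_matrix`.
#' @export
write_proportions <- function(p, path) {
  df <- data.frame(spot_id = rownames(p), as.data.frame(unclass(p)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
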