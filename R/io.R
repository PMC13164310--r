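#' Read an expression matrix from TSV
#'
#' Expects a rectangular tab-separated table with a header row and an
#' identifier column. Orientation is auto-detected by default: an identifier
#' column named like \code{cell_line}/\code{sample} marks cell lines in
#' rows, one named like \code{gene} marks genes in rows; otherwise the
#' larger dimension is taken as genes. It can also be forced with
#' \code{orientation}. The returned matrix always has cell lines in rows
#' and genes in columns.
#'
#' @param path Path to the TSV file.
#' @param orientation \code{"auto"} (default), \code{"cells_in_rows"} or
#'   \code{"genes_in_rows"}.
#' @return Numeric matrix (cell lines x genes) with dimnames.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("auto", "cells_in_rows",
                                                "genes_in_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate identifier(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("non-numeric values in %s", path), call. = FALSE)
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in %s at row '%s', column '%s'", path,
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  id_name <- tolower(names(df)[1L])
  genes_in_rows <- switch(orientation,
                          auto = if (id_name %in% c("cell_line", "cell",
                                                    "sample", "cell_id")) {
                            FALSE
                          } else if (id_name %in% c("gene", "gene_id",
                                                    "gene_symbol")) {
                            TRUE
                          } else {
                            nrow(m) > ncol(m)
                          },
                          genes_in_rows = TRUE,
                          cells_in_rows = FALSE)
  if (genes_in_rows) {
    if (orientation == "auto")
      message(sprintf("%s: treating rows as genes", basename(path)))
    m <- t(m)
  }
  m
}

#' Write an expression matrix to TSV
#'
#' Cell lines in rows, genes in columns, with an identifier column.
#'
#' @param expression Numeric matrix with dimnames.
#' @param path Output path.
#' @param id Name of the identifier column (default \code{"id"};
#'   \code{"cell_line"} makes the orientation self-describing for
#'   \code{\link{read_expression_tsv}}).
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(expression, path, id = "id") {
  df <- data.frame(rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell-line value table (modulator / phenotype) from TSV
#'
#' Two or more columns: the first is the cell line identifier; remaining
#' columns are returned as a data frame.
#'
#' @param path Path to the TSV file.
#' @return Data frame with rownames set to the identifiers.
#' @export
read_modulator_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate identifier(s) in %s", path), call. = FALSE)
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write a precision matrix to TSV
#'
#' Either a dense matrix with identifiers, or a sparse representation: an
#' edge list (\code{gene_i}, \code{gene_j}, \code{weight}; upper triangle)
#' plus a companion \code{*.diag.tsv} file holding the diagonal.
#'
#' @param omega Precision matrix (or \code{cell_line_network}).
#' @param path Output path.
#' @param format \code{"dense"} (default) or \code{"edges"}.
#' @return \code{path}, invisibly.
#' @export
write_precision_tsv <- function(omega, path, format = c("dense", "edges")) {
  format <- match.arg(format)
  om <- if (inherits(omega, "cell_line_network")) omega$omega else
    unclass_matrix(omega)
  ids <- colnames(om)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(om)))
  if (format == "dense") {
    dimnames(om) <- list(ids, ids)
    write_expression_tsv(om, path)
  } else {
    ut <- which(upper.tri(om) & om != 0)
    rc <- arrayInd(ut, dim(om))
    edges <- data.frame(gene_i = ids[rc[, 1L]], gene_j = ids[rc[, 2L]],
                        weight = om[ut], stringsAsFactors = FALSE)
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    diag_df <- data.frame(gene = ids, value = diag(om),
                          stringsAsFactors = FALSE)
    utils::write.table(diag_df, sub("(\\.tsv)?$", ".diag.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a dense precision matrix written by \code{write_precision_tsv}
#'
#' @param path Path to the dense TSV.
#' @return Symmetric numeric matrix.
#' @export
read_precision_tsv <- function(path) {
  m <- read_expression_tsv(path, orientation = "cells_in_rows")
  if (nrow(m) != ncol(m))
    stop(sprintf("%s is not a square matrix", path), call. = FALSE)
  m
}

#' Write a simulated panel to a directory
#'
#' Emits \code{expression.tsv} (cell lines x genes),
#' \code{cells.tsv} (modulator, label per cell line),
#' \code{truth.tsv} (per-subnetwork specificity flags) and
#' \code{partition.tsv} (gene-to-subnetwork map).
#'
#' @param panel A \code{cell_line_panel}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(panel$expression, file.path(dir, "expression.tsv"),
                       id = "cell_line")
  cells <- data.frame(cell_line = rownames(panel$expression),
                      modulator = panel$modulator,
                      label = as.character(panel$labels),
                      stringsAsFactors = FALSE)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- data.frame(subnetwork = names(panel$partition),
                      specific = panel$truth, stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  part <- data.frame(
    gene = colnames(panel$expression),
    subnetwork = rep(names(panel$partition),
                     vapply(panel$partition, length, 0L)),
    stringsAsFactors = FALSE)
  utils::write.table(part, file.path(dir, "partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
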