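#' Developmental stages and lineage labels recognised by the package
#'
#' Embryonic-day stage labels span E3 through E7, with the early-E4 and
#' early-E5 sub-stages that single-cell studies of human preimplantation
#' development distinguish. Lineage labels cover the three blastocyst
#' lineages (epiblast, primitive endoderm, trophectoderm), the pre-lineage
#' state of early-blastocyst cells that still co-express markers of several
#' lineages, and an explicit "unassigned".
#'
#' @name stage-levels
#' @keywords internal
NULL

STAGE_LEVELS <- c("E3", "E4.early", "E4", "E5.early", "E5", "E6", "E7", "other")
LINEAGE_LEVELS <- c("EPI", "PE", "TE", "pre-lineage", "unassigned")
ORIGIN_LEVELS <- c("maternal", "embryonic", "unknown")

#' Construct a validated gene-by-cell expression matrix
#'
#' The central container of the package: a dense non-negative matrix of
#' expression values (FPKM-like or otherwise normalised units; units are
#' treated as opaque) with genes as rows and cells as columns, plus optional
#' per-cell and per-gene annotation. Zero encodes "not detected".
#'
#' @param values numeric matrix, genes x cells, with unique rownames
#'   (gene ids) and colnames (cell ids); all entries finite and >= 0.
#' @param cell_meta optional data.frame with a `cell_id` column matching the
#'   matrix columns; typical columns are `embryo_id`, `stage` (one of
#'   `r paste(STAGE_LEVELS, collapse = ", ")`), `lineage` (one of
#'   `r paste(LINEAGE_LEVELS, collapse = ", ")`) and `dataset_id`.
#' @param gene_meta optional data.frame with a `gene_id` column matching the
#'   matrix rows; may carry an `origin` column (maternal / embryonic /
#'   unknown) used by [origin_summary()].
#'
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `cell_meta`, `gene_meta`.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 2, 3, 4, 5), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
#' em <- expression_matrix(m)
#' dim(em$values)
expression_matrix <- function(values, cell_meta = NULL, gene_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stopf("expression matrix must have at least one gene and one cell (got %d x %d)",
          nrow(values), ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate cell ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stopf("expression values must be finite and non-missing (absent = 0)")
  if (any(values < 0))
    stopf("negative expression values are not allowed")

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(values), stringsAsFactors = FALSE)
  }
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = rownames(values), stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta)) stopf("`cell_meta` needs a `cell_id` column")
  if (!"gene_id" %in% names(gene_meta)) stopf("`gene_meta` needs a `gene_id` column")
  if (!setequal(cell_meta$cell_id, colnames(values)) ||
      anyDuplicated(cell_meta$cell_id))
    stopf("`cell_meta$cell_id` must match the matrix cell ids exactly")
  if (!setequal(gene_meta$gene_id, rownames(values)) ||
      anyDuplicated(gene_meta$gene_id))
    stopf("`gene_meta$gene_id` must match the matrix gene ids exactly")
  # align metadata row order with the matrix axes
  cell_meta <- cell_meta[match(colnames(values), cell_meta$cell_id), , drop = FALSE]
  gene_meta <- gene_meta[match(rownames(values), gene_meta$gene_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  if ("stage" %in% names(cell_meta)) {
    bad <- setdiff(unique(as.character(cell_meta$stage)), STAGE_LEVELS)
    if (length(bad)) stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  }
  if ("lineage" %in% names(cell_meta)) {
    bad <- setdiff(unique(as.character(cell_meta$lineage)), LINEAGE_LEVELS)
    if (length(bad)) stopf("unknown lineage label(s): %s", paste(bad, collapse = ", "))
  }
  if ("origin" %in% names(gene_meta)) {
    bad <- setdiff(unique(as.character(gene_meta$origin)), ORIGIN_LEVELS)
    if (length(bad)) stopf("unknown origin label(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(values = values, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra))
    cat("  cell annotations:", paste(extra, collapse = ", "), "\n")
  extra <- setdiff(names(x$gene_meta), "gene_id")
  if (length(extra))
    cat("  gene annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports dense TSV/CSV (header row of cell ids, first column gene ids)
#' and MatrixMarket triplet format with one-column gene-id and cell-id
#' sidecar files. Whatever the on-disk orientation, the returned object is
#' always genes x cells; the `orientation` flag only relabels axes, it never
#' transforms values. Entries absent from a sparse MTX file become zeros.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; defaults from the file
#'   extension.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`,
#'   describing the file layout.
#' @param gene_ids,cell_ids for `format = "mtx"`, paths to the one-column
#'   row-id and column-id sidecar files (row ids are genes under
#'   `genes_by_cells`).
#' @inheritParams expression_matrix
#' @return an [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "tsv", "csv", "mtx"),
                                   orientation = c("genes_by_cells", "cells_by_genes"),
                                   gene_ids = NULL, cell_ids = NULL,
                                   cell_meta = NULL, gene_meta = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stopf("cannot infer format from extension '%s'; pass `format`", ext))
  }
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                            row.names = NULL, stringsAsFactors = FALSE,
                            comment.char = "")
    if (ncol(df) < 2L) stopf("matrix file %s has no value columns", path)
    ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
      stopf("non-numeric entries in %s", path)
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
  } else {
    if (is.null(gene_ids) || is.null(cell_ids))
      stopf("MTX input needs `gene_ids` and `cell_ids` sidecar files")
    m <- Matrix::readMM(path)
    gid <- readLines(gene_ids); gid <- gid[nzchar(gid)]
    cid <- readLines(cell_ids); cid <- cid[nzchar(cid)]
    # map the logical gene/cell sidecars onto the file's row/column axes
    rid <- if (orientation == "genes_by_cells") gid else cid
    kid <- if (orientation == "genes_by_cells") cid else gid
    if (nrow(m) != length(rid) || ncol(m) != length(kid))
      stopf("MTX dimensions %dx%d do not match id files (%d rows, %d columns)",
            nrow(m), ncol(m), length(rid), length(kid))
    dimnames(m) <- list(rid, kid)
    vals <- as.matrix(m)
    storage.mode(vals) <- "double"
  }
  if (orientation == "cells_by_genes") vals <- t(vals)
  expression_matrix(vals, cell_meta = cell_meta, gene_meta = gene_meta)
}

#' Write an expression matrix to a dense TSV/CSV file
#'
#' Genes as rows, first column `gene_id`, remaining columns the cell ids.
#' Round-trips with [read_expression_matrix()].
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "csv")) {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset an expression matrix by gene and/or cell ids
#'
#' @param x an `expr_matrix`.
#' @param genes,cells character vectors of ids to keep (NULL = keep all).
#' @return an `expr_matrix` restricted to the requested axes.
#' @export
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  genes <- genes %||% rownames(x$values)
  cells <- cells %||% colnames(x$values)
  missing_g <- setdiff(genes, rownames(x$values))
  if (length(missing_g))
    stopf("gene(s) not in matrix: %s", paste(missing_g, collapse = ", "))
  missing_c <- setdiff(cells, colnames(x$values))
  if (length(missing_c))
    stopf("cell(s) not in matrix: %s", paste(missing_c, collapse = ", "))
  expression_matrix(x$values[genes, cells, drop = FALSE],
                    cell_meta = x$cell_meta[x$cell_meta$cell_id %in% cells, , drop = FALSE],
                    gene_meta = x$gene_meta[x$gene_meta$gene_id %in% genes, , drop = FALSE])
}
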