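#' Read a genes x cells expression matrix
#'
#' Two dialects are supported: \code{"dense_tsv"} (first column gene symbols,
#' header row of cell names, tab- or comma-delimited by extension) and
#' \code{"mtx_dir"} (a directory with \code{matrix.mtx} in MatrixMarket
#' triplet format plus \code{genes.tsv} and \code{barcodes.tsv}, one symbol /
#' barcode per line). Values must be non-negative counts or TPM-like numbers.
#' Duplicate gene symbols are collapsed by summation (with a message), the
#' convention for public matrices carrying multiple rows per symbol.
#'
#' @param path File (dense) or directory (mtx) path.
#' @param format \code{"dense_tsv"} or \code{"mtx_dir"}.
#' @return Base numeric matrix, genes in rows (unique symbols as rownames),
#'   cells in columns (unique names as colnames).
#' @export
read_expression <- function(path, format = c("dense_tsv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.delim(path, header = TRUE, sep = sep, quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop(sprintf("format error: %s has no cell columns", path), call. = FALSE)
    genes <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
  } else {
    mtx_path <- file.path(path, "matrix.mtx")
    genes_path <- file.path(path, "genes.tsv")
    barcodes_path <- file.path(path, "barcodes.tsv")
    for (p in c(mtx_path, genes_path, barcodes_path))
      if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    m <- Matrix::readMM(mtx_path)
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
    if (length(genes) != nrow(m))
      stop(sprintf("format error: genes.tsv has %d rows but matrix declares %d",
                   length(genes), nrow(m)), call. = FALSE)
    if (length(barcodes) != ncol(m))
      stop(sprintf("format error: barcodes.tsv has %d rows but matrix declares %d",
                   length(barcodes), ncol(m)), call. = FALSE)
    mat <- as.matrix(m)
    dimnames(mat) <- list(genes, barcodes)
  }
  if (anyNA(mat)) stop("data error: expression matrix contains NA", call. = FALSE)
  if (any(mat < 0)) stop("data error: negative expression values", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("data error: duplicate cell names", call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    ndup <- sum(duplicated(rownames(mat)))
    message(sprintf("read_expression: summing %d duplicate gene row(s)", ndup))
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE)
  }
  mat
}

#' Write an expression matrix + metadata to disk
#'
#' Emits the dialects \code{\link{read_expression}} and
#' \code{\link{read_metadata}} read back: either one dense TSV or a
#' MatrixMarket directory, plus \code{meta.tsv}. Used by the \code{simulate}
#' CLI subcommand and the test fixtures.
#'
#' @param expr Genes x cells matrix with dimnames.
#' @param meta Named character vector: cell name -> cell type.
#' @param dir Output directory.
#' @param format \code{"dense"} or \code{"mtx"}.
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(expr, meta, dir, format = c("dense", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "dense") {
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(expr, sparse = TRUE), "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(expr), file.path(dir, "genes.tsv"))
    writeLines(colnames(expr), file.path(dir, "barcodes.tsv"))
  }
  utils::write.table(data.frame(cell = names(meta), cell_type = unname(meta),
                                stringsAsFactors = FALSE),
                     file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read cell metadata (cell -> cell type)
#'
#' @param path Two-column tab-delimited file with header (cell, cell_type).
#' @return Named character vector mapping cell name to cell-type label.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop(sprintf("format error: %s needs columns (cell, cell_type)", path),
         call. = FALSE)
  cells <- df[[1L]]
  types <- df[[2L]]
  if (anyDuplicated(cells))
    stop(sprintf("data error: duplicated cell name(s) in META: %s",
                 paste(unique(cells[duplicated(cells)]), collapse = ", ")),
         call. = FALSE)
  if (any(types == "" | is.na(types)))
    stop("data error: empty cell type label in META", call. = FALSE)
  stats::setNames(types, cells)
}

#' Library-size normalization
#'
#' \code{"cpm"} rescales every cell (column) linearly so its values sum to
#' 10,000 -- the fixed target any scale-homogeneous score is indifferent to.
#' \code{"none"} passes values through (for TPM input already on a common
#' scale). No log transform is applied anywhere: the enzyme difference and
#' the geometric means are defined on linear expression.
#'
#' @param expr Genes x cells matrix.
#' @param mode \code{"cpm"} or \code{"none"}.
#' @param zero_cells Under cpm, \code{"drop"} all-zero cells with a warning
#'   (default) or \code{"error"}.
#' @return Matrix of the same genes; possibly fewer cells under cpm/drop.
#' @export
normalize_expression <- function(expr, mode = c("cpm", "none"),
                                 zero_cells = c("drop", "error")) {
  mode <- match.arg(mode)
  zero_cells <- match.arg(zero_cells)
  if (mode == "none") return(expr)
  cs <- colSums(expr)
  zero <- cs == 0
  if (any(zero)) {
    if (zero_cells == "error")
      stop(sprintf("data error: %d all-zero cell(s) under cpm normalization",
                   sum(zero)), call. = FALSE)
    warning(sprintf("normalize_expression: dropping %d all-zero cell(s)",
                    sum(zero)), call. = FALSE)
    expr <- expr[, !zero, drop = FALSE]
    cs <- cs[!zero]
  }
  sweep(expr, 2L, cs / 1e4, "/")
}

#' Per-cell-type expression profiles
#'
#' Aggregates a (normalized) matrix to the two quantities scoring consumes:
#' the mean expression of each gene within each cell type, and the expressed
#' fraction (share of the type's cells with value strictly > 0, which drives
#' the N-percent filter). Cells present in the metadata but absent from the
#' matrix are ignored with a warning (the matrix defines the analysis
#' universe); matrix cells without a label are an error.
#'
#' @param expr Genes x cells matrix with dimnames.
#' @param meta Named character vector, cell -> cell type.
#' @return Object of class \code{mlr_profile}: list with \code{mean_expr} and
#'   \code{expr_frac} (genes x cell-types matrices), \code{n_cells} (named
#'   integer), \code{cell_types}.
#' @export
profile_cell_types <- function(expr, meta) {
  cells <- colnames(expr)
  extra <- setdiff(names(meta), cells)
  if (length(extra))
    warning(sprintf("profile_cell_types: ignoring %d META cell(s) absent from the matrix",
                    length(extra)), call. = FALSE)
  missing <- setdiff(cells, names(meta))
  if (length(missing))
    stop(sprintf("data error: matrix cell(s) missing from META: %s",
                 paste(utils::head(missing, 10L), collapse = ", ")), call. = FALSE)
  labels <- unname(meta[cells])
  types <- sort(unique(labels))
  ind <- outer(labels, types, "==") * 1  # cells x types indicator
  n_cells <- colSums(ind)
  mean_expr <- (expr %*% ind) %*% diag(1 / n_cells, nrow = length(types))
  expr_frac <- ((expr > 0) %*% ind) %*% diag(1 / n_cells, nrow = length(types))
  dimnames(mean_expr) <- dimnames(expr_frac) <- list(rownames(expr), types)
  structure(list(mean_expr = mean_expr, expr_frac = expr_frac,
                 n_cells = stats::setNames(as.integer(n_cells), types),
                 cell_types = types),
            class = "mlr_profile")
}

#' @export
print.mlr_profile <- function(x, ...) {
  cat(sprintf("mlr_profile: %d genes x %d cell types (%s)\n",
              nrow(x$mean_expr), length(x$cell_types),
              paste(sprintf("%s: %d", x$cell_types, x$n_cells), collapse = ", ")))
  invisible(x)
}
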