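#' Validate a genes x cells count matrix
#'
#' Coerces `x` to the plain integer-valued matrix used throughout the
#' package: genes in rows, cells in columns, unique row and column labels.
#' Counts are modeled as-is; no normalization, library-size correction or
#' gene filtering is applied anywhere in the package.
#'
#' @param x numeric matrix (or object coercible to one) of non-negative
#'   integer counts, genes in rows.
#' @param gene_ids,cell_ids optional character vectors of labels; default to
#'   the dimnames of `x`, or `gene1..geneG` / `cell1..cellN` when absent.
#' @return a base matrix of mode numeric with integral non-negative entries
#'   and unique dimnames.
#' @export
as_counts <- function(x, gene_ids = NULL, cell_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop("counts must be numeric")
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("counts must have at least 2 genes (rows) and 1 cell (column)")
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers with no missing values")
  if (is.null(gene_ids)) gene_ids <- rownames(x)
  if (is.null(cell_ids)) cell_ids <- colnames(x)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(x)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(x)))
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell ids must be unique")
  dimnames(x) <- list(as.character(gene_ids), as.character(cell_ids))
  storage.mode(x) <- "double"
  x
}

#' Read a count matrix from CSV/TSV or MatrixMarket
#'
#' CSV/TSV layout: header row of cell ids, first column gene ids.
#' MatrixMarket (`.mtx`) layout: triplet file plus sidecar text files (one
#' label per line) for genes and cells; by default `<stem>.genes.txt` and
#' `<stem>.cells.txt` next to the `.mtx` file.
#'
#' @param path file to read.
#' @param format one of `"auto"` (by extension), `"csv"`, `"tsv"`, `"mtx"`.
#' @param genes,cells sidecar label files for the MatrixMarket format.
#' @return a validated count matrix (see [as_counts()]).
#' @export
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        genes = NULL, cells = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
      stop("non-numeric counts in column '", colnames(df)[bad], "'")
    }
    return(as_counts(m))
  }
  stem <- sub("\\.mtx$", "", path)
  if (is.null(genes)) genes <- paste0(stem, ".genes.txt")
  if (is.null(cells)) cells <- paste0(stem, ".cells.txt")
  m <- as.matrix(Matrix::readMM(path))
  as_counts(m,
            gene_ids = readLines(genes),
            cell_ids = readLines(cells))
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; round-trips exactly.
#'
#' @param x count matrix.
#' @param path output file; for `"mtx"`, sidecar `<stem>.genes.txt` and
#'   `<stem>.cells.txt` files are written next to it.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "csv", "tsv", "mtx")) {
  x <- as_counts(x)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(stem, ".genes.txt"))
    writeLines(colnames(x), paste0(stem, ".cells.txt"))
  }
  invisible(path)
}
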