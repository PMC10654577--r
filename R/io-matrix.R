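#' Read a genes-by-spots expression matrix
#'
#' Reads either a TSV (first column gene identifiers, remaining columns one
#' per spot barcode) or a MatrixMarket `.mtx` file with sidecar
#' `genes.tsv`/`barcodes.tsv` files in the same directory (one identifier
#' per line).
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param genes,barcodes Optional sidecar paths for the MatrixMarket case.
#' @param spot_table Optional spot tibble; when given, column barcodes must
#'   all be present in it.
#' @return A base numeric matrix (genes x spots) with dimnames.
#' @export
read_expression_matrix <- function(path, genes = NULL, barcodes = NULL,
                                   spot_table = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes <- genes %||% file.path(dirname(path), "genes.tsv")
    barcodes <- barcodes %||% file.path(dirname(path), "barcodes.tsv")
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(barcodes)
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- as.character(tbl[[1]])
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) {
    abort("duplicate gene identifiers in expression matrix",
      class = "clonospace_schema_error"
    )
  }
  if (any(m < 0)) {
    abort("expression matrix has negative entries",
      class = "clonospace_schema_error"
    )
  }
  if (!is.null(spot_table)) {
    missing <- setdiff(colnames(m), spot_table$barcode)
    if (length(missing)) {
      abort(
        paste0(
          "expression columns absent from spot table: ",
          paste(head(missing, 5), collapse = ", ")
        ),
        class = "clonospace_schema_error"
      )
    }
  }
  m
}

#' Write a genes-by-spots matrix as TSV
#'
#' @param m Numeric matrix with gene rownames and barcode colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  tbl <- as_tibble(m, rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
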