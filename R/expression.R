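# Expression-matrix I/O and validation.
#
# An expression matrix is a plain numeric matrix, genes in rows (rownames =
# gene identifiers), samples in columns (colnames = sample identifiers), with
# no missing values. That is the shape the correlation step consumes.

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants required before network construction: a numeric
#' matrix with unique gene rownames, no missing or non-finite values, at
#' least 3 genes and 3 samples, and no constant (zero-variance) gene rows,
#' for which the Pearson correlation is undefined.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param require_nonconstant If `TRUE` (default), reject constant gene rows.
#' @return `expr`, invisibly, if valid. Otherwise an error naming the problem
#'   (constant-row errors list the offending gene identifiers).
#' @export
validate_expression <- function(expr, require_nonconstant = TRUE) {
  .check(is.matrix(expr) && is.numeric(expr),
         "expression data must be a numeric matrix (genes x samples)")
  .check(!is.null(rownames(expr)), "expression matrix must have gene rownames")
  .check(!anyDuplicated(rownames(expr)), "duplicated gene identifiers in expression matrix")
  .check(nrow(expr) >= 3L && ncol(expr) >= 3L,
         "expression matrix needs at least 3 genes and 3 samples")
  .check(all(is.finite(expr)), "expression matrix contains missing or non-finite values")
  if (require_nonconstant) {
    v <- apply(expr, 1L, var)
    if (any(v == 0)) {
      bad <- rownames(expr)[v == 0]
      stop("constant expression rows (zero variance): ",
           paste(head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "",
           call. = FALSE)
    }
  }
  invisible(expr)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column and
#' one column per sample.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check(ncol(df) >= 2L, "expression TSV needs a gene column plus sample columns")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression(m, require_nonconstant = FALSE)
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
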