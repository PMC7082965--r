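# Gene -> module partitions, including the "unassigned" state (label 0).

#' Construct a module partition
#'
#' A partition maps every gene to a module label `1..K`, or to `0` for
#' unassigned genes (in this pipeline, genes isolated after edge
#' thresholding). Labels must be contiguous `1..K`.
#'
#' @param assignment Named integer vector (names = gene identifiers; values =
#'   module labels, 0 for unassigned).
#' @return Object of class `module_partition` (a named integer vector).
#' @export
module_partition <- function(assignment) {
  .check(!is.null(names(assignment)) && !anyDuplicated(names(assignment)),
         "assignment must be named with unique gene identifiers")
  a <- as.integer(assignment)
  names(a) <- names(assignment)
  .check(all(!is.na(a)) && all(a >= 0L), "module labels must be integers >= 0")
  labs <- sort(unique(a[a > 0L]))
  .check(length(labs) == 0L || identical(labs, seq_along(labs)),
         "module labels must be contiguous 1..K")
  structure(a, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d genes, %d modules, %d unassigned\n",
              length(x), n_modules(x), count_unassigned(x)))
  if (n_modules(x) > 0L) {
    cat("  module sizes:", paste(module_sizes(x), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.module_partition` <- function(x, ...) {
  out <- NextMethod()
  class(out) <- "module_partition"
  out
}

#' Number of modules in a partition
#'
#' @param partition A `module_partition`.
#' @return Integer count of distinct (non-zero) module labels.
#' @export
n_modules <- function(partition) {
  length(unique(partition[partition > 0L]))
}

#' Module sizes, largest first label order
#'
#' @param partition A `module_partition`.
#' @return Integer vector of module sizes indexed by module label (unassigned
#'   genes excluded).
#' @export
module_sizes <- function(partition) {
  if (n_modules(partition) == 0L) return(integer(0))
  as.integer(table(factor(partition[partition > 0L],
                          levels = seq_len(max(partition)))))
}

#' Count unassigned genes
#'
#' @param partition A `module_partition`.
#' @return Number of genes with label 0.
#' @export
count_unassigned <- function(partition) {
  sum(partition == 0L)
}

#' Write / read a partition TSV
#'
#' Two columns, `gene_id` and `module` (0 = unassigned).
#'
#' @param partition A `module_partition`.
#' @param path File path.
#' @return `write_partition()`: `path`, invisibly; `read_partition()`: a
#'   `module_partition`.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(gene_id = names(partition), module = as.integer(partition),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("gene_id", "module") %in% names(df)),
         "partition TSV must have columns gene_id and module")
  a <- as.integer(df$module)
  names(a) <- as.character(df$gene_id)
  module_partition(.relabel_contiguous(a))
}

#' Read a multi-method cluster-assignment table
#'
#' Reads a TSV whose first column is the gene identifier and whose remaining
#' columns are cluster assignments by different methods (0 or empty =
#' unassigned), the layout used for published gene cluster-assignment
#' comparisons. Labels per column are re-coded to contiguous integers.
#'
#' @param path TSV file path.
#' @return Named list of `module_partition` objects, one per method column.
#' @export
read_partition_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .check(ncol(df) >= 2L, "partition table needs a gene column plus method columns")
  genes <- as.character(df[[1L]])
  out <- lapply(df[-1L], function(col) {
    lab <- as.character(col)
    lab[is.na(lab) | lab == "" | lab == "0"] <- NA
    codes <- as.integer(factor(lab))
    codes[is.na(codes)] <- 0L
    names(codes) <- genes
    module_partition(.relabel_contiguous(codes))
  })
  out
}

# re-code positive labels to contiguous 1..K keeping first-appearance order
.relabel_contiguous <- function(a) {
  pos <- a > 0L
  if (any(pos)) {
    a[pos] <- as.integer(factor(a[pos], levels = unique(a[pos])))
  }
  a
}

# relabel so module 1 is the largest, ties by previous label order
.order_by_size <- function(a) {
  if (!any(a > 0L)) return(a)
  sizes <- table(a[a > 0L])
  old <- as.integer(names(sizes))
  new_order <- old[order(-as.integer(sizes), old)]
  map <- integer(max(old))
  map[new_order] <- seq_along(new_order)
  a[a > 0L] <- map[a[a > 0L]]
  a
}
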