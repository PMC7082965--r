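# Feature selection: combining per-comparison differential-expression tables
# and applying the significance / fold-change filters that define the gene
# list entering network construction.
#
# A DE table is a data.frame with columns gene_id, log2_fc, p_value, fdr and
# a comparison label (one table per condition/timepoint contrast). Genes
# significant in several comparisons are collapsed to the row with the lowest
# FDR before filtering.

#' Construct a differential-expression table
#'
#' @param gene_id Character vector of gene identifiers (unique within a table).
#' @param log2_fc Numeric log2 fold changes.
#' @param p_value Numeric p-values in \\[0, 1\\].
#' @param fdr Numeric BH-adjusted p-values (FDR) in \\[0, 1\\].
#' @param comparison Single label naming the comparison (e.g. a timepoint).
#' @return A `de_table` data.frame with columns
#'   `gene_id`, `log2_fc`, `p_value`, `fdr`, `comparison`.
#' @export
de_table <- function(gene_id, log2_fc, p_value, fdr, comparison = "comparison") {
  df <- data.frame(gene_id = as.character(gene_id),
                   log2_fc = as.numeric(log2_fc),
                   p_value = as.numeric(p_value),
                   fdr = as.numeric(fdr),
                   comparison = as.character(comparison)[1L],
                   stringsAsFactors = FALSE)
  validate_de_table(df)
  class(df) <- c("de_table", "data.frame")
  df
}

#' @rdname de_table
#' @param x A data.frame to validate as a DE table.
#' @export
validate_de_table <- function(x) {
  need <- c("gene_id", "log2_fc", "p_value", "fdr")
  .check(is.data.frame(x) && all(need %in% names(x)),
         "DE table must have columns gene_id, log2_fc, p_value, fdr")
  .check(!anyDuplicated(x$gene_id),
         "duplicated gene_id within a DE table")
  .check(all(is.finite(x$fdr)) || nrow(x) == 0L, "non-finite FDR values in DE table")
  .check(all(is.finite(x$p_value)) || nrow(x) == 0L, "non-finite p-values in DE table")
  .check(nrow(x) == 0L || (min(x$fdr) >= 0 && max(x$fdr) <= 1),
         "FDR values must lie in [0, 1]")
  .check(nrow(x) == 0L || (min(x$p_value) >= 0 && max(x$p_value) <= 1),
         "p-values must lie in [0, 1]")
  .check(all(is.finite(x$log2_fc)) || nrow(x) == 0L, "non-finite log2 fold changes")
  invisible(x)
}

#' Read a differential-expression table from TSV
#'
#' Expects the header `gene_id  log2_fc  p_value  fdr`. The comparison label
#' is taken from `label`, or from the file name (without extension) when
#' `label` is `NULL`.
#'
#' @param path TSV file path.
#' @param label Optional comparison label.
#' @return A `de_table`.
#' @export
read_de_table <- function(path, label = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  de_table(df$gene_id, df$log2_fc, df$p_value, df$fdr, comparison = label)
}

#' Combine differential-expression tables across comparisons
#'
#' Collapses several per-comparison DE tables to one record per unique gene.
#' For a gene tested in multiple comparisons, the row with the lowest FDR is
#' kept (its log2 fold change and comparison label travel with it). Ties on
#' FDR are broken by the larger absolute log2 fold change, then by the
#' lexicographically smaller comparison label, so the result is deterministic.
#'
#' @param tables A list of `de_table` objects (at least one).
#' @return A data.frame of combined records with columns `gene_id`, `min_fdr`,
#'   `log2_fc` (the value at the minimizing row), `direction` (`"up"` when
#'   `log2_fc > 0`, else `"down"`), `comparison` (label of the minimizing
#'   row) and `n_comparisons` (number of tables containing the gene), sorted
#'   by gene identifier.
#' @export
combine_de_tables <- function(tables) {
  .check(is.list(tables) && length(tables) >= 1L && all(vapply(tables, is.data.frame, TRUE)),
         "`tables` must be a non-empty list of DE tables")
  for (t in tables) validate_de_table(t)
  all_rows <- do.call(rbind, lapply(tables, function(t) {
    data.frame(gene_id = t$gene_id, log2_fc = t$log2_fc, fdr = t$fdr,
               comparison = if ("comparison" %in% names(t)) t$comparison else "comparison",
               stringsAsFactors = FALSE)
  }))
  # deterministic pick of the minimum-FDR row per gene:
  # fdr ascending, then |log2_fc| descending, then comparison label ascending
  ord <- order(all_rows$gene_id, all_rows$fdr, -abs(all_rows$log2_fc),
               all_rows$comparison, method = "radix")
  all_rows <- all_rows[ord, , drop = FALSE]
  first <- !duplicated(all_rows$gene_id)
  n_cmp <- as.integer(table(all_rows$gene_id)[all_rows$gene_id[first]])
  out <- data.frame(gene_id = all_rows$gene_id[first],
                    min_fdr = all_rows$fdr[first],
                    log2_fc = all_rows$log2_fc[first],
                    direction = ifelse(all_rows$log2_fc[first] > 0, "up", "down"),
                    comparison = all_rows$comparison[first],
                    n_comparisons = n_cmp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter combined DE records on FDR and fold change
#'
#' Keeps genes with `min_fdr <= fdr_max` and `|log2_fc| >= min_abs_log2fc`.
#' The defaults are the stringent network-entry thresholds
#' (FDR \\eqn{\\le 10^{-5}}, fold change \\eqn{\\ge} 1.5, i.e.
#' \\eqn{|log_2 FC| \\ge 0.59}); both filters are applied symmetrically to
#' up- and down-regulated genes.
#'
#' @param records Combined records from [combine_de_tables()].
#' @param fdr_max Maximum FDR, in (0, 1].
#' @param min_abs_log2fc Minimum absolute log2 fold change, >= 0.
#' @return The filtered records, input order preserved.
#' @export
filter_de_genes <- function(records, fdr_max = 1e-5, min_abs_log2fc = 0.59) {
  .check(is.numeric(fdr_max) && length(fdr_max) == 1L && fdr_max > 0 && fdr_max <= 1,
         "`fdr_max` must be in (0, 1]")
  .check(is.numeric(min_abs_log2fc) && length(min_abs_log2fc) == 1L && min_abs_log2fc >= 0,
         "`min_abs_log2fc` must be >= 0")
  .check(is.data.frame(records) && all(c("gene_id", "min_fdr", "log2_fc") %in% names(records)),
         "`records` must come from combine_de_tables()")
  keep <- records$min_fdr <= fdr_max & abs(records$log2_fc) >= min_abs_log2fc
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-comparison counts of significant genes
#'
#' Applies the FDR and fold-change filters to each table separately and
#' tabulates totals and up/down-regulated counts, plus a `Sum` row, the form
#' in which per-timepoint DE results are usually reported.
#'
#' @inheritParams combine_de_tables
#' @inheritParams filter_de_genes
#' @return Data.frame with columns `comparison`, `total`, `up`, `down`;
#'   `total = up + down` in every row.
#' @export
summarize_de_counts <- function(tables, fdr_max = 0.05, min_abs_log2fc = 0.59) {
  .check(is.list(tables) && length(tables) >= 1L, "`tables` must be a non-empty list")
  rows <- lapply(tables, function(t) {
    validate_de_table(t)
    keep <- t$fdr <= fdr_max & abs(t$log2_fc) >= min_abs_log2fc
    up <- sum(keep & t$log2_fc > 0)
    down <- sum(keep & t$log2_fc <= 0)
    data.frame(comparison = if (nrow(t)) t$comparison[1L] else "comparison",
               total = up + down, up = up, down = down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(comparison = "Sum", total = sum(out$total),
                               up = sum(out$up), down = sum(out$down)))
  rownames(out) <- NULL
  out
}

#' Write combined DE records to TSV
#'
#' @param records Combined records from [combine_de_tables()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_combined_de <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
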