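# Partition comparison (Rand index) and the FDR-sweep cutoff selection.

#' Rand index between two gene partitions
#'
#' Pair-counting agreement between two partitions of the same genes:
#' \\eqn{RI = (a + b) / \\binom{n}{2}} with `a` the number of gene pairs
#' placed together in both partitions and `b` the number placed apart in
#' both. By default every unassigned gene is first converted to a cluster by
#' itself (a unique singleton label) in its partition — unassigned genes are
#' not similar to each other, so they must not count as one shared cluster.
#'
#' @param p1,p2 [module_partition()] objects (or named integer vectors,
#'   0 = unassigned) over identical gene sets.
#' @param unassigned_as_singletons Convert unassigned genes to singleton
#'   clusters before counting (default `TRUE`).
#' @return A list of class `rand_index_result`: `ri`, `n_items`,
#'   `agreements`, `pairs`, and the convenience `adjusted_ri`.
#' @export
rand_index <- function(p1, p2, unassigned_as_singletons = TRUE) {
  .check(!is.null(names(p1)) && !is.null(names(p2)),
         "partitions must be named by gene identifier")
  d1 <- setdiff(names(p1), names(p2))
  d2 <- setdiff(names(p2), names(p1))
  if (length(d1) || length(d2)) {
    stop("partitions cover different gene sets; only in first: ",
         paste(head(d1, 5L), collapse = ", "),
         "; only in second: ", paste(head(d2, 5L), collapse = ", "),
         call. = FALSE)
  }
  genes <- names(p1)
  l1 <- as.integer(p1)
  l2 <- as.integer(p2)[match(genes, names(p2))]
  if (unassigned_as_singletons) {
    u1 <- l1 == 0L
    l1[u1] <- max(l1) + seq_len(sum(u1))
    u2 <- l2 == 0L
    l2[u2] <- max(l2) + seq_len(sum(u2))
  } else {
    .check(all(l1 > 0L) && all(l2 > 0L),
           "unassigned genes present; set unassigned_as_singletons = TRUE")
  }
  n <- length(genes)
  .check(n >= 2L, "need at least two genes to compare partitions")
  pairs <- .n_pairs(n)
  nij <- as.numeric(table(paste(l1, l2, sep = "\r")))
  ai <- as.numeric(table(l1))
  bj <- as.numeric(table(l2))
  s_nij <- sum(.n_pairs(nij))
  s_a <- sum(.n_pairs(ai))
  s_b <- sum(.n_pairs(bj))
  agreements <- pairs + 2 * s_nij - s_a - s_b
  exp_idx <- s_a * s_b / pairs
  max_idx <- (s_a + s_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (s_nij - exp_idx) / (max_idx - exp_idx)
  structure(list(ri = agreements / pairs,
                 n_items = n,
                 agreements = agreements,
                 pairs = pairs,
                 adjusted_ri = ari),
            class = "rand_index_result")
}

#' @export
print.rand_index_result <- function(x, ...) {
  cat(sprintf("Rand index: %.4f (%d items, %g/%g agreeing pairs); adjusted: %.4f\n",
              x$ri, x$n_items, x$agreements, x$pairs, x$adjusted_ri))
  invisible(x)
}

#' Sweep the FDR cutoff and record module structure at each value
#'
#' For each candidate FDR cutoff: filters the combined DE records, builds the
#' co-expression network on the retained genes, detects modules, and records
#' the gene count, module count and median module size (over assigned modules
#' only; unassigned singletons are not clusters). The cutoff with the largest
#' median module size is marked as selected — small modules are hard to
#' interpret, so the sweep favors the cutoff producing the most substantial
#' modules.
#'
#' @param records Combined DE records from [combine_de_tables()].
#' @param expr Expression matrix covering all filtered genes.
#' @param cutoffs Numeric vector of FDR cutoffs.
#' @param min_abs_log2fc Fold-change filter applied alongside each cutoff.
#' @param beta Soft-threshold power or `"auto"` (see [build_network()]).
#' @param min_abs_cor Hard edge threshold on `|r|`.
#' @param objective Optimization objective for [detect_modules()].
#' @param min_module_size Passed to [detect_modules()].
#' @param seed Seed for module detection.
#' @return Data.frame with one row per cutoff: `fdr_cutoff`, `n_genes`,
#'   `n_modules`, `median_module_size`, `degenerate` (fewer than 3 genes or
#'   no edges at that cutoff), `selected`. Attribute `selected_cutoff` holds
#'   the winning cutoff.
#' @export
fdr_sweep <- function(records, expr, cutoffs, min_abs_log2fc = 0.59,
                      beta = "auto", min_abs_cor = 0.7,
                      objective = "density", min_module_size = 1L,
                      seed = 1L) {
  .check(is.numeric(cutoffs) && length(cutoffs) >= 1L && all(cutoffs > 0 & cutoffs <= 1),
         "`cutoffs` must be FDR values in (0, 1]")
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  rows <- lapply(cutoffs, function(cf) {
    sel <- filter_de_genes(records, fdr_max = cf, min_abs_log2fc = min_abs_log2fc)
    out <- data.frame(fdr_cutoff = cf, n_genes = nrow(sel),
                      n_modules = NA_integer_,
                      median_module_size = NA_real_, degenerate = TRUE)
    if (nrow(sel) < 3L) return(out)
    miss <- setdiff(sel$gene_id, rownames(expr))
    if (length(miss)) {
      stop("expression matrix is missing filtered genes: ",
           paste(head(miss, 10L), collapse = ", "), call. = FALSE)
    }
    g <- build_network(expr[sel$gene_id, , drop = FALSE],
                       beta = beta, min_abs_cor = min_abs_cor)
    if (nrow(g$edges) == 0L) return(out)
    det <- detect_modules(g, objective = objective, seed = seed,
                          min_module_size = min_module_size)
    out$n_modules <- det$n_modules
    out$median_module_size <- if (det$n_modules > 0L) {
      median(det$module_sizes)
    } else {
      NA_real_
    }
    out$degenerate <- FALSE
    out
  })
  tab <- do.call(rbind, rows)
  tab$selected <- FALSE
  ok <- which(!tab$degenerate & !is.na(tab$median_module_size))
  if (length(ok)) {
    best <- ok[which.max(tab$median_module_size[ok])]
    tab$selected[best] <- TRUE
    attr(tab, "selected_cutoff") <- tab$fdr_cutoff[best]
  }
  tab
}
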