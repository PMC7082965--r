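# Network construction: Pearson correlation, soft-threshold adjacency,
# scale-free topology fit for choosing the power, and hard edge thresholding.

#' Pearson correlation matrix of gene expression profiles
#'
#' Correlates every pair of gene rows across samples. Constant rows are
#' rejected (their correlation is undefined) with an error naming the genes.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @return Symmetric correlation matrix with unit diagonal, gene identifiers
#'   as dimnames.
#' @export
gene_correlation <- function(expr) {
  validate_expression(expr)
  r <- cor(t(expr), method = "pearson")
  # guard against round-off outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Raises absolute correlations to the power `beta`,
#' \\eqn{a_{ij} = |r_{ij}|^\\beta}, the unsigned weighted-network adjacency.
#' The diagonal is set to 0: the network has no self-loops and connectivity
#' sums exclude a gene's self-correlation.
#'
#' @param corr Symmetric correlation matrix (unit diagonal).
#' @param beta Soft-threshold power, an integer or real >= 1.
#' @return Adjacency matrix in \\[0, 1\\] with zero diagonal.
#' @export
soft_adjacency <- function(corr, beta) {
  .check(is.numeric(beta) && length(beta) == 1L && is.finite(beta) && beta >= 1,
         "`beta` must be a single number >= 1")
  .check(is.matrix(corr) && nrow(corr) == ncol(corr),
         "`corr` must be a square correlation matrix")
  a <- abs(corr)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a network's connectivity distribution
#'
#' Computes each node's connectivity \\eqn{k_i = \\sum_j a_{ij}}, bins the
#' connectivities into `n_bins` equal-width bins, and regresses
#' \\eqn{\\log_{10}}(frequency) on \\eqn{\\log_{10}}(mean connectivity) over
#' the non-empty bins. A high coefficient of determination with a negative
#' slope indicates an approximately scale-free (power-law) connectivity
#' distribution.
#'
#' @param adjacency Adjacency matrix (zero diagonal), or a precomputed numeric
#'   vector of connectivities.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return List with `r_squared`, `slope`, `n_bins_used` (non-empty bins with
#'   positive frequency), and the per-bin `k_mean` / `frequency` used in the
#'   regression.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10L) {
  k <- if (is.matrix(adjacency)) rowSums(adjacency) else as.numeric(adjacency)
  .check(length(k) >= 10L, "need at least 10 nodes for a scale-free fit")
  .check(n_bins >= 2L, "`n_bins` must be at least 2")
  if (diff(range(k)) == 0) {
    stop("degenerate connectivity distribution: all connectivities equal",
         call. = FALSE)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin))
  k_mean <- as.numeric(tapply(k, bin, mean))
  keep <- freq > 0 & !is.na(k_mean) & k_mean > 0
  .check(sum(keep) >= 3L, "fewer than 3 usable connectivity bins; cannot fit")
  x <- log10(k_mean[keep])
  y <- log10(freq[keep])
  # direct least-squares fit; R^2 computed from sums of squares so an exact
  # power law yields exactly 1 (no lm summary machinery)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fitted <- mean(y) + slope * (x - mean(x))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - fitted)^2) / sst
  list(r_squared = r2,
       slope = slope,
       n_bins_used = sum(keep),
       k_mean = k_mean[keep],
       frequency = freq[keep])
}

#' Choose the soft-threshold power by the scale-free topology criterion
#'
#' Evaluates the scale-free fit at each candidate power and returns the
#' smallest one whose \\eqn{R^2} reaches `target_r2`. If no candidate
#' reaches the target, the power with the maximal \\eqn{R^2} is returned and
#' flagged (`met_target = FALSE`) rather than failing, so a user can inspect
#' the fit table and decide.
#'
#' @param corr Correlation matrix from [gene_correlation()].
#' @param powers Candidate integer powers (default 1:20).
#' @param target_r2 Required fit \\eqn{R^2} (default 0.9).
#' @param n_bins Bins for [scale_free_fit()].
#' @return List with `beta`, `r_squared`, `slope`, `met_target`, and a
#'   data.frame `fit_table` (one row per candidate power).
#' @export
pick_soft_threshold <- function(corr, powers = 1:20, target_r2 = 0.9, n_bins = 10L) {
  .check(length(powers) >= 1L && all(powers >= 1), "`powers` must be positive")
  .check(is.numeric(target_r2) && target_r2 > 0 && target_r2 < 1,
         "`target_r2` must be in (0, 1)")
  powers <- sort(unique(as.integer(powers)))
  rows <- lapply(powers, function(b) {
    f <- tryCatch(scale_free_fit(soft_adjacency(corr, b), n_bins = n_bins),
                  error = function(e) list(r_squared = NA_real_, slope = NA_real_))
    data.frame(power = b, r_squared = f$r_squared, slope = f$slope)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r_squared) & tab$r_squared >= target_r2)
  if (length(ok)) {
    i <- ok[1L]
    met <- TRUE
  } else {
    .check(any(!is.na(tab$r_squared)), "scale-free fit failed for every candidate power")
    i <- which.max(tab$r_squared)
    met <- FALSE
  }
  list(beta = tab$power[i], r_squared = tab$r_squared[i], slope = tab$slope[i],
       met_target = met, fit_table = tab)
}

#' Hard-threshold the correlation network into a graph
#'
#' Keeps gene pairs with \\eqn{|r_{ij}| \\ge} `min_abs_cor` as edges; each
#' retained edge carries the raw correlation and the soft-threshold adjacency
#' weight. Genes with no retained edge remain in the node set as isolated
#' nodes (they become the unassigned genes downstream).
#'
#' @param corr Correlation matrix.
#' @param adjacency Matching adjacency matrix from [soft_adjacency()].
#' @param min_abs_cor Hard threshold on `|r|`, in (0, 1). Default 0.7.
#' @param beta The power used for `adjacency` (recorded on the graph).
#' @return A [coexpression_graph()].
#' @export
threshold_network <- function(corr, adjacency, min_abs_cor = 0.7, beta = NA_real_) {
  .check(is.numeric(min_abs_cor) && length(min_abs_cor) == 1L &&
           min_abs_cor > 0 && min_abs_cor < 1,
         "`min_abs_cor` must be in (0, 1)")
  .check(all(dim(corr) == dim(adjacency)), "corr and adjacency dimensions differ")
  genes <- rownames(corr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(corr)))
  keep <- which(abs(corr) >= min_abs_cor & upper.tri(corr), arr.ind = TRUE)
  edges <- data.frame(from = genes[keep[, 1L]],
                      to = genes[keep[, 2L]],
                      correlation = corr[keep],
                      weight = adjacency[keep],
                      stringsAsFactors = FALSE)
  coexpression_graph(genes, edges, beta = beta, min_abs_cor = min_abs_cor)
}

#' Build the thresholded co-expression network from expression data
#'
#' Convenience wrapper running correlation, soft-threshold power selection
#' (or a fixed power), adjacency and hard edge thresholding in one call.
#'
#' @param expr Expression matrix (genes x samples).
#' @param beta Fixed soft-threshold power, or `"auto"` to choose it with
#'   [pick_soft_threshold()].
#' @param min_abs_cor Hard threshold on `|r|` (default 0.7).
#' @param powers,target_r2 Passed to [pick_soft_threshold()] when
#'   `beta = "auto"`.
#' @return A `coexpression_graph`; the chosen power and, when auto-selected,
#'   the full fit are attached as attributes `beta` and `soft_threshold_fit`.
#' @export
build_network <- function(expr, beta = "auto", min_abs_cor = 0.7,
                          powers = 1:20, target_r2 = 0.9) {
  corr <- gene_correlation(expr)
  fit <- NULL
  if (identical(beta, "auto")) {
    fit <- pick_soft_threshold(corr, powers = powers, target_r2 = target_r2)
    beta <- fit$beta
  }
  adj <- soft_adjacency(corr, beta)
  g <- threshold_network(corr, adj, min_abs_cor = min_abs_cor, beta = beta)
  if (!is.null(fit)) attr(g, "soft_threshold_fit") <- fit
  g
}
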