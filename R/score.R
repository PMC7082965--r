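# Partition quality scores: weighted Newman modularity Q and modularity
# density Qds. These are independent R implementations used for reporting;
# the compiled optimizer tracks the same objectives internally and the two
# are cross-checked in the test suite.

# Per-community aggregates for a scored partition. Unassigned genes (label 0)
# are treated as singleton communities. Returns the community weight matrix
# M (M[c,c] = internal edge weight, off-diagonal = inter-community weight),
# community sizes, and total edge weight W.
.community_aggregates <- function(graph, partition) {
  .check(inherits(graph, "coexpression_graph"), "`graph` must be a coexpression_graph")
  miss <- setdiff(graph$nodes, names(partition))
  if (length(miss)) {
    stop("partition is missing graph nodes: ",
         paste(head(miss, 10L), collapse = ", "), call. = FALSE)
  }
  lab <- as.integer(partition[graph$nodes])
  k0 <- max(lab, 0L)
  una <- which(lab == 0L)
  lab[una] <- k0 + seq_along(una)   # unassigned -> unique singleton labels
  K <- max(lab)
  sizes <- tabulate(lab, nbins = K)
  M <- matrix(0, K, K)
  e <- graph$edges
  if (nrow(e)) {
    ci <- lab[match(e$from, graph$nodes)]
    cj <- lab[match(e$to, graph$nodes)]
    lo <- pmin(ci, cj)
    hi <- pmax(ci, cj)
    agg <- rowsum(e$weight, group = (lo - 1L) * K + hi)
    idx <- as.integer(rownames(agg))
    r <- (idx - 1L) %/% K + 1L
    c <- (idx - 1L) %% K + 1L
    M[cbind(r, c)] <- M[cbind(r, c)] + agg[, 1L]
    off <- r != c
    M[cbind(c[off], r[off])] <- M[cbind(r[off], c[off])]
  }
  list(M = M, sizes = sizes, W = sum(e$weight), K = K)
}

#' Weighted Newman modularity of a partition
#'
#' Computes
#' \\eqn{Q = \\sum_c \\left( W^{in}_c / W - (S_c / 2W)^2 \\right)}
#' where \\eqn{W^{in}_c} is the internal edge weight of community c,
#' \\eqn{S_c} its total strength and \\eqn{W} the total edge weight —
#' equivalently \\eqn{(1/2W)\\sum_{ij}(A_{ij} - s_i s_j/2W)\\,\\delta(c_i,c_j)}.
#' Unassigned genes score as singleton communities.
#'
#' @param graph A [coexpression_graph()] (edge weights are the soft-threshold
#'   adjacency).
#' @param partition A [module_partition()] covering every graph node.
#' @return The modularity Q (a real number \\eqn{\\le 1}).
#' @export
modularity_score <- function(graph, partition) {
  ag <- .community_aggregates(graph, partition)
  .check(ag$W > 0, "graph has no edges; modularity undefined")
  win <- diag(ag$M)
  strength <- 2 * win + (rowSums(ag$M) - win)
  sum(win / ag$W - (strength / (2 * ag$W))^2)
}

#' Modularity density of a partition
#'
#' A density-weighted variant of modularity with an explicit split penalty,
#' designed to overcome the resolution limit of plain modularity. With
#' internal density \\eqn{d_c = 2W^{in}_c / (n_c (n_c - 1))} (defined as 0
#' for singletons) and pair density
#' \\eqn{d_{cc'} = W_{cc'} / (n_c n_{c'})}, each community contributes
#' \\deqn{\\frac{W^{in}_c}{W} d_c
#'   - \\left( \\frac{2W^{in}_c + W^{out}_c}{2W} d_c \\right)^2
#'   - \\sum_{c' \\ne c} \\frac{W_{cc'}}{2W} d_{cc'}}
#' with edge weights in place of edge counts throughout. Unassigned genes
#' score as singleton communities.
#'
#' @inheritParams modularity_score
#' @return The modularity density Qds.
#' @export
modularity_density <- function(graph, partition) {
  ag <- .community_aggregates(graph, partition)
  .check(ag$W > 0, "graph has no edges; modularity density undefined")
  M <- ag$M
  n <- ag$sizes
  W <- ag$W
  win <- diag(M)
  wout <- rowSums(M) - win
  d <- ifelse(n > 1, 2 * win / (n * (n - 1)), 0)
  term1 <- (win / W) * d
  term2 <- ((2 * win + wout) / (2 * W) * d)^2
  Moff <- M
  diag(Moff) <- 0
  pair_pen <- (Moff / (2 * W)) * (Moff / outer(n, n))
  sum(term1 - term2) - sum(pair_pen)
}
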