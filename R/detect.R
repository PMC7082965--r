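# Module detection on the thresholded weighted network.

#' Detect modules by greedy modularity / modularity-density maximization
#'
#' Runs the compiled optimizer on the non-isolated part of the graph: every
#' node starts as its own community, connected community pairs are merged
#' greedily on the largest positive objective gain, and the result is
#' fine-tuned by single-node moves (including extraction to a fresh
#' singleton) until no step improves the objective by more than `eps`.
#' Isolated nodes never enter the optimization and are returned as
#' unassigned. The standard weighted modularity Q of the final partition is
#' always reported alongside the optimized objective.
#'
#' @param graph A [coexpression_graph()] with at least one edge.
#' @param objective `"density"` (modularity density, the default) or
#'   `"modularity"` (plain weighted Q).
#' @param seed Integer seed controlling the optional randomized restarts.
#' @param n_restarts Number of restarts; the first is deterministic, further
#'   ones relabel nodes at random and the best local optimum is kept.
#'   Default 1 (fully deterministic).
#' @param min_module_size Communities smaller than this are demoted to
#'   unassigned by [finalize_partition()]. Default 1 (no effect).
#' @param eps Convergence tolerance on objective gains.
#' @return A list of class `module_detection`: `partition`
#'   (a [module_partition()], modules ordered by decreasing size),
#'   `objective` (name), `objective_value` (value reached by the optimizer),
#'   `q` and `qds` (both scores of the final partition), `n_modules`,
#'   `n_unassigned`, `module_sizes`.
#' @export
detect_modules <- function(graph, objective = c("density", "modularity"),
                           seed = 1L, n_restarts = 1L,
                           min_module_size = 1L, eps = 1e-12) {
  objective <- match.arg(objective)
  .check(inherits(graph, "coexpression_graph"), "`graph` must be a coexpression_graph")
  .check(length(graph$nodes) > 0L, "empty graph")
  .check(nrow(graph$edges) > 0L, "graph has no edges; nothing to cluster")
  iso <- isolated_nodes(graph)
  connected <- setdiff(graph$nodes, iso)
  A <- graph_adjacency(graph, connected)
  res <- with_seed(seed, .cpp_maximize(A, objective == "density",
                                       eps, as.integer(n_restarts)))
  assignment <- integer(length(graph$nodes))
  names(assignment) <- graph$nodes
  assignment[connected] <- res$assignment
  partition <- finalize_partition(module_partition(.relabel_contiguous(assignment)),
                                  graph, min_module_size = min_module_size)
  q <- modularity_score(graph, partition)
  qds <- modularity_density(graph, partition)
  structure(list(partition = partition,
                 objective = objective,
                 objective_value = res$objective,
                 q = q,
                 qds = qds,
                 n_modules = n_modules(partition),
                 n_unassigned = count_unassigned(partition),
                 module_sizes = module_sizes(partition)),
            class = "module_detection")
}

#' @export
print.module_detection <- function(x, ...) {
  cat(sprintf("Module detection (%s objective)\n", x$objective))
  cat(sprintf("  %d modules, %d unassigned genes\n", x$n_modules, x$n_unassigned))
  cat(sprintf("  Q = %.4f, Qds = %.4f\n", x$q, x$qds))
  invisible(x)
}

#' Finalize a partition: unassigned convention and label ordering
#'
#' Demotes isolated nodes and members of communities smaller than
#' `min_module_size` to unassigned (label 0), then re-compacts labels so
#' module 1 is the largest.
#'
#' @param partition A [module_partition()].
#' @param graph The graph the partition lives on (isolated nodes are read
#'   from it).
#' @param min_module_size Minimum community size to keep as a module.
#' @return A `module_partition`.
#' @export
finalize_partition <- function(partition, graph, min_module_size = 1L) {
  a <- as.integer(partition)
  names(a) <- names(partition)
  a[names(a) %in% isolated_nodes(graph)] <- 0L
  if (min_module_size > 1L && any(a > 0L)) {
    sizes <- table(a[a > 0L])
    small <- as.integer(names(sizes)[sizes < min_module_size])
    a[a %in% small] <- 0L
  }
  a <- .order_by_size(.relabel_contiguous(a))
  module_partition(a)
}
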