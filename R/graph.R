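# The thresholded weighted co-expression graph and its I/O.

#' Construct a co-expression graph
#'
#' A lightweight container for the thresholded weighted network: all genes as
#' nodes (genes whose every correlation fell below the edge threshold stay in
#' the node set as isolated nodes) and an edge table carrying both the raw
#' Pearson correlation and the soft-threshold adjacency weight
#' \\eqn{a_{ij} = |r_{ij}|^\\beta} of each retained pair.
#'
#' @param nodes Character vector of gene identifiers.
#' @param edges Data.frame with columns `from`, `to` (gene identifiers),
#'   `correlation` and `weight` (adjacency). No self-loops, no duplicate pairs.
#' @param beta Soft-threshold power used to compute the weights (or `NA`).
#' @param min_abs_cor Hard correlation threshold applied to the edges (or `NA`).
#' @return An object of class `coexpression_graph`.
#' @export
coexpression_graph <- function(nodes, edges, beta = NA_real_, min_abs_cor = NA_real_) {
  nodes <- as.character(nodes)
  .check(!anyDuplicated(nodes), "duplicated node identifiers")
  .check(is.data.frame(edges) &&
           all(c("from", "to", "correlation", "weight") %in% names(edges)),
         "edges must have columns from, to, correlation, weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  .check(all(edges$from %in% nodes) && all(edges$to %in% nodes),
         "edge endpoints must be graph nodes")
  .check(!any(edges$from == edges$to), "self-loops are not allowed")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  .check(!anyDuplicated(key), "duplicate edges")
  .check(nrow(edges) == 0L || all(edges$weight > 0 & edges$weight <= 1),
         "adjacency weights must lie in (0, 1]")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 beta = beta, min_abs_cor = min_abs_cor),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  iso <- sum(!(x$nodes %in% c(x$edges$from, x$edges$to)))
  cat(sprintf("Co-expression graph: %d nodes, %d edges (%d isolated)\n",
              length(x$nodes), nrow(x$edges), iso))
  if (!is.na(x$beta)) cat(sprintf("  soft-threshold power beta = %g\n", x$beta))
  if (!is.na(x$min_abs_cor)) cat(sprintf("  edge filter |r| >= %g\n", x$min_abs_cor))
  invisible(x)
}

#' Number of edges / total edge weight of a co-expression graph
#'
#' @param graph A `coexpression_graph`.
#' @return `graph_edge_count()`: integer edge count; `graph_total_weight()`:
#'   the sum of adjacency weights over edges.
#' @export
graph_edge_count <- function(graph) nrow(graph$edges)

#' @rdname graph_edge_count
#' @export
graph_total_weight <- function(graph) sum(graph$edges$weight)

#' Identify isolated nodes
#'
#' @param graph A `coexpression_graph`.
#' @return Character vector of nodes incident to no edge. These are the genes
#'   the pipeline reports as unassigned.
#' @export
isolated_nodes <- function(graph) {
  graph$nodes[!(graph$nodes %in% c(graph$edges$from, graph$edges$to))]
}

#' Dense weighted adjacency matrix of a graph
#'
#' @param graph A `coexpression_graph`.
#' @param nodes Optional subset/order of nodes (default: all graph nodes).
#' @return Symmetric numeric matrix of adjacency weights with zero diagonal.
#' @export
graph_adjacency <- function(graph, nodes = graph$nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    keep <- !is.na(i) & !is.na(j)
    A[cbind(i[keep], j[keep])] <- graph$edges$weight[keep]
    A[cbind(j[keep], i[keep])] <- graph$edges$weight[keep]
  }
  A
}

#' Convert to an igraph object
#'
#' Edge attribute `weight` is the soft-threshold adjacency, `correlation` the
#' raw Pearson correlation.
#'
#' @param graph A `coexpression_graph`.
#' @return An [igraph::graph] object including isolated vertices.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "weight", "correlation")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' Write / read a weighted edge list
#'
#' TSV with header `gene_a  gene_b  correlation  adjacency`. Isolated nodes
#' are not representable in an edge list, so `read_edge_list()` accepts an
#' optional full node vector to restore them.
#'
#' @param graph A `coexpression_graph`.
#' @param path File path.
#' @return `write_edge_list()`: `path`, invisibly. `read_edge_list()`: a
#'   `coexpression_graph`.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(gene_a = graph$edges$from, gene_b = graph$edges$to,
                   correlation = graph$edges$correlation,
                   adjacency = graph$edges$weight, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes Optional character vector of all node identifiers (to restore
#'   isolated nodes absent from the edge list).
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(df$gene_a), to = as.character(df$gene_b),
                      correlation = df$correlation, weight = df$adjacency,
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  coexpression_graph(union(nodes, c(edges$from, edges$to)), edges)
}

#' Export a graph to GraphML
#'
#' Writes GraphML with `weight` (adjacency) and `correlation` edge attributes.
#'
#' @param graph A `coexpression_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
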