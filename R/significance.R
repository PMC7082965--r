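# Permutation test for the significance of the modular structure.

#' Randomly rewire a network, preserving edge count and weight multiset
#'
#' The default null model draws, for each permutation, the same number of
#' edges uniformly at random among all distinct unordered node pairs (no
#' self-loops, no duplicates) and reassigns the observed edge
#' weight/correlation pairs to the new edges in shuffled order. Edge count
#' and the multiset of edge weights are conserved exactly; the degree
#' distribution is not (uniform rewiring randomizes it).
#'
#' `method = "degree"` instead performs double-edge swaps (endpoint exchanges
#' between two random edges, rejected when they would create a self-loop or
#' duplicate edge), which additionally preserves each node's edge count.
#'
#' Uses the current RNG stream; seed with [set.seed()] or via the `seed`
#' argument of [module_significance()].
#'
#' @param graph A [coexpression_graph()] with at least one edge.
#' @param method `"uniform"` (default) or `"degree"`.
#' @param n_swaps For `"degree"`: number of attempted swaps (default 10 per
#'   edge).
#' @return A `coexpression_graph` on the same node set.
#' @export
permute_network <- function(graph, method = c("uniform", "degree"),
                            n_swaps = NULL) {
  method <- match.arg(method)
  e <- graph$edges
  .check(nrow(e) >= 1L, "graph has no edges to permute")
  nodes <- graph$nodes
  n <- length(nodes)
  if (method == "uniform") {
    .check(nrow(e) <= .n_pairs(n), "more edges than node pairs")
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- ut[sample.int(nrow(ut), nrow(e)), , drop = FALSE]
    ord <- sample.int(nrow(e))
    new_edges <- data.frame(from = nodes[pick[, 1L]],
                            to = nodes[pick[, 2L]],
                            correlation = e$correlation[ord],
                            weight = e$weight[ord],
                            stringsAsFactors = FALSE)
  } else {
    if (is.null(n_swaps)) n_swaps <- 10L * nrow(e)
    a <- match(e$from, nodes)
    b <- match(e$to, nodes)
    key <- function(x, y) pmin(x, y) * (n + 1) + pmax(x, y)
    have <- new.env(hash = TRUE)
    for (k in key(a, b)) assign(as.character(k), TRUE, envir = have)
    m <- nrow(e)
    for (s in seq_len(n_swaps)) {
      ij <- sample.int(m, 2L)
      i <- ij[1L]; j <- ij[2L]
      # exchange one endpoint of each edge
      na1 <- a[i]; nb1 <- b[i]; na2 <- a[j]; nb2 <- b[j]
      if (runif(1L) < 0.5) {
        p1 <- c(na1, nb2); p2 <- c(na2, nb1)
      } else {
        p1 <- c(na1, na2); p2 <- c(nb1, nb2)
      }
      if (p1[1L] == p1[2L] || p2[1L] == p2[2L]) next
      k1 <- as.character(key(p1[1L], p1[2L]))
      k2 <- as.character(key(p2[1L], p2[2L]))
      if (k1 == k2 || exists(k1, envir = have) || exists(k2, envir = have)) next
      rm(list = c(as.character(key(na1, nb1)), as.character(key(na2, nb2))),
         envir = have)
      assign(k1, TRUE, envir = have)
      assign(k2, TRUE, envir = have)
      a[i] <- p1[1L]; b[i] <- p1[2L]
      a[j] <- p2[1L]; b[j] <- p2[2L]
    }
    new_edges <- data.frame(from = nodes[pmin(a, b)], to = nodes[pmax(a, b)],
                            correlation = e$correlation, weight = e$weight,
                            stringsAsFactors = FALSE)
  }
  coexpression_graph(nodes, new_edges, beta = graph$beta,
                     min_abs_cor = graph$min_abs_cor)
}

#' Permutation z-score for the observed modular structure
#'
#' Clusters the observed network, then reclusters `n_permutations` randomly
#' rewired networks (same edge count and weight multiset) and summarizes how
#' far the observed modularity lies above the permutation null:
#' \\eqn{z = (Q_{obs} - \\bar{Q}_{null}) / sd(Q_{null})}. The statistic
#' compared is always the standard weighted modularity Q of each network's
#' maximized partition, regardless of which objective drives the optimizer.
#'
#' @param graph A [coexpression_graph()].
#' @param n_permutations Number of network permutations (default 1000).
#' @param objective Optimization objective, as in [detect_modules()].
#' @param seed Integer seed for the whole procedure.
#' @param null_model `"uniform"` (default) or `"degree"`, see
#'   [permute_network()].
#' @param min_module_size Passed to [detect_modules()].
#' @return A list of class `null_summary`: `n_permutations`, `q_observed`,
#'   `q_null_mean`, `q_null_sd`, `z_score`, `seed`, `objective`,
#'   `null_model`, `degenerate` (`TRUE` when all permuted Q are identical,
#'   in which case `z_score` is `NA`), and the vector `q_null`.
#' @export
module_significance <- function(graph, n_permutations = 1000L,
                                objective = c("density", "modularity"),
                                seed = 1L,
                                null_model = c("uniform", "degree"),
                                min_module_size = 1L) {
  objective <- match.arg(objective)
  null_model <- match.arg(null_model)
  .check(n_permutations >= 2L, "need at least 2 permutations")
  obs <- detect_modules(graph, objective = objective, seed = NULL,
                        min_module_size = min_module_size)
  q_null <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    gp <- permute_network(graph, method = null_model)
    detect_modules(gp, objective = objective, seed = NULL,
                   min_module_size = min_module_size)$q
  }, numeric(1L)))
  m <- mean(q_null)
  s <- sd(q_null)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    warning("degenerate permutation null: all permuted modularities identical",
            call. = FALSE)
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 q_observed = obs$q,
                 q_null_mean = m,
                 q_null_sd = s,
                 z_score = if (degenerate) NA_real_ else (obs$q - m) / s,
                 seed = seed,
                 objective = objective,
                 null_model = null_model,
                 degenerate = degenerate,
                 q_null = q_null,
                 observed = obs),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %s null)\n",
              x$n_permutations, x$null_model))
  cat(sprintf("  observed Q = %.4f, null mean = %.4f, null sd = %.4g\n",
              x$q_observed, x$q_null_mean, x$q_null_sd))
  cat(sprintf("  z-score = %.2f\n", x$z_score))
  invisible(x)
}
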