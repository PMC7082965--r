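# Shared fixtures and independent oracles used across the test files.
# Everything here is deliberately written by the most direct route available
# (explicit loops over the defining formulas, full enumeration) so it stays
# independent of the package's vectorized / compiled implementations.

# all set partitions of n items as label vectors (restricted growth strings)
partitions_of <- function(n) {
  out <- list()
  rec <- function(a, i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      a[i] <- v
      rec(a, i + 1L, max(mx, v))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# brute-force weighted Newman modularity by the defining double sum
brute_modularity <- function(A, lab) {
  twoW <- sum(A)
  s <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (lab[i] == lab[j]) {
        q <- q + A[i, j] - s[i] * s[j] / twoW
      }
    }
  }
  q / twoW
}

# brute-force modularity density, community by community from the definition
brute_modularity_density <- function(A, lab) {
  W <- sum(A) / 2
  twoW <- sum(A)
  q <- 0
  for (c in unique(lab)) {
    idx <- which(lab == c)
    nc <- length(idx)
    win <- sum(A[idx, idx]) / 2
    wout <- sum(A[idx, -idx, drop = FALSE])
    d <- if (nc > 1) 2 * win / (nc * (nc - 1)) else 0
    t1 <- win / W * d
    t2 <- ((2 * win + wout) / twoW * d)^2
    t3 <- 0
    for (cc in setdiff(unique(lab), c)) {
      jdx <- which(lab == cc)
      wcc <- sum(A[idx, jdx])
      t3 <- t3 + (wcc / twoW) * (wcc / (nc * length(jdx)))
    }
    q <- q + t1 - t2 - t3
  }
  q
}

# Rand index by explicit enumeration of all item pairs
brute_rand_index <- function(l1, l2) {
  n <- length(l1)
  agree <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      together1 <- l1[i] == l1[j]
      together2 <- l2[i] == l2[j]
      if (together1 == together2) agree <- agree + 1
    }
  }
  agree / (n * (n - 1) / 2)
}

# random symmetric weighted adjacency on n nodes (zero diagonal)
random_adjacency <- function(n, p_edge = 0.55) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        A[i, j] <- A[j, i] <- round(runif(1, 0.1, 1), 3)
      }
    }
  }
  A
}

# coexpression_graph from a weighted adjacency matrix
graph_from_adjacency <- function(A, nodes = paste0("n", seq_len(nrow(A)))) {
  idx <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  coexpression_graph(nodes,
                     data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                                correlation = A[idx], weight = A[idx],
                                stringsAsFactors = FALSE))
}

# canonical fixture: two disjoint unit-weight triangles on 6 nodes
two_triangles <- function() {
  nodes <- letters[1:6]
  coexpression_graph(nodes, data.frame(
    from = c("a", "a", "b", "d", "d", "e"),
    to = c("b", "c", "c", "e", "f", "f"),
    correlation = 1, weight = 1, stringsAsFactors = FALSE))
}

# small DE-table fixture builder
make_de_table <- function(genes, lfc, fdr, label, p = fdr) {
  de_table(genes, lfc, pmin(p, 1), fdr, comparison = label)
}
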