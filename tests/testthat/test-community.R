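test_that("modularity of canonical partitions matches hand evaluation", {
  g <- two_triangles()
  nodes <- g$nodes
  one <- module_partition(stats::setNames(rep(1L, 6), nodes))
  expect_equal(modularity_score(g, one), 0)           # whole graph: 1 - 1

  comp <- module_partition(stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), nodes))
  expect_equal(modularity_score(g, comp), 0.5)        # 2 x (3/6 - (6/12)^2)

  singletons <- module_partition(stats::setNames(1:6, nodes))
  expect_lt(modularity_score(g, singletons), 0)       # -sum (s_i/2w)^2
})

test_that("modularity density of canonical partitions matches the formula", {
  g <- two_triangles()
  comp <- module_partition(stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), g$nodes))
  expect_equal(modularity_density(g, comp), 0.5)      # densities 1, no split penalty

  # one community covering a clique: (W/W)*1 - (1*1)^2 = 0
  k4 <- graph_from_adjacency(matrix(1, 4, 4) - diag(4))
  one <- module_partition(stats::setNames(rep(1L, 4), k4$nodes))
  expect_equal(modularity_density(k4, one), 0)
})

test_that("both scores agree with brute-force oracles over random partitions", {
  set.seed(407)
  n_cases <- 0
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    A <- random_adjacency(n)
    if (sum(A) == 0) next
    g <- graph_from_adjacency(A)
    parts <- partitions_of(n)
    for (lab in parts[sample.int(length(parts), min(12, length(parts)))]) {
      p <- module_partition(stats::setNames(as.integer(lab), g$nodes))
      expect_equal(modularity_score(g, p), brute_modularity(A, lab),
                   tolerance = 1e-12)
      expect_equal(modularity_density(g, p), brute_modularity_density(A, lab),
                   tolerance = 1e-12)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 300)
})

test_that("modularity agrees with igraph on weighted graphs", {
  set.seed(408)
  for (rep in 1:5) {
    A <- random_adjacency(8)
    if (sum(A) == 0) next
    g <- graph_from_adjacency(A)
    lab <- sample(1:3, 8, replace = TRUE)
    lab <- as.integer(factor(lab))   # contiguous
    p <- module_partition(stats::setNames(lab, g$nodes))
    ig <- as_igraph(g)
    expect_equal(modularity_score(g, p),
                 igraph::modularity(ig, lab[match(igraph::V(ig)$name, g$nodes)],
                                    weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("scoring rejects partitions missing graph nodes", {
  g <- two_triangles()
  partial <- module_partition(stats::setNames(c(1L, 1L, 1L), c("a", "b", "c")))
  expect_error(modularity_score(g, partial), "missing")
})

test_that("detection recovers the components of two disjoint triangles", {
  g <- two_triangles()
  for (obj in c("density", "modularity")) {
    det <- detect_modules(g, objective = obj)
    expect_equal(det$n_modules, 2L)
    expect_equal(det$q, 0.5)
    expect_equal(det$qds, 0.5)
    expect_equal(unname(module_sizes(det$partition)), c(3L, 3L))
    # members of one triangle share a label
    p <- det$partition
    expect_equal(length(unique(p[c("a", "b", "c")])), 1L)
    expect_equal(length(unique(p[c("d", "e", "f")])), 1L)
  }
})

test_that("a single edge is clustered as one community (Q = 0 beats negative)", {
  g <- coexpression_graph(c("x", "y"),
                          data.frame(from = "x", to = "y",
                                     correlation = 0.9, weight = 0.9^6))
  det <- detect_modules(g)
  expect_equal(det$n_modules, 1L)
  expect_equal(det$q, 0)
})

test_that("detection reaches the exhaustive optimum on small graphs", {
  set.seed(409)
  checked <- 0
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    A <- random_adjacency(n)
    if (sum(A) == 0) next
    g <- graph_from_adjacency(A)
    conn <- which(rowSums(A) > 0)
    iso <- setdiff(seq_len(n), conn)
    parts <- partitions_of(length(conn))
    # isolated nodes are unassigned by construction: enumerate them as
    # fixed singletons, matching the optimizer's domain
    full <- lapply(parts, function(p) {
      lab <- integer(n)
      lab[conn] <- p
      lab[iso] <- max(p) + seq_along(iso)
      lab
    })
    for (obj in c("density", "modularity")) {
      oracle <- if (obj == "density") brute_modularity_density else brute_modularity
      best <- max(vapply(full, function(p) oracle(A, p), numeric(1)))
      det <- detect_modules(g, objective = obj, seed = 1, n_restarts = 8)
      got <- if (obj == "density") det$qds else det$q
      expect_equal(got, best, tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 16)
})

test_that("the found partition beats both trivial partitions", {
  set.seed(410)
  for (rep in 1:5) {
    A <- random_adjacency(10, p_edge = 0.4)
    if (sum(A) == 0) next
    g <- graph_from_adjacency(A)
    det <- detect_modules(g, objective = "modularity")
    nodes <- g$nodes
    one <- module_partition(stats::setNames(rep(1L, 10), nodes))
    single <- module_partition(stats::setNames(1:10, nodes))
    expect_gte(det$q, modularity_score(g, one) - 1e-12)
    expect_gte(det$q, modularity_score(g, single) - 1e-12)
  }
})

test_that("detection is equivariant under node relabeling", {
  set.seed(411)
  A <- random_adjacency(12, p_edge = 0.45)
  g <- graph_from_adjacency(A)
  det1 <- detect_modules(g)
  perm <- sample(12)
  g2 <- graph_from_adjacency(A[perm, perm], nodes = g$nodes[perm])
  det2 <- detect_modules(g2)
  expect_equal(det1$qds, det2$qds, tolerance = 1e-12)
  ri <- rand_index(det1$partition, det2$partition)
  expect_equal(ri$ri, 1)
})

test_that("no community spans two components under the modularity objective", {
  set.seed(412)
  A <- matrix(0, 12, 12)
  A[1:6, 1:6] <- random_adjacency(6, p_edge = 0.7)
  A[7:12, 7:12] <- random_adjacency(6, p_edge = 0.7)
  g <- graph_from_adjacency(A)
  det <- detect_modules(g, objective = "modularity")
  p <- det$partition
  left <- unique(p[g$nodes[1:6]][p[g$nodes[1:6]] > 0])
  right <- unique(p[g$nodes[7:12]][p[g$nodes[7:12]] > 0])
  expect_length(intersect(left, right), 0)
})

test_that("reported objective value matches the R scoring of the partition", {
  set.seed(413)
  A <- random_adjacency(15, p_edge = 0.3)
  g <- graph_from_adjacency(A)
  for (obj in c("density", "modularity")) {
    det <- detect_modules(g, objective = obj)
    score <- if (obj == "density") modularity_density(g, det$partition) else
      modularity_score(g, det$partition)
    expect_equal(det$objective_value, score, tolerance = 1e-9)
  }
})

test_that("finalize demotes isolated nodes and small modules, ordering by size", {
  nodes <- paste0("g", 1:9)
  edges <- data.frame(from = c("g1", "g1", "g2", "g4", "g6"),
                      to = c("g2", "g3", "g3", "g5", "g7"),
                      correlation = 1, weight = 1)
  g <- coexpression_graph(nodes, edges)   # g8, g9 isolated
  raw <- module_partition(stats::setNames(c(2L, 2L, 2L, 1L, 1L, 3L, 3L, 4L, 5L), nodes))
  fin <- finalize_partition(raw, g)
  expect_equal(count_unassigned(fin), 2L)
  expect_setequal(names(fin)[fin == 0L], c("g8", "g9"))
  expect_equal(unname(fin[c("g1", "g2", "g3")]), rep(1L, 3))  # largest is module 1

  fin2 <- finalize_partition(raw, g, min_module_size = 3)
  expect_equal(n_modules(fin2), 1L)
  expect_equal(count_unassigned(fin2), 6L)

  # min_module_size = 1 is the identity on non-isolated nodes
  fin3 <- finalize_partition(raw, g, min_module_size = 1)
  expect_equal(n_modules(fin3), 3L)
})

test_that("planted five-module structure is recovered exactly", {
  sim <- simulate_modular_expression(sizes = rep(20, 5), within_correlation = 0.95,
                                     n_noise_genes = 10, n_samples = 30, seed = 7)
  g <- build_network(sim$expr, beta = 6, min_abs_cor = 0.7)
  det <- detect_modules(g)
  expect_equal(det$n_modules, 5L)
  ri <- rand_index(det$partition, sim$truth)
  expect_gte(ri$ri, 0.95)
})

test_that("empty and edgeless graphs are rejected", {
  expect_error(detect_modules(coexpression_graph(
    "a", data.frame(from = character(), to = character(),
                    correlation = numeric(), weight = numeric()))),
    "no edges")
})

test_that("partition TSVs round-trip", {
  p <- module_partition(stats::setNames(c(1L, 1L, 2L, 0L), paste0("g", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write_partition(p, path)
  back <- read_partition(path)
  expect_equal(as.integer(back), as.integer(p))
  expect_equal(names(back), names(p))
})
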