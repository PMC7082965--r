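test_that("gene correlation matches the textbook formula and handles exact cases", {
  x <- rbind(a = c(1, 2, 3, 4),
             b = c(2, 4, 6, 8),    # identical profile up to scale -> r = 1
             c = c(-1, -2, -3, -4),  # negated -> r = -1
             d = c(1, 2, 3, 5))
  colnames(x) <- paste0("s", 1:4)
  r <- gene_correlation(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  # independent two-pass evaluation of Pearson's formula for (1,2,3,4) vs (1,2,3,5)
  u <- x["a", ]; v <- x["d", ]
  num <- sum((u - mean(u)) * (v - mean(v)))
  den <- sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(r["a", "d"], num / den, tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("constant gene rows are rejected by name", {
  x <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, 1, 0))
  colnames(x) <- paste0("s", 1:3)
  expect_error(gene_correlation(x), "g2")
})

test_that("correlation is invariant to positive affine maps and flips under negation", {
  set.seed(402)
  x <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  r0 <- gene_correlation(x)
  y <- x
  y[2, ] <- 3.7 * x[2, ] + 11          # a > 0: invariant
  y[4, ] <- -0.5 * x[4, ] + 2          # a < 0: sign flip on row 4
  r1 <- gene_correlation(y)
  flip <- diag(c(1, 1, 1, -1, 1))
  expect_equal(r1, flip %*% r0 %*% flip, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("soft adjacency matches direct power evaluation and zeroes the diagonal", {
  r <- matrix(c(1, 0.9, -0.8,
                0.9, 1, 0.5,
                -0.8, 0.5, 1), 3, 3)
  a <- soft_adjacency(r, 16)
  expect_equal(a[1, 2], 0.9^16, tolerance = 1e-12)
  expect_equal(a[1, 3], 0.8^16, tolerance = 1e-12)  # sign dropped
  expect_equal(a[2, 3], 0.5^16, tolerance = 1e-12)
  expect_equal(unname(diag(a)), rep(0, 3))
  expect_error(soft_adjacency(r, 0.5), ">= 1")
})

test_that("soft adjacency is monotone in |r| and in beta", {
  rs <- seq(0.05, 0.95, by = 0.1)
  a6 <- sapply(rs, function(r) abs(r)^6)
  expect_true(all(diff(a6) > 0))                     # larger |r| -> larger a
  for (r in rs) {
    expect_true(abs(r)^16 < abs(r)^6)                # larger beta -> smaller a, |r|<1
  }
})

test_that("an exact power-law connectivity histogram fits with R squared 1", {
  # connectivities placed so each equal-width bin holds one distinct value
  # with frequency 64 * k^-1: a perfect line in log-log space
  k <- rep(c(1, 2, 4, 8), times = c(64, 32, 16, 8))
  fit <- scale_free_fit(k, n_bins = 8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
})

test_that("preferential-attachment graphs fit scale-free topology better than random", {
  set.seed(403)
  pa <- igraph::sample_pa(1000, m = 3, directed = FALSE)
  er <- igraph::sample_gnm(1000, igraph::ecount(pa))
  k_pa <- igraph::degree(pa)
  k_er <- igraph::degree(er)
  fit_pa <- scale_free_fit(k_pa)
  fit_er <- scale_free_fit(k_er)
  expect_gte(fit_pa$r_squared, 0.8)
  expect_lt(fit_er$r_squared, fit_pa$r_squared)
  expect_lt(fit_pa$slope, 0)
})

test_that("degenerate connectivity distributions are a named error", {
  expect_error(scale_free_fit(rep(3, 50)), "degenerate")
})

test_that("soft-threshold selection returns the smallest qualifying power or flags", {
  set.seed(404)
  sim <- simulate_modular_expression(sizes = rep(15, 4), within_correlation = 0.9,
                                     n_noise_genes = 20, n_samples = 30, seed = 19)
  corr <- gene_correlation(sim$expr)
  pick <- pick_soft_threshold(corr, powers = 1:12, target_r2 = 0.8)
  expect_true(pick$beta %in% 1:12)
  if (pick$met_target) {
    expect_gte(pick$r_squared, 0.8)
    qualifying <- pick$fit_table$power[!is.na(pick$fit_table$r_squared) &
                                         pick$fit_table$r_squared >= 0.8]
    expect_equal(pick$beta, min(qualifying))   # smallest qualifying power
  }
  # deterministic: same input, same answer
  pick2 <- pick_soft_threshold(corr, powers = 1:12, target_r2 = 0.8)
  expect_identical(pick, pick2)
  # single-candidate grid returns that candidate, flagged if below target
  one <- pick_soft_threshold(corr, powers = 1, target_r2 = 0.999)
  expect_equal(one$beta, 1L)
  expect_false(one$met_target)
})

test_that("edge thresholding works on |r| and keeps isolated nodes", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.71
  r[1, 3] <- r[3, 1] <- 0.69
  r[2, 3] <- r[3, 2] <- -0.75
  rownames(r) <- colnames(r) <- paste0("g", 1:4)
  a <- soft_adjacency(r, 2)
  g <- threshold_network(r, a, min_abs_cor = 0.7)
  expect_equal(graph_edge_count(g), 2L)   # 0.71 and -0.75 pass, 0.69 does not
  expect_setequal(isolated_nodes(g), "g4")
  expect_setequal(g$nodes, paste0("g", 1:4))
  neg <- g$edges[g$edges$correlation < 0, ]
  expect_equal(neg$weight, 0.75^2, tolerance = 1e-12)

  # threshold above max |r|: empty graph, all isolated
  g0 <- threshold_network(r, a, min_abs_cor = 0.99)
  expect_equal(graph_edge_count(g0), 0L)
  expect_equal(length(isolated_nodes(g0)), 4L)
  # threshold near 0: complete graph
  gc <- threshold_network(r, a, min_abs_cor = 1e-6)
  expect_equal(graph_edge_count(gc), 3L)
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(405)
  sim <- simulate_modular_expression(sizes = c(10, 10), within_correlation = 0.8,
                                     n_noise_genes = 10, n_samples = 20, seed = 5)
  corr <- gene_correlation(sim$expr)
  a <- soft_adjacency(corr, 6)
  counts <- sapply(seq(0.1, 0.9, by = 0.1), function(th) {
    graph_edge_count(threshold_network(corr, a, min_abs_cor = th))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("pipeline is equivariant under gene relabeling", {
  sim <- simulate_modular_expression(sizes = c(8, 8), within_correlation = 0.9,
                                     n_noise_genes = 4, n_samples = 25, seed = 77)
  g1 <- build_network(sim$expr, beta = 4, min_abs_cor = 0.6)
  set.seed(406)
  perm <- sample(nrow(sim$expr))
  g2 <- build_network(sim$expr[perm, , drop = FALSE], beta = 4, min_abs_cor = 0.6)
  key <- function(g) sort(paste(pmin(g$edges$from, g$edges$to),
                                pmax(g$edges$from, g$edges$to),
                                signif(g$edges$weight, 12)))
  expect_identical(key(g1), key(g2))
  expect_setequal(isolated_nodes(g1), isolated_nodes(g2))
})

test_that("graphs round-trip through edge-list TSV and export to GraphML", {
  g <- two_triangles()
  dir <- tempdir()
  path <- file.path(dir, "edges.tsv")
  write_edge_list(g, path)
  back <- read_edge_list(path, nodes = g$nodes)
  expect_setequal(back$nodes, g$nodes)
  expect_equal(graph_total_weight(back), graph_total_weight(g))

  gml <- file.path(dir, "net.graphml")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(ig), 6)
  expect_equal(igraph::ecount(ig), 6)
  expect_equal(sort(igraph::E(ig)$weight), sort(g$edges$weight))
})
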