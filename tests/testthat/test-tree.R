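test_that("Kruskal tree weight equals the exhaustive-enumeration maximum", {
  set.seed(17)
  for (rep in 1:50) {
    w <- random_pli_matrix(5)
    tr <- max_spanning_tree(w)
    expect_equal(sum(tr$edges$weight), oracle_max_tree_weight(w),
                 tolerance = 1e-12)
  }
})

test_that("max spanning tree on w equals igraph min spanning tree on 1 - w", {
  skip_if_not_installed("igraph")
  set.seed(18)
  for (rep in 1:10) {
    w <- random_pli_matrix(19, analysis_labels())
    mine <- max_spanning_tree(w)
    g <- igraph::graph_from_adjacency_matrix(1 - w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g)
    ig_edges <- igraph::as_edgelist(ig)
    expect_identical(edge_key(mine),
                     sort(paste(pmin(ig_edges[, 1], ig_edges[, 2]),
                                pmax(ig_edges[, 1], ig_edges[, 2]))))
  }
})

test_that("every 19-channel tree has 19 nodes, 18 edges and is valid", {
  set.seed(19)
  for (rep in 1:20) {
    tr <- max_spanning_tree(random_pli_matrix(19, analysis_labels()))
    expect_identical(tr$n, 19L)
    expect_identical(nrow(tr$edges), 18L)   # constructor checked acyclicity
  }
  w2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_identical(nrow(max_spanning_tree(w2)$edges), 1L)
  expect_error(max_spanning_tree(matrix(0, 3, 3)), "disconnected")
})

test_that("degree, leaf, diameter and BC metrics match hand values", {
  star <- as_spanning_tree(make_reference_tree("star", 19))
  path <- as_spanning_tree(make_reference_tree("path", 19))

  expect_identical(degree_metrics(star)$max_degree, 18L)
  expect_identical(degree_metrics(path)$max_degree, 2L)
  expect_identical(sum(degree_metrics(star)$degrees), 36L)   # handshake

  expect_identical(leaf_metrics(star)$leaf_number, 18L)
  expect_equal(leaf_metrics(star)$leaf_fraction, 1)
  expect_identical(leaf_metrics(path)$leaf_number, 2L)

  expect_identical(tree_diameter(path), 18L)
  expect_identical(tree_diameter(star), 2L)   # d_max = m - L + 2 with L = m

  bs <- betweenness_tree(star)
  expect_equal(unname(bs$bc[1L]), 1)               # hub carries every path
  expect_equal(unname(bs$bc[-1L]), rep(0, 18))     # leaves score 0
  p5 <- as_spanning_tree(make_reference_tree("path", 5))
  expect_equal(unname(betweenness_tree(p5)$bc[3L]), 4 / 6)  # 2*2 of 6 pairs
})

test_that("betweenness agrees with igraph under the pair normalization", {
  skip_if_not_installed("igraph")
  set.seed(20)
  for (rep in 1:10) {
    tr <- max_spanning_tree(random_pli_matrix(19, analysis_labels()))
    g <- igraph::graph_from_edgelist(as.matrix(tr$edges[, 1:2]),
                                     directed = FALSE)
    ig_bc <- igraph::betweenness(g) / (18 * 17 / 2)
    mine <- betweenness_tree(tr)$bc
    expect_equal(unname(mine[igraph::V(g)$name]), unname(ig_bc),
                 tolerance = 1e-12)
  }
})

test_that("degree correlation is Newman assortativity", {
  star <- as_spanning_tree(make_reference_tree("star", 19))
  expect_equal(degree_correlation(star), -1)
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:10) {
    tr <- max_spanning_tree(random_pli_matrix(19, analysis_labels()))
    r <- degree_correlation(tr)
    expect_true(is.na(r) || (r >= -1 && r <= 1))
    g <- igraph::graph_from_edgelist(as.matrix(tr$edges[, 1:2]),
                                     directed = FALSE)
    expect_equal(r, igraph::assortativity_degree(g), tolerance = 1e-10)
  }
})

test_that("metric bounds hold over random trees", {
  set.seed(22)
  for (rep in 1:100) {
    tr <- as_spanning_tree(make_reference_tree("random", 19))
    L <- leaf_metrics(tr)$leaf_number
    d <- tree_diameter(tr)
    bc <- betweenness_tree(tr)$bc
    expect_true(L >= 2L && L <= 18L)
    expect_true(d >= 2L && d <= 18L - L + 2L)   # d <= m - L + 2
    expect_true(all(bc >= 0 & bc <= 1))
    deg <- degree_metrics(tr)$degrees
    expect_true(all(bc[deg == 1L] == 0))
  }
})

test_that("regional BC averages node BC within disjoint regions", {
  # star with its hub planted on T6: the whole load sits posteriorly
  labels <- analysis_labels()
  hub_first <- c("T6", setdiff(labels, "T6"))
  star <- as_spanning_tree(make_reference_tree("star", 19), hub_first)
  reg <- regional_bc(star)
  expect_equal(reg$bc_posterior, (1 + 6 * 0) / 7)
  expect_equal(reg$bc_anterior, 0)

  # all-equal BC: both regions identical (cycle-free path interior excluded)
  p3 <- spanning_tree(c("F3", "Cz", "P3"),
                      data.frame(from = c("F3", "Cz"), to = c("Cz", "P3"),
                                 weight = 1))
  rc <- region_config(anterior = "F3", posterior = "P3", excluded = "Cz")
  rr <- regional_bc(p3, rc)
  expect_equal(rr$bc_anterior, rr$bc_posterior)

  expect_error(regional_bc(star, region_config(anterior = c("F3", "XX"),
                                               posterior = "P3")),
               "not in tree")
})

test_that("subject-band metrics are the arithmetic mean over epochs", {
  set.seed(23)
  eps1 <- array(rnorm(6 * 2048), c(6, 2048, 1))
  labels <- c("F3", "F4", "Fz", "P3", "P4", "Pz")
  rc <- region_config(anterior = c("F3", "F4", "Fz"),
                      posterior = c("P3", "P4", "Pz"), excluded = character(0))
  one <- subject_band_metrics(epoch_set(eps1, 500, labels), rc)
  direct <- mst_metrics(max_spanning_tree(pli_matrix(eps1[, , 1], labels)), rc)
  expect_equal(one$leaf_fraction, direct$leaf_fraction)
  expect_equal(one$bc_max, direct$bc_max)
  expect_equal(one$pli, global_pli(pli_matrix(eps1[, , 1], labels)))

  # identical epochs: metrics equal the single-epoch values
  rep3 <- epoch_set(array(eps1[, , c(1, 1, 1)], c(6, 2048, 3)), 500, labels)
  expect_equal(subject_band_metrics(rep3, rc)[-2], one[-2])

  # two different epochs: every metric is the midpoint
  ep2 <- array(c(eps1[, , 1], rnorm(6 * 2048)), c(6, 2048, 2))
  both <- subject_band_metrics(epoch_set(ep2, 500, labels), rc)
  second <- subject_band_metrics(epoch_set(ep2[, , 2, drop = FALSE], 500,
                                           labels), rc)
  expect_equal(both$diameter, (one$diameter + second$diameter) / 2)
  expect_equal(both$bc_posterior, (one$bc_posterior + second$bc_posterior) / 2)
})
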