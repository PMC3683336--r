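test_that("is_chordal handles the canonical small cases", {
  expect_true(is_chordal(skeleton(4)))
  expect_false(is_chordal(chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4),
                                               c(1, 4)))))
  expect_true(is_chordal(chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4),
                                              c(1, 4), c(1, 3)))))
  expect_true(is_chordal(chrom_graph(3)))  # empty graph
})

test_that("is_chordal agrees with the simplicial-elimination oracle on random graphs", {
  set.seed(42)
  for (rep in 1:60) {
    p <- sample(4:8, 1)
    n_e <- sample.int(p * (p - 1) / 2, 1)
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    g <- chrom_graph(p, pairs[sample.int(nrow(pairs), n_e), , drop = FALSE])
    expect_identical(is_chordal(g), oracle_is_chordal(g))
  }
})

test_that("mcs_triangulate returns chordal supergraphs and is exact on chordal input", {
  g <- chrom_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 4), c(4, 5)))
  tri <- mcs_triangulate(g)
  expect_equal(nrow(tri$fill_edges), 0)
  expect_true(graphs_equal(tri$graph, g))

  cyc4 <- chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  tri4 <- mcs_triangulate(cyc4)
  expect_equal(nrow(tri4$fill_edges), 1)
  expect_true(is_chordal(tri4$graph))
  expect_true(all(edge_keys(cyc4) %in% edge_keys(tri4$graph)))
})

test_that("mcs_triangulate matches the elimination-game oracle and is idempotent", {
  # 6-cycle: fill count must equal brute-force elimination along the
  # reverse MCS order with lowest-index tie-breaking
  cyc6 <- chrom_graph(6, cbind(1:6, c(2:6, 1)))
  ord <- ldgraph:::mcs_run(ldgraph:::cg_adj(cyc6))$order
  tri <- mcs_triangulate(cyc6)
  expect_equal(nrow(tri$fill_edges), oracle_elimination_fill(cyc6, rev(ord)))
  expect_true(is_chordal(tri$graph))

  set.seed(7)
  for (rep in 1:20) {
    p <- sample(5:9, 1)
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    g <- chrom_graph(p, pairs[sample.int(nrow(pairs), p), , drop = FALSE])
    tri <- mcs_triangulate(g)
    expect_true(is_chordal(tri$graph))
    expect_true(all(edge_keys(g) %in% edge_keys(tri$graph)))
    # idempotence
    expect_equal(nrow(mcs_triangulate(tri$graph)$fill_edges), 0)
  }
})

test_that("clique_forest reproduces the textbook examples", {
  f <- clique_forest(chrom_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3))))
  expect_equal(f$cliques, list(1:3))
  expect_length(f$separators, 0)

  f <- clique_forest(skeleton(3))
  expect_setequal(sapply(f$cliques, paste, collapse = ","), c("1,2", "2,3"))
  expect_equal(f$separators, list(2L))

  f <- clique_forest(chrom_graph(4, rbind(c(1, 2), c(1, 3), c(2, 3),
                                          c(2, 4), c(3, 4))))
  expect_setequal(sapply(f$cliques, paste, collapse = ","),
                  c("1,2,3", "2,3,4"))
  expect_equal(f$separators, list(2:3))

  expect_error(clique_forest(chrom_graph(4, rbind(c(1, 2), c(2, 3),
                                                  c(3, 4), c(1, 4)))),
               "chordal")
})

test_that("clique_forest invariants hold on random chordal graphs", {
  set.seed(11)
  for (rep in 1:25) {
    p <- sample(6:15, 1)
    g <- rand_chordal(p, sample(0:6, 1))
    f <- clique_forest(g)
    expect_identical(ldgraph:::check_clique_forest(f, g), TRUE)
    # every vertex covered; one tree per connected component
    expect_setequal(sort(unique(unlist(f$cliques))), seq_len(p))
    n_comp <- length(connected_components(g))
    expect_equal(length(f$cliques) - nrow(f$tree_edges), n_comp)
  }
})

test_that("clique maximality agrees with igraph's max_cliques oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:15) {
    p <- sample(5:12, 1)
    g <- rand_chordal(p, sample(0:8, 1))
    f <- clique_forest(g)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, p - igraph::vcount(ig)))
    want <- sort(vapply(igraph::max_cliques(ig),
                        function(v) paste(sort(as.integer(v)),
                                          collapse = ","), character(1)))
    got <- sort(vapply(f$cliques, paste, collapse = ",", FUN.VALUE = ""))
    expect_identical(got, want)
  }
})

test_that("edge_addable examples and error behaviour", {
  res <- edge_addable(skeleton(3), NULL, 1, 3)
  expect_true(res$ok)
  expect_equal(res$S, 2L)

  expect_false(edge_addable(skeleton(4), NULL, 1, 4)$ok)

  g <- chrom_graph(4, rbind(c(1, 2), c(3, 4)))
  res <- edge_addable(g, NULL, 2, 3)
  expect_true(res$ok)
  expect_length(res$S, 0)

  expect_error(edge_addable(skeleton(3), NULL, 1, 2), "already present")
  expect_error(edge_addable(skeleton(3), NULL, 2, 2), "must differ")
})

test_that("edge_removable examples and error behaviour", {
  tri <- chrom_graph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  res <- edge_removable(tri, NULL, 1, 2)
  expect_true(res$ok)
  expect_equal(res$S, 3L)

  g <- chrom_graph(4, rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
  expect_false(edge_removable(g, NULL, 2, 3)$ok)

  res <- edge_removable(skeleton(3), NULL, 1, 2)
  expect_true(res$ok)
  expect_length(res$S, 0)

  expect_error(edge_removable(skeleton(3), NULL, 1, 3), "not present")
})

test_that("single-edge perturbation tests match chordality of the perturbed graph", {
  set.seed(99)
  for (rep in 1:40) {
    p <- sample(4:8, 1)
    g <- rand_chordal(p, sample(0:5, 1),
                      start = chrom_graph(p, if (p > 1)
                        cbind(1:(p - 1), 2:p) else NULL))
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    dimnames(pairs) <- NULL
    present <- paste(pairs[, 1], pairs[, 2]) %in% edge_keys(g)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      if (present[k]) {
        got <- edge_removable(g, NULL, a, b)
        keep <- !(g$edges[, 1] == a & g$edges[, 2] == b)
        gm <- chrom_graph(p, g$edges[keep, , drop = FALSE])
        expect_identical(got$ok, is_chordal(gm))
        if (got$ok) {
          # S must be the host clique minus the endpoints
          cl <- Filter(function(c) all(c(a, b) %in% c),
                       clique_forest(g)$cliques)
          expect_length(cl, 1)
          expect_equal(got$S, sort(setdiff(cl[[1]], c(a, b))))
        }
      } else {
        got <- edge_addable(g, NULL, a, b)
        gp <- chrom_graph(p, rbind(g$edges, c(a, b)))
        expect_identical(got$ok, is_chordal(gp))
        if (got$ok) {
          cl <- Filter(function(c) all(c(a, b) %in% c),
                       clique_forest(gp)$cliques)
          expect_length(cl, 1)
          expect_equal(sort(cl[[1]]), sort(c(a, b, got$S)))
        }
      }
    }
  }
})

test_that("connected_components partitions vertices in smallest-member order", {
  expect_equal(connected_components(skeleton(5)), list(1:5))
  expect_equal(connected_components(chrom_graph(3)),
               list(1L, 2L, 3L))
  expect_equal(connected_components(chrom_graph(5, rbind(c(1, 2), c(4, 5)))),
               list(1:2, 3L, 4:5))
})

test_that("boundary matches its defining formula", {
  g <- skeleton(4)
  expect_equal(boundary(g, c(2, 3)), c(1L, 4L))
  expect_equal(boundary(g, 1:4), integer())
  expect_equal(boundary(chrom_graph(3, rbind(c(1, 2))), 3), integer())
  expect_error(boundary(g, 9), "1..p")
})
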