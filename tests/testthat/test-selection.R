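test_that("skeleton builds the serial graph", {
  expect_equal(n_edges(skeleton(1)), 0)
  expect_equal(n_edges(skeleton(5)), 4)
  hw <- heights_widths(skeleton(5))
  expect_true(all(hw$heights == 1) && all(hw$widths == 1))
  expect_error(skeleton(0), ">= 1")
})

test_that("forward_search leaves a true chain model alone under BIC", {
  # v1 independent of v3 given v2, strong serial dependence: with high
  # probability no edge should be added to the skeleton
  added <- vapply(1:20, function(s) {
    set.seed(s)
    m <- serial_mm(2000, 3, flip = 0.2)
    fit <- forward_search(m, skeleton(3), selection_config("bic"))
    n_edges(fit$graph) - 2L
  }, integer(1))
  expect_gte(sum(added == 0L), 18)
})

test_that("forward_search finds a strong conditional dependence", {
  # XOR-structured clique {1,2,3}: x3 = x1 xor x2 (noisy), so (1,3) carries
  # strong dependence given 2 but is marginally near-independent
  set.seed(123)
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 2000
    x1 <- sample(0:1, n, TRUE)
    x2 <- sample(0:1, n, TRUE)
    x3 <- ifelse(stats::runif(n) < 0.05, 1L - xor(x1, x2), xor(x1, x2))
    m <- marker_matrix(cbind(x1, x2, as.integer(x3)), "haplotype")
    fit <- forward_search(m, skeleton(3), selection_config("bic"))
    "1 3" %in% edge_keys(fit$graph)
  }, logical(1))
  expect_true(all(hits))
})

test_that("forward_search terminates at a local optimum with chordal intermediates", {
  set.seed(77)
  rl <- random_ld_model(15, n_extra = 5, max_width = 4, seed = 42,
                        concentration = 0.4)
  m <- sample_model(rl$model, 800, seed = 43)
  cfg <- selection_config("bic")
  fit <- forward_search(m, skeleton(15), cfg)
  # trace is strictly improving
  expect_true(all(fit$trace$d_ic < 0))
  # replay: every intermediate graph is chordal and contains the skeleton
  g <- skeleton(15)
  for (k in seq_len(nrow(fit$trace))) {
    g <- chrom_graph(15, rbind(g$edges, c(fit$trace$a[k], fit$trace$b[k])))
    expect_true(is_chordal(g))
  }
  expect_true(graphs_equal(g, fit$graph))
  expect_true(all(edge_keys(skeleton(15)) %in% edge_keys(fit$graph)))
  # no remaining addition improves the criterion
  alpha <- log(m$n_rows)
  pairs <- which(upper.tri(matrix(0, 15, 15)), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (paste(a, b) %in% edge_keys(fit$graph)) next
    chk <- edge_addable(fit$graph, NULL, a, b)
    if (!chk$ok) next
    d <- delta_score(m, NULL, a, b, chk$S, alpha, "add")
    expect_gte(d$d_ic, 0)
  }
})

test_that("backward_prune removes an independent adjacent pair", {
  pruned <- vapply(1:20, function(s) {
    set.seed(s)
    x <- cbind(sample(0:1, 5000, TRUE), sample(0:1, 5000, TRUE))
    m <- marker_matrix(x, "haplotype")
    fit <- backward_prune(m, skeleton(2), selection_config("bic"))
    n_edges(fit$graph) == 0L
  }, logical(1))
  expect_gte(sum(pruned), 18)
})

test_that("backward_prune empties a saturated clique fitted to independent data", {
  set.seed(31)
  m <- rand_mm(4000, 3)
  sat <- chrom_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  fit <- backward_prune(m, sat, selection_config("bic"))
  expect_equal(n_edges(fit$graph), 0)
  # termination contract: no removal improves
  expect_true(all(fit$trace$d_ic < 0))
})

test_that("fit_standard returns the empty graph for independent columns", {
  empty <- vapply(1:20, function(s) {
    set.seed(s)
    m <- rand_mm(5000, 3)
    n_edges(fit_standard(m, selection_config("bic"))$graph) == 0L
  }, logical(1))
  expect_gte(sum(empty), 18)
})

test_that("fit_standard is locally optimal and never worse than the skeleton", {
  set.seed(55)
  rl <- random_ld_model(5, n_extra = 2, max_width = 3, seed = 9,
                        concentration = 0.5)
  m <- sample_model(rl$model, 1000, seed = 10)
  cfg <- selection_config("bic")
  fwd <- forward_search(m, skeleton(5), cfg)
  fit <- fit_standard(m, cfg)
  alpha <- log(m$n_rows)
  ic_skel <- model_score(m, clique_forest(skeleton(5)), alpha)$ic
  expect_lte(fit$score$ic, ic_skel + 1e-9)
  # exhaustive single-edge neighbourhood check, phase-wise: no addition
  # improves the forward-phase optimum, no removal improves the final graph
  pairs <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (!(paste(a, b) %in% edge_keys(fwd$graph))) {
      chk <- edge_addable(fwd$graph, NULL, a, b)
      if (chk$ok) {
        d <- delta_score(m, NULL, a, b, chk$S, alpha, "add")
        expect_gte(d$d_ic, -1e-9)
      }
    }
    if (paste(a, b) %in% edge_keys(fit$graph)) {
      chk <- edge_removable(fit$graph, NULL, a, b)
      if (chk$ok) {
        d <- delta_score(m, NULL, a, b, chk$S, alpha, "remove")
        expect_gte(d$d_ic, -1e-9)
      }
    }
  }
})

test_that("block_bounds matches the stated block spans", {
  fc <- fast_config(L = 100, K = 20)
  expect_equal(unname(block_bounds(260, fc)),
               rbind(c(1, 100), c(81, 180), c(161, 260)))
  expect_equal(unname(block_bounds(100, fc)), rbind(c(1, 100)))
  expect_equal(unname(block_bounds(150, fc)), rbind(c(1, 100), c(81, 150)))
  # a final block of length <= K is merged into the previous one
  expect_equal(unname(block_bounds(115, fc)), rbind(c(1, 100), c(81, 115)))
  expect_equal(unname(block_bounds(5, fc)), rbind(c(1, 5)))
  expect_error(fast_config(L = 10, K = 10), "0 < K < L")
})

test_that("stitch applies the m* rule", {
  # worked example: L = 10, K = 4; cumulative = skeleton(1..10) + (5,8),
  # block 2 = skeleton(7..16).  m* = 8; the merged graph is
  # skeleton(1..16) + (5,8)
  cum <- rbind(cbind(1:9, 2:10), c(5, 8))
  state <- list(cum_edges = cum, e = 10L, m_star = NA_integer_,
                violated = FALSE, warnings = character())
  blk <- cbind(7:15, 8:16)
  out <- stitch(state, blk, block_start = 7, block_end = 16, K = 4)
  expect_equal(out$m_star, 8)
  want <- chrom_graph(16, rbind(cbind(1:15, 2:16), c(5, 8)))
  expect_true(graphs_equal(chrom_graph(16, out$cum_edges), want))
  expect_false(out$violated)

  # pure skeleton on both sides: m* = s and the result is the union skeleton
  state <- list(cum_edges = cbind(1:9, 2:10), e = 10L,
                m_star = NA_integer_, violated = FALSE,
                warnings = character())
  out <- stitch(state, cbind(7:15, 8:16), 7, 16, K = 4)
  expect_equal(out$m_star, 7)
  expect_true(graphs_equal(chrom_graph(16, out$cum_edges),
                           skeleton(16)))

  # overlap violation: a block edge looks past the cumulative end while
  # m* reaches it
  cum <- rbind(cbind(1:9, 2:10), c(5, 9))
  state <- list(cum_edges = cum, e = 10L, m_star = NA_integer_,
                violated = FALSE, warnings = character())
  blk <- rbind(cbind(7:15, 8:16), c(8, 12))
  expect_warning(out <- stitch(state, blk, 7, 16, K = 4), "overlap")
  expect_true(out$violated)

  expect_error(stitch(state, blk, 6, 16, K = 4), "cum_end - K \\+ 1")
})

test_that("fast_forward on a single block equals plain forward search", {
  set.seed(14)
  rl <- random_ld_model(30, n_extra = 6, max_width = 4, seed = 3,
                        concentration = 0.5)
  m <- sample_model(rl$model, 800, seed = 4)
  cfg <- selection_config("bic")
  ff <- fast_forward(m, cfg, fast_config(L = 100, K = 20))
  fs <- forward_search(m, skeleton(30), cfg)
  expect_true(graphs_equal(ff$graph, fs$graph))
})

test_that("fast_forward output is chordal, contains the skeleton, and respects independent halves", {
  set.seed(15)
  # two independent halves with no cross-boundary dependence
  half1 <- sample_model(random_ld_model(30, 6, 4, seed = 21,
                                        concentration = 0.5)$model,
                        1500, seed = 22)
  half2 <- sample_model(random_ld_model(30, 6, 4, seed = 23,
                                        concentration = 0.5)$model,
                        1500, seed = 24)
  m <- marker_matrix(cbind(half1$values, half2$values), "haplotype")
  cfg <- selection_config("bic")
  ff <- fast_forward(m, cfg, fast_config(L = 25, K = 8))
  expect_true(is_chordal(ff$graph))
  expect_true(all(edge_keys(skeleton(60)) %in% edge_keys(ff$graph)))
  crossing <- ff$graph$edges[, 1] <= 30 & ff$graph$edges[, 2] >= 31
  cross_edges <- ff$graph$edges[crossing, , drop = FALSE]
  # only the skeleton edge (30, 31) may span the boundary
  expect_true(all(paste(cross_edges[, 1], cross_edges[, 2]) == "30 31"))
})

test_that("fit_fast propagates warnings and improves on the forward graph", {
  set.seed(16)
  rl <- random_ld_model(60, n_extra = 10, max_width = 4, seed = 31,
                        concentration = 0.5)
  m <- sample_model(rl$model, 800, seed = 32)
  cfg <- selection_config("bic")
  ff <- fast_forward(m, cfg, fast_config(L = 25, K = 8))
  fit <- fit_fast(m, cfg, fast_config(L = 25, K = 8))
  ic_forward <- model_score(m, clique_forest(ff$graph), log(m$n_rows))$ic
  expect_true(is.finite(fit$score$ic))
  expect_lte(fit$score$ic, ic_forward + 1e-9)
})

test_that("selection_config validates alpha and presets", {
  expect_error(selection_config(alpha = -1), "positive")
  m <- rand_mm(100, 2)
  expect_equal(ldgraph:::resolve_alpha(selection_config("aic"), m), 2)
  expect_equal(ldgraph:::resolve_alpha(selection_config("bic"), m), log(100))
  expect_equal(ldgraph:::resolve_alpha(selection_config(alpha = 5), m), 5)
})

test_that("max_span restricts candidate edges", {
  set.seed(17)
  rl <- random_ld_model(12, n_extra = 4, max_width = 5, seed = 51,
                        concentration = 0.4)
  m <- sample_model(rl$model, 1500, seed = 52)
  fit <- forward_search(m, skeleton(12),
                        selection_config("bic", max_span = 2))
  expect_true(all(fit$graph$edges[, 2] - fit$graph$edges[, 1] <= 2))
})
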