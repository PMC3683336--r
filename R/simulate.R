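#' Fit clique-marginal probability tables of a decomposable model
#'
#' The maximum likelihood estimate of a decomposable model is assembled
#' from the empirical clique marginals: each clique table is its count
#' table divided by N. Separator consistency (the two endpoint cliques of
#' every junction-forest edge agree on their separator margin) holds by
#' construction and is asserted.
#'
#' @param m A [marker_matrix()].
#' @param f A [clique_forest()] valid for `m`.
#' @return Object of class `fitted_model`: list with `forest`, `tables`
#'   (per clique: `vars`, `configs`, `probs`), `levels` (per-vertex sorted
#'   observed codes), `p` and `kind`.
#' @export
fit_model <- function(m, f) {
  if (m$n_rows == 0L) stop("cannot fit a model to zero observations")
  tables <- lapply(f$cliques, function(cl) {
    jc <- joint_code(m$values[, cl, drop = FALSE])
    list(vars = cl, configs = jc$configs, probs = jc$counts / m$n_rows)
  })
  levels <- lapply(seq_len(n_markers(m)),
                   function(j) sort(unique(m$values[, j])))
  model <- structure(
    list(forest = f, tables = tables, levels = levels,
         p = n_markers(m), kind = m$kind),
    class = "fitted_model"
  )
  assert_consistent(model)
  model
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model: %d SNPs (%s), %d cliques\n",
              x$p, x$kind, length(x$tables)))
  invisible(x)
}

# margin of a clique table onto a subset of its variables
table_margin <- function(tab, vars) {
  pos <- match(vars, tab$vars)
  if (any(is.na(pos))) stop("margin variables outside the clique")
  if (length(pos) == 0L) {
    return(list(configs = matrix(integer(), 1L, 0L), probs = sum(tab$probs)))
  }
  sub <- tab$configs[, pos, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = ",")
  agg <- vapply(split(tab$probs, key), sum, numeric(1))
  first <- !duplicated(key)
  cfg <- sub[first, , drop = FALSE]
  ord <- order(apply(cfg, 1L, paste, collapse = ","))
  list(configs = cfg[ord, , drop = FALSE],
       probs = unname(agg[apply(cfg, 1L, paste, collapse = ",")[ord]]))
}

assert_consistent <- function(model, tol = 1e-9) {
  f <- model$forest
  for (tab in model$tables) {
    if (abs(sum(tab$probs) - 1) > tol) stop("clique table does not sum to 1")
  }
  if (nrow(f$tree_edges) == 0L) return(invisible(TRUE))
  for (e in seq_len(nrow(f$tree_edges))) {
    s <- f$separators[[e]]
    m1 <- table_margin(model$tables[[f$tree_edges[e, 1L]]], s)
    m2 <- table_margin(model$tables[[f$tree_edges[e, 2L]]], s)
    if (!identical(dim(m1$configs), dim(m2$configs)) ||
        !all(m1$configs == m2$configs) ||
        max(abs(m1$probs - m2$probs)) > tol) {
      stop("separator margins disagree between adjacent cliques")
    }
  }
  invisible(TRUE)
}

# roots = cliques that are not the child of any tree edge
forest_roots <- function(f) {
  setdiff(seq_along(f$cliques),
          if (nrow(f$tree_edges) > 0L) f$tree_edges[, 2L] else integer())
}

#' Sample observations from a fitted decomposable model
#'
#' Draws by traversing each junction tree from its root (the clique
#' containing the tree's lowest-indexed vertex): the root clique is sampled
#' from its table, then each child clique's non-separator variables are
#' sampled from the conditional distribution given the already-drawn
#' separator configuration. Reproducible given `seed`.
#'
#' @param model A [fit_model()] / [random_ld_model()] result.
#' @param n Number of observations.
#' @param seed Optional integer seed.
#' @return A [marker_matrix()] of `n` rows.
#' @export
sample_model <- function(model, n, seed = NULL) {
  n <- as.integer(n)
  with_seed(seed, {
    out <- matrix(0L, n, model$p)
    f <- model$forest
    for (r in forest_roots(f)) {
      tab <- model$tables[[r]]
      idx <- sample.int(length(tab$probs), n, replace = TRUE,
                        prob = tab$probs)
      out[, tab$vars] <- tab$configs[idx, , drop = FALSE]
    }
    if (nrow(f$tree_edges) > 0L) {
      for (e in seq_len(nrow(f$tree_edges))) {
        child <- f$tree_edges[e, 2L]
        s <- f$separators[[e]]
        tab <- model$tables[[child]]
        spos <- match(s, tab$vars)
        dpos <- setdiff(seq_along(tab$vars), spos)
        if (length(dpos) == 0L) next
        cell_key <- apply(tab$configs[, spos, drop = FALSE], 1L,
                          paste, collapse = ",")
        row_key <- apply(out[, s, drop = FALSE], 1L, paste, collapse = ",")
        cells_by_key <- split(seq_along(cell_key), cell_key)
        rows_by_key <- split(seq_len(n), row_key)
        for (key in names(rows_by_key)) {
          cells <- cells_by_key[[key]]
          # a drawn separator configuration always has positive probability
          # in a consistent model
          stopifnot(!is.null(cells))
          rows <- rows_by_key[[key]]
          pr <- tab$probs[cells]
          pick <- cells[sample.int(length(cells), length(rows),
                                   replace = TRUE, prob = pr)]
          out[rows, tab$vars[dpos]] <-
            tab$configs[pick, dpos, drop = FALSE]
        }
      }
    }
    marker_matrix(out, model$kind)
  })
}

#' Generate a random sparse LD-like decomposable model
#'
#' Builds a random chordal graph containing the skeleton by attempting to
#' add `n_extra` random short-range edges `(i, j)` with `2 <= j - i <=
#' max_width`, accepting only decomposability-preserving additions, then
#' equips its junction forest with random consistent clique tables: the
#' root clique of each tree gets a symmetric Dirichlet draw and every child
#' clique gets Dirichlet conditionals given each separator configuration.
#' Smaller `concentration` gives stronger (more skewed) LD.
#'
#' @param p Number of SNPs.
#' @param n_extra Extra edges beyond the skeleton to attempt.
#' @param max_width Cap on `j - i` for extra edges (>= 2).
#' @param concentration Dirichlet concentration (default 1).
#' @param kind `"haplotype"` (binary) or `"genotype"` (trichotomous).
#' @param seed Optional integer seed.
#' @return List with `graph` (chordal `chrom_graph`) and `model`
#'   (`fitted_model`). If fewer than `n_extra` edges could be placed a
#'   warning is raised.
#' @export
random_ld_model <- function(p, n_extra = 0L, max_width = 6L,
                            concentration = 1, kind = c("haplotype",
                                                        "genotype"),
                            seed = NULL) {
  kind <- match.arg(kind)
  p <- as.integer(p)
  n_extra <- as.integer(n_extra)
  max_width <- as.integer(max_width)
  if (max_width < 2L) stop("'max_width' must be >= 2")
  if (n_extra < 0L) stop("'n_extra' must be >= 0")
  with_seed(seed, {
    adj <- cg_adj(skeleton(p))
    placed <- 0L
    attempts <- 0L
    max_attempts <- 60L * max(n_extra, 1L)
    while (placed < n_extra && attempts < max_attempts) {
      attempts <- attempts + 1L
      span <- sample(2:max_width, 1L)
      if (p - span < 1L) next
      i <- sample.int(p - span, 1L)
      j <- i + span
      if (adj[i, j]) next
      if (addable_adj(adj, i, j)$ok) {
        adj[i, j] <- adj[j, i] <- TRUE
        placed <- placed + 1L
      }
    }
    if (placed < n_extra) {
      warning(sprintf("placed only %d of %d extra edges", placed, n_extra))
    }
    g <- adj_to_graph(adj)
    f <- clique_forest(g)
    r <- if (kind == "haplotype") 2L else 3L
    codes <- 0:(r - 1L)
    full_configs <- function(k) {
      m <- as.matrix(expand.grid(rep(list(codes), k),
                                 KEEP.OUT.ATTRS = FALSE))
      dimnames(m) <- NULL
      matrix(as.integer(m), ncol = k)
    }
    rdirichlet <- function(k) {
      x <- stats::rgamma(k, shape = concentration)
      while (sum(x) == 0) x <- stats::rgamma(k, shape = concentration)
      x / sum(x)
    }
    tables <- vector("list", length(f$cliques))
    # roots first, then children in tree-edge order (parents precede)
    for (ri in forest_roots(f)) {
      cl <- f$cliques[[ri]]
      cfg <- full_configs(length(cl))
      tables[[ri]] <- list(vars = cl, configs = cfg,
                           probs = rdirichlet(nrow(cfg)))
    }
    if (nrow(f$tree_edges) > 0L) {
      for (e in seq_len(nrow(f$tree_edges))) {
        parent <- f$tree_edges[e, 1L]
        child <- f$tree_edges[e, 2L]
        s <- f$separators[[e]]
        cl <- f$cliques[[child]]
        d <- setdiff(cl, s)
        cfg <- full_configs(length(cl))
        colnames(cfg) <- NULL
        spos <- match(s, cl)
        dpos <- match(d, cl)
        sep_margin <- table_margin(tables[[parent]], s)
        sep_key <- apply(cfg[, spos, drop = FALSE], 1L, paste, collapse = ",")
        margin_key <- apply(sep_margin$configs, 1L, paste, collapse = ",")
        probs <- numeric(nrow(cfg))
        for (u in unique(sep_key)) {
          cells <- which(sep_key == u)
          psep <- sep_margin$probs[match(u, margin_key)]
          probs[cells] <- psep * rdirichlet(length(cells))
        }
        tables[[child]] <- list(vars = cl, configs = cfg, probs = probs)
      }
    }
    model <- structure(
      list(forest = f, tables = tables,
           levels = rep(list(codes), p), p = p, kind = kind),
      class = "fitted_model"
    )
    assert_consistent(model)
    list(graph = g, model = model)
  })
}

#' Edgewise comparison of a true and an estimated graph
#'
#' Undershoot counts edges of the generating graph missed by the estimate
#' (false negatives); overshoot counts estimated edges absent from the
#' truth (false inclusions). Rates normalize both counts by the number of
#' true edges.
#'
#' @param true_g,est_g `chrom_graph`s on the same `p`.
#' @return Object of class `graph_comparison`: list with `undershoot`,
#'   `overshoot`, `fnr`, `fir`.
#' @export
compare_graphs <- function(true_g, est_g) {
  if (true_g$p != est_g$p) {
    stop(sprintf("vertex counts differ: %d vs %d", true_g$p, est_g$p))
  }
  key <- function(e) e[, 1L] * (true_g$p + 1) + e[, 2L]
  kt <- key(true_g$edges)
  ke <- key(est_g$edges)
  under <- sum(!(kt %in% ke))
  over <- sum(!(ke %in% kt))
  nt <- length(kt)
  rate <- function(x) {
    if (nt > 0L) x / nt else if (x == 0L) 0 else Inf
  }
  structure(
    list(undershoot = under, overshoot = over,
         fnr = rate(under), fir = rate(over)),
    class = "graph_comparison"
  )
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat(sprintf(
    "graph_comparison: undershoot %d (fnr %.4g), overshoot %d (fir %.4g)\n",
    x$undershoot, x$fnr, x$overshoot, x$fir))
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotypes
#'
#' Sums consecutive haplotype row pairs (rows `2t - 1` and `2t`) into the
#' genotype row `t`. The operation is not invertible: phase is lost.
#'
#' @param h A haplotype-kind [marker_matrix()] with an even row count.
#' @return A genotype-kind [marker_matrix()].
#' @export
diploid_from_haplotypes <- function(h) {
  if (h$kind != "haplotype") stop("input must be haplotype data")
  n <- h$n_rows
  if (n %% 2L != 0L) stop("row count must be even (two rows per individual)")
  odd <- seq(1L, n, by = 2L)
  marker_matrix(h$values[odd, , drop = FALSE] +
                  h$values[odd + 1L, , drop = FALSE],
                "genotype", marker_ids = h$marker_ids,
                positions = h$positions)
}

#' Serialize a fitted model to structured text (JSON)
#'
#' @param model A `fitted_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    p = model$p, kind = model$kind,
    levels = model$levels,
    cliques = model$forest$cliques,
    tree_edges = model$forest$tree_edges,
    separators = model$forest$separators,
    tables = lapply(model$tables, function(t)
      list(vars = t$vars, configs = t$configs, probs = t$probs))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted model written by [write_model()]
#'
#' @param path Input path.
#' @return A `fitted_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_int_mat <- function(rows, ncol) {
    if (is.null(rows) || length(rows) == 0L) {
      return(matrix(integer(), 0L, ncol))
    }
    do.call(rbind, lapply(rows, function(r)
      as.integer(unlist(r, use.names = FALSE))))
  }
  f <- structure(
    list(cliques = lapply(x$cliques,
                          function(c) as.integer(unlist(c))),
         tree_edges = as_int_mat(x$tree_edges, 2L),
         separators = lapply(x$separators,
                             function(s) as.integer(unlist(s))),
         p = as.integer(x$p)),
    class = "clique_forest"
  )
  tables <- lapply(x$tables, function(t) {
    vars <- as.integer(unlist(t$vars))
    list(vars = vars,
         configs = as_int_mat(t$configs, length(vars)),
         probs = as.numeric(unlist(t$probs)))
  })
  model <- structure(
    list(forest = f, tables = tables,
         levels = lapply(x$levels, function(l) as.integer(unlist(l))),
         p = as.integer(x$p), kind = x$kind),
    class = "fitted_model"
  )
  assert_consistent(model)
  model
}
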