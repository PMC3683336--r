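#' Undirected graph on ordered SNP vertices
#'
#' A `chrom_graph` is an undirected graph whose vertices are the integers
#' `1..p`, representing SNPs in physical order along a chromosome. Edges are
#' stored as a two-column integer matrix of pairs `i < j`. This is the
#' container used throughout the package for LD dependence graphs.
#'
#' @param p Number of vertices (positive integer).
#' @param edges Two-column matrix (or vector coercible to one) of vertex
#'   pairs; order within a pair is ignored, duplicates are removed.
#' @return An object of class `chrom_graph` with fields `p` and `edges`.
#' @examples
#' g <- chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' n_edges(g)
#' @export
chrom_graph <- function(p, edges = NULL) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L) {
    stop("'p' must be a single positive integer")
  }
  edges <- canon_edges(edges)
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (any(edges < 1L) || any(edges > p)) {
      stop("edge endpoints must lie in 1..p")
    }
  }
  structure(list(p = p, edges = edges), class = "chrom_graph")
}

#' @export
print.chrom_graph <- function(x, ...) {
  cat(sprintf("chrom_graph: %d vertices, %d edges\n", x$p, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a graph
#' @param g A `chrom_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
`==.chrom_graph` <- function(e1, e2) {
  e1$p == e2$p && identical(canon_edges(e1$edges), canon_edges(e2$edges))
}

# logical adjacency matrix
cg_adj <- function(g) {
  a <- matrix(FALSE, g$p, g$p)
  if (nrow(g$edges) > 0L) {
    a[g$edges] <- TRUE
    a[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  a
}

# adjacency matrix -> chrom_graph
adj_to_graph <- function(a) {
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  chrom_graph(nrow(a), idx)
}

# Maximum cardinality search on an adjacency matrix.
# Ties in the cardinality label are broken by lowest vertex index.
# Returns the visit order and, per vertex, its already-visited neighbours
# ("prev" sets), plus a chordality flag from the Tarjan-Yannakakis check.
mcs_run <- function(a) {
  p <- nrow(a)
  w <- integer(p)            # cardinality labels
  visited <- logical(p)
  order <- integer(p)
  rank <- integer(p)         # position in visit order
  prev <- vector("list", p)  # earlier-visited neighbours of each vertex
  chordal <- TRUE
  for (k in seq_len(p)) {
    cand <- which(!visited)
    v <- cand[which.max(w[cand])]  # which.max takes the first max: lowest index
    visited[v] <- TRUE
    order[k] <- v
    rank[v] <- k
    pv <- which(a[, v] & visited)
    pv <- pv[pv != v]
    prev[[v]] <- pv
    if (chordal && length(pv) > 1L) {
      u <- pv[which.max(rank[pv])]  # most recently visited earlier neighbour
      rest <- pv[pv != u]
      if (!all(a[rest, u])) chordal <- FALSE
    }
    nb <- which(a[, v] & !visited)
    w[nb] <- w[nb] + 1L
  }
  list(order = order, rank = rank, prev = prev, chordal = chordal)
}

#' Test whether a graph is chordal (triangulated)
#'
#' A graph is chordal when it contains no chordless cycle of length four or
#' more. Decomposable graphical models are exactly those whose dependence
#' graph is chordal. The test runs maximum cardinality search and verifies
#' the resulting elimination ordering.
#'
#' @param g A `chrom_graph`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_chordal(chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4))))       # TRUE
#' is_chordal(chrom_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))) # FALSE
#' @export
is_chordal <- function(g) {
  mcs_run(cg_adj(g))$chordal
}

#' Triangulate a graph by maximum cardinality search
#'
#' Computes an MCS visit order (ties broken by lowest vertex index) and plays
#' the elimination game along the reverse of that order: vertices are
#' eliminated from last-visited to first, connecting the remaining neighbours
#' of each eliminated vertex. The output is a chordal supergraph of the
#' input; a chordal input is returned unchanged with no fill edges.
#'
#' @param g A `chrom_graph`.
#' @return A list with components `graph` (chordal `chrom_graph`) and
#'   `fill_edges` (two-column matrix of added edges).
#' @export
mcs_triangulate <- function(g) {
  a <- cg_adj(g)
  ord <- mcs_run(a)$order
  p <- g$p
  alive <- rep(TRUE, p)
  fill <- list()
  for (k in rev(seq_len(p))) {
    v <- ord[k]
    nb <- which(a[, v] & alive)
    nb <- nb[nb != v]
    if (length(nb) > 1L) {
      for (ii in seq_len(length(nb) - 1L)) {
        for (jj in seq.int(ii + 1L, length(nb))) {
          x <- nb[ii]; y <- nb[jj]
          if (!a[x, y]) {
            a[x, y] <- a[y, x] <- TRUE
            fill[[length(fill) + 1L]] <- c(x, y)
          }
        }
      }
    }
    alive[v] <- FALSE
  }
  fill <- if (length(fill)) do.call(rbind, fill) else NULL
  list(graph = adj_to_graph(a), fill_edges = canon_edges(fill))
}

#' Clique forest (junction forest) of a chordal graph
#'
#' Extracts the maximal cliques of a chordal graph together with a junction
#' forest over them: a forest of clique-index edges satisfying the running
#' intersection property, with one tree per connected component. Each forest
#' edge carries the separator, the intersection of its two endpoint cliques.
#' Uses the clique-tracking variant of maximum cardinality search.
#'
#' @param g A chordal `chrom_graph`.
#' @return An object of class `clique_forest`: list with `cliques` (list of
#'   sorted integer vectors), `tree_edges` (two-column matrix of clique
#'   indices), `separators` (list of sorted integer vectors, one per tree
#'   edge) and `p`.
#' @export
clique_forest <- function(g) {
  a <- cg_adj(g)
  mc <- mcs_run(a)
  if (!mc$chordal) stop("clique_forest() requires a chordal graph")
  p <- g$p
  cliques <- list()
  tree_edges <- list()
  separators <- list()
  home <- integer(p)  # clique a vertex was absorbed into at visit time
  cur <- 0L
  prev_w <- -1L
  for (k in seq_len(p)) {
    v <- mc$order[k]
    pv <- mc$prev[[v]]
    if (length(pv) <= prev_w) {
      # previous clique is complete; v starts a new clique {v} union prev(v)
      cur <- length(cliques) + 1L
      cliques[[cur]] <- sort(c(v, pv))
      if (length(pv) > 0L) {
        parent <- home[pv[which.max(mc$rank[pv])]]
        tree_edges[[length(tree_edges) + 1L]] <- c(parent, cur)
        separators[[length(separators) + 1L]] <- sort(pv)
      }
    } else if (cur == 0L) {
      cur <- 1L
      cliques[[1L]] <- v
    } else {
      cliques[[cur]] <- sort(c(cliques[[cur]], v))
    }
    home[v] <- cur
    prev_w <- length(pv)
  }
  tree_edges <- if (length(tree_edges)) do.call(rbind, tree_edges) else
    matrix(integer(), ncol = 2L)
  structure(
    list(cliques = cliques, tree_edges = tree_edges,
         separators = separators, p = p),
    class = "clique_forest"
  )
}

#' @export
print.clique_forest <- function(x, ...) {
  cat(sprintf("clique_forest: %d cliques, %d separators, max clique size %d\n",
              length(x$cliques), length(x$separators),
              if (length(x$cliques)) max(lengths(x$cliques)) else 0L))
  invisible(x)
}

# Shared core of the single-edge perturbation tests, on an adjacency matrix.
# Adding (a,b) to a chordal graph keeps it chordal iff the common
# neighbourhood S = N(a) & N(b) is complete and S separates a from b
# (or a and b lie in different components, in which case S is empty).
# When the move is legal the unique clique of the new graph containing both
# endpoints is {a, b} union S.
addable_adj <- function(adj, a, b) {
  s <- which(adj[, a] & adj[, b])
  if (length(s) > 1L) {
    sub <- adj[s, s, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) return(list(ok = FALSE, S = NULL))
  }
  # reachability of b from a avoiding S
  p <- nrow(adj)
  blocked <- logical(p)
  blocked[s] <- TRUE
  seen <- logical(p)
  seen[a] <- TRUE
  frontier <- a
  while (length(frontier) > 0L) {
    nxt <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & !seen & !blocked)
    if (any(nxt == b)) return(list(ok = FALSE, S = NULL))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  list(ok = TRUE, S = s)
}

# Removing (a,b) keeps chordality iff the edge lies in exactly one clique,
# which holds iff the common neighbourhood of a and b is complete; the host
# clique is then {a, b} union that neighbourhood.
removable_adj <- function(adj, a, b) {
  s <- which(adj[, a] & adj[, b])
  if (length(s) > 1L) {
    sub <- adj[s, s, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) return(list(ok = FALSE, S = NULL))
  }
  list(ok = TRUE, S = s)
}

#' Can an edge be added while preserving decomposability?
#'
#' Tests whether adding the edge `(a, b)` to a chordal graph yields a chordal
#' graph, i.e. whether the move stays inside the class of decomposable
#' models. When legal, the returned set `S` is such that exactly one clique
#' of the augmented graph contains both `a` and `b`, namely `{a, b} union S`;
#' `S` is the conditioning set used to score the move.
#'
#' @param g A chordal `chrom_graph`.
#' @param f Optional `clique_forest` of `g` (accepted for interface
#'   compatibility; the test is neighbourhood-based and does not need it).
#' @param a,b Distinct non-adjacent vertices.
#' @return List with `ok` (logical) and `S` (sorted integer vector, or `NULL`
#'   when `ok` is `FALSE`).
#' @export
edge_addable <- function(g, f = NULL, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) stop("'a' and 'b' must differ")
  adj <- cg_adj(g)
  if (adj[a, b]) stop("edge is already present")
  res <- addable_adj(adj, a, b)
  if (res$ok) list(ok = TRUE, S = res$S) else list(ok = FALSE, S = NULL)
}

#' Can an edge be removed while preserving decomposability?
#'
#' Tests whether deleting the edge `(a, b)` from a chordal graph yields a
#' chordal graph. This holds exactly when the edge lies in a single clique
#' `C`; the returned `S` is then `C` minus the endpoints.
#'
#' @inheritParams edge_addable
#' @return List with `ok` and `S` as in [edge_addable()].
#' @export
edge_removable <- function(g, f = NULL, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  adj <- cg_adj(g)
  if (!adj[a, b]) stop("edge is not present")
  res <- removable_adj(adj, a, b)
  if (res$ok) list(ok = TRUE, S = res$S) else list(ok = FALSE, S = NULL)
}

#' Connected components of a graph
#'
#' @param g A `chrom_graph`.
#' @return List of sorted integer vectors partitioning `1..p`, ordered by
#'   smallest member.
#' @export
connected_components <- function(g) {
  comp <- components_adj(cg_adj(g))
  # labels are assigned in order of smallest member, so split order is right
  unname(split(seq_len(g$p), comp))
}

# integer component labels from an adjacency matrix (labelled by discovery
# order from vertex 1 upwards, so labels are sorted by smallest member)
components_adj <- function(adj) {
  p <- nrow(adj)
  comp <- integer(p)
  lab <- 0L
  for (v in seq_len(p)) {
    if (comp[v] == 0L) {
      lab <- lab + 1L
      frontier <- v
      comp[v] <- lab
      while (length(frontier) > 0L) {
        nxt <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & comp == 0L)
        comp[nxt] <- lab
        frontier <- nxt
      }
    }
  }
  comp
}

#' Boundary of a vertex set
#'
#' The boundary `bd(A)` is the set of vertices outside `A` adjacent to some
#' vertex of `A`.
#'
#' @param g A `chrom_graph`.
#' @param A Integer vector of vertices.
#' @return Sorted integer vector.
#' @export
boundary <- function(g, A) {
  A <- as.integer(A)
  if (length(A) && (min(A) < 1L || max(A) > g$p)) stop("'A' must lie in 1..p")
  if (length(A) == 0L) return(integer())
  adj <- cg_adj(g)
  out <- which(rowSums(adj[, A, drop = FALSE]) > 0)
  sort(setdiff(out, A))
}

# validity checks used by tests and by simulate: maximality of cliques and
# the running intersection property relative to the forest ordering
check_clique_forest <- function(f, g) {
  adj <- cg_adj(g)
  for (cl in f$cliques) {
    if (length(cl) > 1L) {
      sub <- adj[cl, cl, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) return("clique not complete")
    }
    others <- which(rowSums(adj[, cl, drop = FALSE]) == length(cl))
    if (length(setdiff(others, cl)) > 0L) return("clique not maximal")
  }
  if (nrow(f$tree_edges) > 0L) {
    for (e in seq_len(nrow(f$tree_edges))) {
      c1 <- f$cliques[[f$tree_edges[e, 1L]]]
      c2 <- f$cliques[[f$tree_edges[e, 2L]]]
      if (!identical(sort(intersect(c1, c2)), f$separators[[e]])) {
        return("separator is not the endpoint intersection")
      }
    }
  }
  # running intersection via the rooted construction order: every clique's
  # intersection with the union of earlier cliques is inside its parent
  if (length(f$cliques) > 1L) {
    seen <- integer()
    parent_sep <- vector("list", length(f$cliques))
    if (nrow(f$tree_edges) > 0L) {
      for (e in seq_len(nrow(f$tree_edges))) {
        parent_sep[[f$tree_edges[e, 2L]]] <- f$separators[[e]]
      }
    }
    for (i in seq_along(f$cliques)) {
      inter <- intersect(f$cliques[[i]], seen)
      want <- parent_sep[[i]] %||% integer()
      if (!setequal(inter, want)) return("running intersection violated")
      seen <- union(seen, f$cliques[[i]])
    }
  }
  TRUE
}
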