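#' Search configuration
#'
#' Settings for the greedy model searches. The penalized likelihood
#' criterion is `IC(G) = -2 loglik + alpha dim(G)`; `criterion = "bic"`
#' resolves `alpha = log(N)` against the supplied data (N = number of rows,
#' so phased data are treated as a sample of 2 x individuals haplotypes)
#' and `"aic"` sets `alpha = 2`.
#'
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param alpha Optional explicit penalization constant overriding the
#'   criterion preset; must be positive.
#' @param dim_mode `"nominal"` or `"observed"` (see [model_dimension()]).
#' @param protect_skeleton_forward Keep the start graph's edges fixed
#'   during forward search (the forward phase only ever adds edges, so this
#'   is a statement of contract; pruning may later remove them).
#' @param max_span Optional cap on `|j - i|` for candidate edges; `NULL`
#'   (default) leaves candidates uncapped.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(criterion = c("bic", "aic"), alpha = NULL,
                             dim_mode = c("nominal", "observed"),
                             protect_skeleton_forward = TRUE,
                             max_span = NULL) {
  criterion <- match.arg(criterion)
  dim_mode <- match.arg(dim_mode)
  if (!is.null(alpha) && alpha <= 0) stop("'alpha' must be positive")
  structure(
    list(criterion = criterion, alpha = alpha, dim_mode = dim_mode,
         protect_skeleton_forward = isTRUE(protect_skeleton_forward),
         max_span = max_span),
    class = "selection_config"
  )
}

#' Blockwise (fast algorithm) configuration
#'
#' Block length `L` and overlap `K` for the linear-time blockwise forward
#' search. Defaults L = 100 and K = 20. The overlap should comfortably
#' exceed the expected maximum edge width so that boundary contamination
#' stays inside the discarded margin.
#'
#' @param L Block length (> K).
#' @param K Overlap between consecutive blocks (0 < K < L).
#' @return A list of class `fast_config`.
#' @export
fast_config <- function(L = 100L, K = 20L) {
  L <- as.integer(L); K <- as.integer(K)
  if (!(K > 0L && K < L)) stop("need 0 < K < L")
  structure(list(L = L, K = K), class = "fast_config")
}

resolve_alpha <- function(cfg, m) {
  if (!is.null(cfg$alpha)) return(cfg$alpha)
  if (cfg$criterion == "aic") 2 else log(m$n_rows)
}

#' The skeleton: serial graph of physically adjacent SNPs
#'
#' The start graph of the forward search: edges exactly between
#' consecutively positioned SNPs, `(i, i+1)` for `i = 1..p-1`. Every
#' interval of the skeleton has height and width 1.
#'
#' @param p Number of SNPs (>= 1).
#' @return A `chrom_graph`.
#' @export
skeleton <- function(p) {
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be >= 1")
  if (p == 1L) return(chrom_graph(1L))
  chrom_graph(p, cbind(seq_len(p - 1L), seq.int(2L, p)))
}

# Does 's' separate a from b in the graph given by 'adj'?  Bidirectional
# BFS expanding the smaller frontier; exhausting either side without
# touching the other means separation.
sep_check <- function(adj, a, b, s) {
  p <- nrow(adj)
  mark <- integer(p)  # 0 unseen, 1 a-side, 2 b-side, 3 blocked
  mark[s] <- 3L
  mark[a] <- 1L
  mark[b] <- 2L
  fa <- a
  fb <- b
  repeat {
    if (length(fa) == 0L || length(fb) == 0L) return(TRUE)
    if (length(fa) <= length(fb)) {
      nxt <- which(rowSums(adj[, fa, drop = FALSE]) > 0)
      if (any(mark[nxt] == 2L)) return(FALSE)
      nxt <- nxt[mark[nxt] == 0L]
      mark[nxt] <- 1L
      fa <- nxt
    } else {
      nxt <- which(rowSums(adj[, fb, drop = FALSE]) > 0)
      if (any(mark[nxt] == 1L)) return(FALSE)
      nxt <- nxt[mark[nxt] == 0L]
      mark[nxt] <- 2L
      fb <- nxt
    }
  }
}

# Cached IC delta of a single-edge move.  Deltas depend only on the data
# and on (a, b, S), so values survive across iterations in 'cache'.
delta_cached <- function(m, a, b, s, alpha, dim_mode, cache, direction) {
  key <- paste0(direction, "|", a, "|", b, "|", paste(s, collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- delta_score(m, NULL, a, b, s, alpha, direction, dim_mode)
  cache[[key]] <- d
  d
}

# One sweep over legal additions; returns NULL or the best move.
best_addition <- function(m, adj, alpha, dim_mode, max_span, cache) {
  p <- nrow(adj)
  comp <- components_adj(adj)
  storage.mode(adj) <- "logical"
  cn <- crossprod(adj)
  cand <- which(!adj & upper.tri(adj) & cn > 0, arr.ind = TRUE)
  if (length(comp) && max(comp) > 1L) {
    cross <- which(outer(comp, comp, "!=") & upper.tri(adj), arr.ind = TRUE)
    cand <- rbind(cand, cross)
  }
  if (nrow(cand) == 0L) return(NULL)
  if (!is.null(max_span)) {
    cand <- cand[cand[, 2L] - cand[, 1L] <= max_span, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
  }
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1L]
    b <- cand[k, 2L]
    if (comp[a] == comp[b]) {
      s <- which(adj[, a] & adj[, b])
      if (length(s) > 1L) {
        sub <- adj[s, s, drop = FALSE]
        if (!all(sub[upper.tri(sub)])) next
      }
      if (!sep_check(adj, a, b, s)) next
    } else {
      s <- integer()
    }
    d <- delta_cached(m, a, b, s, alpha, dim_mode, cache, "add")
    if (is.null(best) || d$d_ic < best$d_ic) {
      best <- list(a = a, b = b, S = s, d_ic = d$d_ic,
                   d_deviance = d$d_deviance, d_dim = d$d_dim)
    }
  }
  best
}

# One sweep over legal removals; returns NULL or the best move.
best_removal <- function(m, adj, alpha, dim_mode, cache) {
  g <- adj_to_graph(adj)
  if (nrow(g$edges) == 0L) return(NULL)
  best <- NULL
  for (k in seq_len(nrow(g$edges))) {
    a <- g$edges[k, 1L]
    b <- g$edges[k, 2L]
    s <- which(adj[, a] & adj[, b])
    if (length(s) > 1L) {
      sub <- adj[s, s, drop = FALSE]
      if (!all(sub[upper.tri(sub)])) next
    }
    d <- delta_cached(m, a, b, s, alpha, dim_mode, cache, "remove")
    if (is.null(best) || d$d_ic < best$d_ic) {
      best <- list(a = a, b = b, S = s, d_ic = d$d_ic,
                   d_deviance = d$d_deviance, d_dim = d$d_dim)
    }
  }
  best
}

fit_result <- function(m, start_graph, adj, trace_rows, separators, alpha,
                       dim_mode, tracked_ic, warnings) {
  g <- adj_to_graph(adj)
  f <- clique_forest(g)
  score <- model_score(m, f, alpha, dim_mode)
  if (length(trace_rows) > 0L && is.finite(tracked_ic) &&
      abs(tracked_ic - score$ic) > 1e-6 * max(1, abs(score$ic))) {
    warnings <- c(warnings, sprintf(
      "incremental score drifted from recomputation: %.8g vs %.8g",
      tracked_ic, score$ic))
  }
  trace <- if (length(trace_rows) > 0L) {
    do.call(rbind, lapply(trace_rows, function(r) {
      data.frame(a = r$a, b = r$b, direction = r$direction,
                 d_deviance = r$d_deviance, d_dim = r$d_dim, d_ic = r$d_ic)
    }))
  } else {
    data.frame(a = integer(), b = integer(), direction = character(),
               d_deviance = numeric(), d_dim = numeric(), d_ic = numeric())
  }
  structure(
    list(graph = g, forest = f, score = score, trace = trace,
         separators = separators, start_graph = start_graph,
         warnings = warnings),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  added <- sum(x$trace$direction == "add")
  removed <- sum(x$trace$direction == "remove")
  cat(sprintf(
    "fit_result: %d vertices, %d edges (%d added, %d removed), IC = %.2f\n",
    x$graph$p, nrow(x$graph$edges), added, removed, x$score$ic))
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

# shared greedy engine
greedy_phase <- function(m, g0, cfg, direction) {
  p <- n_markers(m)
  if (g0$p != p) stop("graph and data disagree on p")
  adj <- cg_adj(g0)
  if (!mcs_run(adj)$chordal) stop("start graph must be chordal")
  alpha <- resolve_alpha(cfg, m)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  score0 <- model_score(m, clique_forest(g0), alpha, cfg$dim_mode)
  ic <- score0$ic
  trace_rows <- list()
  separators <- list()
  warnings <- character()
  repeat {
    mv <- if (direction == "add") {
      best_addition(m, adj, alpha, cfg$dim_mode, cfg$max_span, cache)
    } else {
      best_removal(m, adj, alpha, cfg$dim_mode, cache)
    }
    if (is.null(mv) || mv$d_ic >= 0) break
    val <- direction == "remove"
    adj[mv$a, mv$b] <- adj[mv$b, mv$a] <- !val
    ic <- ic + mv$d_ic
    trace_rows[[length(trace_rows) + 1L]] <-
      list(a = mv$a, b = mv$b, direction = direction,
           d_deviance = mv$d_deviance, d_dim = mv$d_dim, d_ic = mv$d_ic)
    separators[[length(separators) + 1L]] <- mv$S
  }
  fit_result(m, g0, adj, trace_rows, separators, alpha, cfg$dim_mode, ic,
             warnings)
}

#' Greedy forward search over decomposable models
#'
#' Starting from a chordal graph (normally the [skeleton()]), repeatedly
#' adds the eligible edge with the largest IC reduction, considering only
#' edges whose inclusion keeps the graph chordal, until no addition
#' improves the criterion. Ties are broken by the lexicographically
#' smallest `(i, j)` pair. Every intermediate graph is chordal and contains
#' the start graph.
#'
#' @param m A [marker_matrix()].
#' @param g0 Chordal start graph.
#' @param cfg A [selection_config()].
#' @return A `fit_result`: final `graph`, its `forest`, `score`, the move
#'   `trace` (with separators), the `start_graph` and accumulated
#'   `warnings`.
#' @export
forward_search <- function(m, g0, cfg = selection_config()) {
  greedy_phase(m, g0, cfg, "add")
}

#' Greedy backward pruning of a decomposable model
#'
#' Repeatedly removes the edge (skeletal edges included) whose deletion
#' keeps the graph chordal and most reduces the IC, until no removal
#' improves the criterion.
#'
#' @inheritParams forward_search
#' @param g Chordal graph to prune.
#' @return A `fit_result`.
#' @export
backward_prune <- function(m, g, cfg = selection_config()) {
  greedy_phase(m, g, cfg, "remove")
}

#' Standard forward-backward model selection
#'
#' Forward search from the skeleton followed by backward pruning: the
#' reference (non-blockwise) algorithm.
#'
#' @inheritParams forward_search
#' @return A `fit_result` whose trace concatenates both phases (replayable
#'   from the skeleton).
#' @export
fit_standard <- function(m, cfg = selection_config()) {
  fwd <- forward_search(m, skeleton(n_markers(m)), cfg)
  bwd <- backward_prune(m, fwd$graph, cfg)
  bwd$trace <- rbind(fwd$trace, bwd$trace)
  bwd$separators <- c(fwd$separators, bwd$separators)
  bwd$start_graph <- fwd$start_graph
  bwd$warnings <- c(fwd$warnings, bwd$warnings)
  bwd
}

#' Block boundaries of the fast algorithm
#'
#' Block `i` spans `[(i-1)(L-K)+1, (i-1)(L-K)+L]`, truncated at `p`;
#' generation stops once a block reaches `p`, and a final block that would
#' be entirely contained in the overlap (length <= K) is merged into the
#' previous one.
#'
#' @param p Number of SNPs.
#' @param fc A [fast_config()].
#' @return Two-column integer matrix of `(start, end)` rows.
#' @export
block_bounds <- function(p, fc = fast_config()) {
  p <- as.integer(p)
  if (p < 1L) stop("'p' must be >= 1")
  L <- fc$L; K <- fc$K
  out <- list()
  i <- 1L
  repeat {
    s <- (i - 1L) * (L - K) + 1L
    e <- min(s + L - 1L, p)
    if (i > 1L && e - s + 1L <= K) break  # contained in the previous block
    out[[i]] <- c(s, e)
    if (e >= p) break
    i <- i + 1L
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

#' Stitch a block estimate onto the cumulative graph
#'
#' Implements the overlap rule for combining the cumulative estimate on
#' `1..e` with the next block's estimate on `[s, e']`, where `s = e - K + 1`.
#' With `m* = max{w : (v, w) in cumulative edges, v <= s - 1}`, the merged
#' edge set keeps cumulative edges with `w <= m*` and block edges with
#' `w > m*`: marginal models can carry spurious boundary associations, and
#' the discarded margins are exactly where those live. If `m*` reaches the
#' block's own right-looking boundary (i.e. `m* >= min{v : (v, w) in block
#' edges, w >= e + 1}`), the overlap `K` was too small; a warning is
#' recorded and the run proceeds.
#'
#' @param state List with `cum_edges` (edge matrix on `1..e`), `e`,
#'   `m_star`, `violated`, `warnings`.
#' @param block_edges Edge matrix of the block estimate, in chromosome
#'   coordinates within `[block_start, block_end]`.
#' @param block_start,block_end Block span.
#' @param cum_end Right end `e` of the cumulative graph (default
#'   `state$e`).
#' @param K Overlap; when supplied, the precondition
#'   `block_start == cum_end - K + 1` is enforced.
#' @return Updated state.
#' @export
stitch <- function(state, block_edges, block_start, block_end,
                   cum_end = state$e, K = NULL) {
  s <- as.integer(block_start)
  e <- as.integer(cum_end)
  if (!is.null(K) && s != e - as.integer(K) + 1L) {
    stop("block_start must equal cum_end - K + 1")
  }
  block_edges <- canon_edges(block_edges)
  if (nrow(block_edges) > 0L &&
      (min(block_edges) < s || max(block_edges) > block_end)) {
    stop("block edges outside the block span")
  }
  cum <- canon_edges(state$cum_edges)
  left <- cum[, 1L] <= s - 1L
  m_star <- if (any(left)) max(cum[left, 2L]) else s - 1L
  violated <- FALSE
  if (nrow(block_edges) > 0L) {
    fwd <- block_edges[, 2L] >= e + 1L
    if (any(fwd) && m_star >= min(block_edges[fwd, 1L])) {
      violated <- TRUE
    }
  }
  keep_cum <- cum[cum[, 2L] <= m_star, , drop = FALSE]
  keep_blk <- block_edges[block_edges[, 2L] > m_star, , drop = FALSE]
  warnings <- state$warnings
  if (violated) {
    warnings <- c(warnings, sprintf(
      "overlap too small at block starting %d: m* = %d reaches the block boundary",
      s, m_star))
    warning(warnings[length(warnings)], call. = FALSE)
  }
  list(cum_edges = canon_edges(rbind(keep_cum, keep_blk)),
       e = as.integer(block_end), m_star = m_star,
       violated = state$violated || violated, warnings = warnings)
}

#' Fast blockwise forward search
#'
#' Runs the greedy forward search independently on overlapping blocks of
#' `L` SNPs (each from its own internal skeleton), folds the block
#' estimates left to right through [stitch()], and triangulates the result
#' with [mcs_triangulate()]. Runtime is linear in `p` for fixed block
#' length.
#'
#' @inheritParams forward_search
#' @param fc A [fast_config()].
#' @return List with `graph` (chordal, contains the skeleton),
#'   `fill_edges` added by triangulation, and `warnings`.
#' @export
fast_forward <- function(m, cfg = selection_config(), fc = fast_config()) {
  p <- n_markers(m)
  bounds <- block_bounds(p, fc)
  state <- NULL
  warnings <- character()
  for (i in seq_len(nrow(bounds))) {
    s <- bounds[i, 1L]; e <- bounds[i, 2L]
    sub <- mm_subset(m, s:e)
    fr <- forward_search(sub, skeleton(e - s + 1L), cfg)
    warnings <- c(warnings, fr$warnings)
    edges <- fr$graph$edges
    if (nrow(edges) > 0L) edges <- edges + (s - 1L)
    if (i == 1L) {
      state <- list(cum_edges = canon_edges(edges), e = e, m_star = NA_integer_,
                    violated = FALSE, warnings = character())
    } else {
      state <- withCallingHandlers(
        stitch(state, edges, s, e, K = fc$K),
        warning = function(w) invokeRestart("muffleWarning"))
    }
  }
  tri <- mcs_triangulate(chrom_graph(p, state$cum_edges))
  list(graph = tri$graph, fill_edges = tri$fill_edges,
       warnings = c(warnings, state$warnings))
}

#' Fast forward-backward model selection
#'
#' The linear-time variant: [fast_forward()] followed by
#' [backward_prune()] on the full data.
#'
#' @inheritParams fast_forward
#' @return A `fit_result` (warnings from the blockwise phase propagated).
#' @export
fit_fast <- function(m, cfg = selection_config(), fc = fast_config()) {
  ff <- fast_forward(m, cfg, fc)
  res <- backward_prune(m, ff$graph, cfg)
  res$warnings <- c(ff$warnings, res$warnings)
  res
}
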