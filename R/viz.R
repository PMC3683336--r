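#' LD-graph layout along the chromosome
#'
#' Deterministic layout for long, thin LD graphs: the x-coordinate of every
#' vertex is its SNP index, and y-coordinates are exponentially smoothed in
#' SNP order, `y~_1 = y_1`, `y~_i = lambda y~_(i-1) + (1 - lambda) y_i`.
#' Initial y values come from a dependency-light heuristic: the number of
#' non-skeleton edges incident to a vertex, sign-alternated by index, so
#' that purely serial regions sit flat on the axis and structurally complex
#' regions oscillate away from it. Vertices far from the axis therefore
#' flag regions of complex LD.
#'
#' @param g A `chrom_graph`.
#' @param lambda Smoothing constant in `[0, 1)`; default 0.7.
#' @return Object of class `ld_layout`: list with `x` (= 1..p), `y`,
#'   `lambda`.
#' @export
layout_graph <- function(g, lambda = 0.7) {
  if (lambda < 0 || lambda >= 1) stop("'lambda' must be in [0, 1)")
  p <- g$p
  extra <- integer(p)
  if (nrow(g$edges) > 0L) {
    span <- g$edges[, 2L] - g$edges[, 1L]
    ns <- g$edges[span > 1L, , drop = FALSE]
    if (nrow(ns) > 0L) {
      tab <- tabulate(c(ns[, 1L], ns[, 2L]), nbins = p)
      extra <- tab
    }
  }
  y0 <- extra * ifelse(seq_len(p) %% 2L == 0L, 1, -1)
  y <- numeric(p)
  y[1L] <- y0[1L]
  for (i in seq_len(p)[-1L]) y[i] <- lambda * y[i - 1L] + (1 - lambda) * y0[i]
  structure(list(x = seq_len(p), y = y, lambda = lambda),
            class = "ld_layout")
}

#' Plot an LD graph
#'
#' Draws vertices at their layout coordinates and edges as segments, and
#' writes a GraphML sidecar (same path plus `.graphml`) carrying the
#' coordinates for external viewers.
#'
#' @param g A `chrom_graph`.
#' @param layout An [layout_graph()] result for `g` (computed when `NULL`).
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_ld_graph <- function(g, layout = NULL, path, width = 1600,
                          height = 400) {
  if (is.null(layout)) layout <- layout_graph(g)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 1, 1))
  graphics::plot(layout$x, layout$y, pch = 16, cex = 0.4,
                 xlab = "SNP index", ylab = "", las = 1)
  if (nrow(g$edges) > 0L) {
    graphics::segments(layout$x[g$edges[, 1L]], layout$y[g$edges[, 1L]],
                       layout$x[g$edges[, 2L]], layout$y[g$edges[, 2L]],
                       col = grDevices::grey(0.3))
  }
  write_layout_graphml(g, layout, paste0(path, ".graphml"))
  invisible(path)
}

write_layout_graphml <- function(g, layout, path) {
  nodes <- sprintf(
    '    <node id="n%d"><data key="x">%d</data><data key="y">%.6g</data></node>',
    seq_len(g$p), layout$x, layout$y)
  edges <- if (nrow(g$edges) > 0L) {
    sprintf('    <edge source="n%d" target="n%d"/>',
            g$edges[, 1L], g$edges[, 2L])
  } else {
    character()
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="x" for="node" attr.name="x" attr.type="double"/>',
    '  <key id="y" for="node" attr.name="y" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    nodes, edges, "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' Union of several LD graphs with edge frequencies
#'
#' Used to display model uncertainty across replicate fits: the union graph
#' carries, for each edge, the number of input graphs containing it.
#'
#' @param graphs List of `chrom_graph`s sharing the same `p`.
#' @return Object of class `edge_frequency_map`: list with `p`, `edges`
#'   (union edge matrix), `freq` (per-edge counts) and `n_graphs`.
#' @export
union_graphs <- function(graphs) {
  if (length(graphs) == 0L) stop("need at least one graph")
  p <- graphs[[1L]]$p
  for (g in graphs) {
    if (g$p != p) stop("all graphs must share the same vertex count")
  }
  keys <- lapply(graphs, function(g) {
    g$edges[, 1L] * (p + 1) + g$edges[, 2L]
  })
  all_keys <- sort(unique(unlist(keys)))
  freq <- integer(length(all_keys))
  for (k in keys) freq <- freq + (all_keys %in% k)
  edges <- cbind(all_keys %/% (p + 1), all_keys %% (p + 1))
  structure(
    list(p = p, edges = canon_edges(edges), freq = freq[order(
      all_keys %/% (p + 1), all_keys %% (p + 1))],
      n_graphs = length(graphs)),
    class = "edge_frequency_map"
  )
}

#' Plot an edge-frequency union graph
#'
#' Edges found in every input graph are black; the rest are interpolated
#' from light blue (rare) to blue (frequent).
#'
#' @param efm An [union_graphs()] result.
#' @param layout Optional [layout_graph()] layout for the union graph.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_union_graph <- function(efm, layout = NULL, path) {
  g <- chrom_graph(efm$p, efm$edges)
  if (is.null(layout)) layout <- layout_graph(g)
  ramp <- grDevices::colorRamp(c("lightblue", "blue"))
  cols <- vapply(efm$freq, function(f) {
    if (f >= efm$n_graphs) return("black")
    rgb <- ramp((f - 1) / max(efm$n_graphs - 1, 1))
    grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
  }, character(1))
  grDevices::png(path, width = 1600, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 1, 1))
  graphics::plot(layout$x, layout$y, pch = 16, cex = 0.4,
                 xlab = "SNP index", ylab = "", las = 1)
  if (nrow(g$edges) > 0L) {
    graphics::segments(layout$x[g$edges[, 1L]], layout$y[g$edges[, 1L]],
                       layout$x[g$edges[, 2L]], layout$y[g$edges[, 2L]],
                       col = cols)
  }
  invisible(path)
}

#' Triangular heatmap of pairwise LD values
#'
#' Renders the upper triangle of a symmetric r-squared matrix; values are
#' clipped to `[0, 1]` before colouring.
#'
#' @param ld Symmetric numeric matrix (e.g. from [pairwise_ld()]).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(ld, path) {
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld)) stop("LD matrix must be square")
  v <- pmin(pmax(ld, 0), 1)
  n <- nrow(v)
  v[lower.tri(v)] <- NA
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(3, 3, 1, 1))
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, 1), xlab = "", ylab = "", axes = FALSE)
  graphics::box()
  invisible(path)
}
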