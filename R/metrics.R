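#' Interval heights and widths of an LD graph
#'
#' For each of the `p - 1` intervals between consecutive SNPs, the height
#' `h_i` is the number of edges `(j, k)` with `j <= i < k` spanning the
#' interval, and the width `w_i` is the maximum `k - j` over those edges
#' (0 when none). By the global Markov property `h_i = 0` means the SNPs up
#' to `i` are independent of those after `i`; `h_i = 1` (the skeleton case)
#' means they are independent given `v_i`.
#'
#' @param g A `chrom_graph`.
#' @return Object of class `interval_profile`: list with `heights` and
#'   `widths`, each of length `p - 1`.
#' @export
heights_widths <- function(g) {
  p <- g$p
  h <- integer(max(p - 1L, 0L))
  w <- integer(max(p - 1L, 0L))
  if (nrow(g$edges) > 0L) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
      idx <- i:(j - 1L)
      h[idx] <- h[idx] + 1L
      w[idx] <- pmax(w[idx], j - i)
    }
  }
  structure(list(heights = h, widths = w), class = "interval_profile")
}

#' Sliding-window haplotype entropy
#'
#' For each window of `window` adjacent SNPs, the entropy
#' `H = -sum_i f_i log f_i` (nats) of the relative frequencies of the
#' distinct rows observed in that window. Large values mean many distinct,
#' similarly frequent haplotypes. Intended for phased haplotype data;
#' genotype input is accepted and then measures diversity of multilocus
#' genotypes instead.
#'
#' @param m A [marker_matrix()].
#' @param window Window length in SNPs (default 7).
#' @return Object of class `entropy_profile`: list with `window`,
#'   `window_starts` and `values` (H in nats, `0 <= H <= log(N)`).
#' @export
window_entropy <- function(m, window = 7L) {
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1")
  p <- n_markers(m)
  if (window > p) stop("'window' exceeds the number of SNPs")
  n <- m$n_rows
  starts <- seq_len(p - window + 1L)
  vals <- vapply(starts, function(i) {
    cnt <- joint_code(m$values[, i:(i + window - 1L), drop = FALSE])$counts
    f <- cnt / n
    -sum(f * log(f))
  }, numeric(1))
  structure(list(window = window, window_starts = starts, values = vals),
            class = "entropy_profile")
}

#' Median window entropy grouped by interval complexity
#'
#' Assigns each entropy window to the inter-SNP interval at its centre
#' (ties resolved to the left) and reports the median entropy for each
#' observed height value and each observed width value — the summary
#' behind "diversity increases with structural complexity" displays.
#'
#' @param ep An [window_entropy()] profile.
#' @param ip A [heights_widths()] profile over the same `p`.
#' @return List with data frames `by_height` and `by_width` (columns
#'   `height`/`width`, `median_entropy`, `n_windows`).
#' @export
entropy_by_complexity <- function(ep, ip) {
  if (length(ep$values) == 0L) {
    empty <- data.frame(value = integer(), median_entropy = numeric(),
                        n_windows = integer())
    return(list(by_height = stats::setNames(empty, c("height", "median_entropy", "n_windows")),
                by_width = stats::setNames(empty, c("width", "median_entropy", "n_windows"))))
  }
  # window starting at i spans intervals i .. i+window-2; centre, ties left
  centre <- ep$window_starts + (ep$window - 2L) %/% 2L
  centre <- pmin(pmax(centre, 1L), length(ip$heights))
  grp <- function(key, name) {
    agg <- vapply(split(ep$values, key), stats::median, numeric(1))
    cnt <- vapply(split(ep$values, key), length, integer(1))
    out <- data.frame(as.integer(names(agg)), unname(agg), unname(cnt))
    names(out) <- c(name, "median_entropy", "n_windows")
    out[order(out[[name]]), , drop = FALSE]
  }
  list(by_height = grp(ip$heights[centre], "height"),
       by_width = grp(ip$widths[centre], "width"))
}

#' Sample tree (prefix trie) of a genomic interval
#'
#' Summarizes the haplotypes observed over a short interval as a rooted
#' trie: each non-root node is a prefix `(x_from, ..., x_k)` present in the
#' data, each edge carries the extending allele code and the number of
#' observations passing through it. Children are ordered by allele code.
#'
#' @param m A [marker_matrix()].
#' @param interval Length-2 vector `(from, to)`, `1 <= from <= to <= p`.
#' @return Object of class `sample_tree`: list with `nodes` (data frame
#'   `id`, `depth`, `count`; id 0 is the root with count N) and `edges`
#'   (data frame `parent`, `child`, `code`, `count`).
#' @export
sample_tree <- function(m, interval) {
  from <- as.integer(interval[1L]); to <- as.integer(interval[2L])
  if (!(from >= 1L && from <= to && to <= n_markers(m))) {
    stop("invalid interval")
  }
  x <- m$values[, from:to, drop = FALSE]
  n <- nrow(x)
  q <- ncol(x)
  nodes <- data.frame(id = 0L, depth = 0L, count = n)
  edges <- data.frame(parent = integer(), child = integer(),
                      code = integer(), count = integer())
  # parent node id of each observation at current depth
  parent_of <- rep.int(0L, n)
  next_id <- 1L
  for (k in seq_len(q)) {
    key <- paste(parent_of, x[, k])
    # order groups by (parent, code) so children come out code-sorted
    groups <- split(seq_len(n), key)
    pk <- vapply(groups, function(ix) parent_of[ix[1L]], integer(1))
    ck <- vapply(groups, function(ix) x[ix[1L], k], integer(1))
    ord <- order(pk, ck)
    new_parent <- integer(n)
    for (gi in ord) {
      ix <- groups[[gi]]
      id <- next_id
      next_id <- next_id + 1L
      nodes <- rbind(nodes, data.frame(id = id, depth = k,
                                       count = length(ix)))
      edges <- rbind(edges, data.frame(parent = pk[gi], child = id,
                                       code = ck[gi], count = length(ix)))
      new_parent[ix] <- id
    }
    parent_of <- new_parent
  }
  structure(list(nodes = nodes, edges = edges, interval = c(from, to)),
            class = "sample_tree")
}

#' Export a sample tree as a DOT file
#'
#' Root on the left (left-to-right rank direction), edge width proportional
#' to the observation count, edges coloured by allele code.
#'
#' @param tree A [sample_tree()].
#' @param path Output path.
#' @param palette Colours indexed by allele code + 1.
#' @return `path`, invisibly.
#' @export
sample_tree_dot <- function(tree, path,
                            palette = c("red", "blue", "darkgreen")) {
  n <- tree$nodes$count[tree$nodes$id == 0L]
  lines <- c("digraph sample_tree {", "  rankdir=LR;",
             "  node [shape=point];")
  for (k in seq_len(nrow(tree$edges))) {
    e <- tree$edges[k, ]
    col <- palette[(e$code %% length(palette)) + 1L]
    lines <- c(lines, sprintf(
      '  n%d -> n%d [color="%s", penwidth=%.3f, label="%d"];',
      e$parent, e$child, col, 0.5 + 6 * e$count / n, e$code))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Pairwise LD (r-squared) matrix
#'
#' For haplotype data this is the classical haplotype `r^2` (squared
#' Pearson correlation of the 0/1 allele indicators); for genotype data the
#' squared correlation of the 0/1/2 codes (composite LD). Monomorphic
#' columns have undefined correlation and are reported as 0, flagged in the
#' `monomorphic` attribute.
#'
#' @param m A [marker_matrix()].
#' @param interval Length-2 vector `(from, to)`; default the whole range.
#' @return Symmetric matrix of values in `[0, 1]` with unit diagonal for
#'   polymorphic columns, and attribute `monomorphic` (logical vector).
#' @export
pairwise_ld <- function(m, interval = c(1L, n_markers(m))) {
  from <- as.integer(interval[1L]); to <- as.integer(interval[2L])
  if (!(from >= 1L && from <= to && to <= n_markers(m))) {
    stop("invalid interval")
  }
  x <- m$values[, from:to, drop = FALSE]
  mono <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  r2 <- suppressWarnings(stats::cor(x))^2
  r2[!is.finite(r2)] <- 0
  diag(r2)[mono] <- 0
  dimnames(r2) <- list(m$marker_ids[from:to], m$marker_ids[from:to])
  attr(r2, "monomorphic") <- mono
  r2
}

#' Write an interval profile as TSV
#' @param ip A [heights_widths()] profile.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_profile <- function(ip, path) {
  utils::write.table(
    data.frame(interval = seq_along(ip$heights), height = ip$heights,
               width = ip$widths),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an entropy profile as TSV
#' @param ep An [window_entropy()] profile.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(ep, path) {
  utils::write.table(
    data.frame(start = ep$window_starts, entropy = ep$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
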