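# Internal helpers shared across modules.

# Encode the rows of an integer matrix as group ids 1..k.
# Returns ids, the distinct configurations (rows, in code order) and counts.
# Uses mixed-radix packing into doubles; exact for < 2^53 states, far beyond
# any clique size this package ever forms.
joint_code <- function(x) {
  n <- nrow(x)
  if (ncol(x) == 0L) {
    return(list(
      id = rep.int(1L, n),
      configs = matrix(integer(), nrow = 1L, ncol = 0L),
      counts = n
    ))
  }
  code <- numeric(n)
  for (j in seq_len(ncol(x))) {
    base <- max(x[, j]) + 1
    code <- code * base + x[, j]
  }
  u <- sort(unique(code))
  id <- match(code, u)
  first <- match(u, code)
  list(
    id = id,
    configs = x[first, , drop = FALSE],
    counts = tabulate(id, nbins = length(u))
  )
}

# sum of n * log(n / N) over positive counts (0 log 0 := 0)
nlogn_sum <- function(counts, n_total) {
  counts <- counts[counts > 0]
  sum(counts * log(counts / n_total))
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# canonical edge matrix: 2 integer columns, i < j, sorted lexicographically
canon_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

`%||%` <- function(a, b) if (is.null(a)) b else a
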