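# Independent oracles and fixture builders used across the test files.

# --- graph helpers ----------------------------------------------------------

edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) return(character())
  paste(g$edges[, 1L], g$edges[, 2L])
}

graphs_equal <- function(g1, g2) {
  g1$p == g2$p && setequal(edge_keys(g1), edge_keys(g2))
}

# random chordal graph built by decomposability-preserving random additions
# on top of a start graph (skeleton by default)
rand_chordal <- function(p, n_extra, start = skeleton(p), max_tries = 200L) {
  g <- start
  placed <- 0L
  tries <- 0L
  while (placed < n_extra && tries < max_tries) {
    tries <- tries + 1L
    a <- sample.int(p, 1L)
    b <- sample.int(p, 1L)
    if (a == b) next
    e <- sort(c(a, b))
    if (paste(e[1L], e[2L]) %in% edge_keys(g)) next
    chk <- edge_addable(g, NULL, e[1L], e[2L])
    if (chk$ok) {
      g <- chrom_graph(p, rbind(g$edges, e))
      placed <- placed + 1L
    }
  }
  g
}

# independent chordality oracle: recursive simplicial-vertex elimination.
# A graph is chordal iff one can repeatedly delete a vertex whose
# neighbourhood is complete.
oracle_is_chordal <- function(g) {
  adj <- matrix(FALSE, g$p, g$p)
  if (nrow(g$edges) > 0L) {
    adj[g$edges] <- TRUE
    adj[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  alive <- rep(TRUE, g$p)
  repeat {
    verts <- which(alive)
    if (length(verts) == 0L) return(TRUE)
    found <- FALSE
    for (v in verts) {
      nb <- which(adj[, v] & alive)
      nb <- nb[nb != v]
      ok <- TRUE
      if (length(nb) > 1L) {
        sub <- adj[nb, nb, drop = FALSE]
        ok <- all(sub[upper.tri(sub)])
      }
      if (ok) {
        alive[v] <- FALSE
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
}

# elimination-game fill oracle: eliminate vertices in the given order,
# connecting remaining neighbours of each eliminated vertex; returns the
# number of fill edges added
oracle_elimination_fill <- function(g, order) {
  adj <- matrix(FALSE, g$p, g$p)
  if (nrow(g$edges) > 0L) {
    adj[g$edges] <- TRUE
    adj[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  alive <- rep(TRUE, g$p)
  fill <- 0L
  for (v in order) {
    nb <- which(adj[, v] & alive)
    nb <- nb[nb != v]
    if (length(nb) > 1L) {
      for (i in seq_len(length(nb) - 1L)) {
        for (j in seq.int(i + 1L, length(nb))) {
          if (!adj[nb[i], nb[j]]) {
            adj[nb[i], nb[j]] <- adj[nb[j], nb[i]] <- TRUE
            fill <- fill + 1L
          }
        }
      }
    }
    alive[v] <- FALSE
  }
  fill
}

# --- scoring oracles --------------------------------------------------------

# brute-force conditional mutual information by explicit cell loops
oracle_cmi <- function(x, a, b, S) {
  n <- nrow(x)
  keyS <- if (length(S) == 0L) rep("", n) else
    apply(x[, S, drop = FALSE], 1L, paste, collapse = ",")
  total <- 0
  for (s in unique(keyS)) {
    rows <- which(keyS == s)
    ns <- length(rows)
    for (va in unique(x[rows, a])) {
      for (vb in unique(x[rows, b])) {
        nab <- sum(x[rows, a] == va & x[rows, b] == vb)
        if (nab == 0L) next
        na <- sum(x[rows, a] == va)
        nb <- sum(x[rows, b] == vb)
        total <- total + (nab / n) * log(nab * ns / (na * nb))
      }
    }
  }
  total
}

# direct evaluation oracle for the decomposable log-likelihood: the fitted
# probability of each observed row is the product of empirical clique
# probabilities divided by the product of empirical separator probabilities
oracle_loglik <- function(x, cliques, separators) {
  n <- nrow(x)
  ll <- 0
  logp_set <- function(set) {
    if (length(set) == 0L) return(rep(0, n))
    key <- apply(x[, set, drop = FALSE], 1L, paste, collapse = ",")
    cnt <- table(key)
    log(as.numeric(cnt[key]) / n)
  }
  for (cl in cliques) ll <- ll + sum(logp_set(cl))
  for (s in separators) ll <- ll - sum(logp_set(s))
  ll
}

# --- data fixtures ----------------------------------------------------------

rand_mm <- function(n, p, kind = "haplotype") {
  r <- if (kind == "haplotype") 2L else 3L
  marker_matrix(matrix(sample.int(r, n * p, replace = TRUE) - 1L, n, p),
                kind)
}

# serially correlated binary data: each column copies the previous one
# with probability 1 - flip
serial_mm <- function(n, p, flip = 0.1) {
  x <- matrix(0L, n, p)
  x[, 1L] <- sample(0:1, n, replace = TRUE)
  for (j in seq_len(p)[-1L]) {
    f <- stats::runif(n) < flip
    x[, j] <- ifelse(f, 1L - x[, j - 1L], x[, j - 1L])
  }
  marker_matrix(x, "haplotype")
}

write_tiny_vcf <- function(path, gts, ids = NULL, positions = NULL,
                           alts = NULL) {
  # gts: matrix of GT strings, variants x samples
  nv <- nrow(gts)
  ns <- ncol(gts)
  if (is.null(ids)) ids <- paste0("rs", seq_len(nv))
  if (is.null(positions)) positions <- seq_len(nv) * 100L
  if (is.null(alts)) alts <- rep("T", nv)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_len(ns))), collapse = "\t"))
  rows <- vapply(seq_len(nv), function(i) {
    paste(c("1", positions[i], ids[i], "A", alts[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

has_variantannotation <- function() {
  requireNamespace("VariantAnnotation", quietly = TRUE) &&
    requireNamespace("SummarizedExperiment", quietly = TRUE) &&
    requireNamespace("GenomicRanges", quietly = TRUE)
}
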