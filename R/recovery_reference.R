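#' Bundled reference recovery counts
#'
#' Loads the packaged table of edgewise undershoot/overshoot counts from a
#' chromosome-scale simulation benchmark: ten replicates sampled from a
#' serial skeleton model (p = 2863, 2862 edges) and ten from a fitted
#' LD-graph model (4340 edges), each refitted with the fast
#' forward-backward algorithm under BIC. Used to pin down the rate
#' definitions of [edge_recovery_rates()].
#'
#' @return List with `counts` (data frame of per-replicate counts),
#'   `true_edges_skeleton` and `true_edges_ldgraph`.
#' @export
recovery_reference <- function() {
  path <- system.file("extdata", "recovery_reference.tsv",
                      package = "ldgraph", mustWork = TRUE)
  lines <- readLines(path)
  get_const <- function(key) {
    as.integer(sub(sprintf("^#\\s*%s:\\s*", key), "",
                   grep(sprintf("^#\\s*%s:", key), lines, value = TRUE)[1L]))
  }
  counts <- utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#")
  list(counts = counts,
       true_edges_skeleton = get_const("true_edges_skeleton"),
       true_edges_ldgraph = get_const("true_edges_ldgraph"))
}

#' Mean edgewise recovery rates over replicates
#'
#' The edgewise false negative rate is the mean undershoot divided by the
#' number of true edges; the false inclusion rate is the mean overshoot
#' divided by the same denominator (both counts normalized by `|E_true|`).
#'
#' @param undershoot,overshoot Integer vectors of per-replicate counts.
#' @param n_true_edges Number of edges of the generating graph.
#' @return List with `fnr` and `fir`.
#' @export
edge_recovery_rates <- function(undershoot, overshoot, n_true_edges) {
  if (n_true_edges <= 0) stop("'n_true_edges' must be positive")
  list(fnr = mean(undershoot) / n_true_edges,
       fir = mean(overshoot) / n_true_edges)
}
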