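#' Joint count table over a set of markers
#'
#' Exact joint counts of the observed configurations of the listed columns,
#' keyed in the given column order. These are the sufficient statistics of
#' a decomposable model: its maximized likelihood is a function of clique
#' and separator count tables only.
#'
#' @param m A [marker_matrix()].
#' @param vars Non-empty vector of distinct column indices.
#' @return Object of class `count_table`: list with `vars`, `configs`
#'   (matrix of distinct observed code tuples, one row per cell), `counts`
#'   and `total` (= N).
#' @export
count_table <- function(m, vars) {
  vars <- as.integer(vars)
  if (length(vars) == 0L) stop("'vars' must be non-empty")
  if (anyDuplicated(vars)) stop("'vars' must be distinct")
  if (min(vars) < 1L || max(vars) > n_markers(m)) {
    stop("'vars' outside 1..p")
  }
  jc <- joint_code(m$values[, vars, drop = FALSE])
  structure(
    list(vars = vars, configs = jc$configs, counts = jc$counts,
         total = m$n_rows),
    class = "count_table"
  )
}

#' Maximized log-likelihood of a decomposable model
#'
#' For a chordal graph with cliques `C` and separators `S`, the maximized
#' log-likelihood of the data is
#' `sum_C sum_cells n(x_C) log(n(x_C)/N) - sum_S sum_cells n(x_S) log(n(x_S)/N)`
#' in nats, with `0 log 0 = 0`. Isolated vertices are singleton cliques and
#' contribute their univariate terms.
#'
#' @param m A [marker_matrix()].
#' @param f A [clique_forest()] on the columns of `m`.
#' @return Log-likelihood in nats.
#' @export
decomposable_loglik <- function(m, f) {
  n <- m$n_rows
  ll <- 0
  for (cl in f$cliques) {
    if (max(cl) > n_markers(m)) stop("clique references a column outside 1..p")
    jc <- joint_code(m$values[, cl, drop = FALSE])
    ll <- ll + nlogn_sum(jc$counts, n)
  }
  for (s in f$separators) {
    if (length(s) == 0L) next
    jc <- joint_code(m$values[, s, drop = FALSE])
    ll <- ll - nlogn_sum(jc$counts, n)
  }
  ll
}

#' Number of free parameters of a decomposable model
#'
#' Nominal mode uses the classical formula
#' `sum_C (prod_{v in C} r_v - 1) - sum_S (prod_{v in S} r_v - 1)` with
#' `r_v` the per-column level counts. In sparse tables not all of these
#' parameters are estimable; `mode = "observed"` replaces each product of
#' level counts by the number of distinct configurations actually observed
#' for that vertex set.
#'
#' @param f A [clique_forest()].
#' @param levels Integer vector of per-vertex level counts (ignored in
#'   observed mode).
#' @param mode `"nominal"` or `"observed"`.
#' @param m Marker matrix, required for observed mode.
#' @return Integer model dimension.
#' @export
model_dimension <- function(f, levels, mode = c("nominal", "observed"),
                            m = NULL) {
  mode <- match.arg(mode)
  size <- function(set) {
    if (mode == "nominal") {
      if (any(levels[set] < 1L)) stop("level counts must be >= 1")
      prod(levels[set])
    } else {
      if (is.null(m)) stop("observed mode requires the marker matrix")
      length(joint_code(m$values[, set, drop = FALSE])$counts)
    }
  }
  dim <- 0
  for (cl in f$cliques) dim <- dim + size(cl) - 1
  for (s in f$separators) if (length(s) > 0L) dim <- dim - (size(s) - 1)
  as.integer(round(dim))
}

#' Empirical conditional mutual information
#'
#' `I(a; b | S) = sum (n_abS / N) log(n_abS * n_S / (n_aS * n_bS))` over
#' observed cells, in nats, with `0 log 0 = 0`. With `S` empty this is the
#' marginal mutual information. `2 N I(a; b | S)` is the deviance change of
#' the single-edge move with conditioning set `S`.
#'
#' @param m A [marker_matrix()].
#' @param a,b Distinct column indices not in `S`.
#' @param S Integer vector of conditioning columns (possibly empty).
#' @return Non-negative value in nats.
#' @export
cmi <- function(m, a, b, S = integer()) {
  a <- as.integer(a); b <- as.integer(b); S <- as.integer(S)
  if (a == b || a %in% S || b %in% S) {
    stop("'a' and 'b' must be distinct and outside 'S'")
  }
  x <- m$values
  n <- m$n_rows
  id_s <- joint_code(x[, S, drop = FALSE])$id
  xa <- x[, a]
  xb <- x[, b]
  ra <- max(xa) + 1L
  rb <- max(xb) + 1L
  ks <- max(id_s)
  # pack (S, a, b) cells exactly; counts of the four margins involved
  c_ab <- tabulate(((id_s - 1L) * ra + xa) * rb + xb + 1L, nbins = ks * ra * rb)
  c_a <- tabulate((id_s - 1L) * ra + xa + 1L, nbins = ks * ra)
  c_b <- tabulate((id_s - 1L) * rb + xb + 1L, nbins = ks * rb)
  c_s <- tabulate(id_s, nbins = ks)
  cell <- which(c_ab > 0)
  i_b <- (cell - 1L) %% rb
  rest <- (cell - 1L) %/% rb
  i_a <- rest %% ra
  i_s <- rest %/% ra + 1L
  nab <- c_ab[cell]
  val <- sum(nab / n * log(nab * c_s[i_s] /
                             (c_a[(i_s - 1L) * ra + i_a + 1L] *
                                c_b[(i_s - 1L) * rb + i_b + 1L])))
  max(val, 0)
}

#' Penalized likelihood score of a fitted graph
#'
#' `IC(G) = -2 loglik + alpha * dim(G)`, with `alpha = 2` for the AIC and
#' `alpha = log(N)` for the BIC.
#'
#' @param m A [marker_matrix()].
#' @param f A [clique_forest()].
#' @param alpha Penalization constant.
#' @param dim_mode `"nominal"` or `"observed"` (see [model_dimension()]).
#' @return Object of class `model_score`: list with `loglik`, `dim`,
#'   `alpha`, `ic`.
#' @export
model_score <- function(m, f, alpha, dim_mode = "nominal") {
  ll <- decomposable_loglik(m, f)
  dm <- model_dimension(f, levels = m$levels, mode = dim_mode, m = m)
  structure(list(loglik = ll, dim = dm, alpha = alpha,
                 ic = -2 * ll + alpha * dm),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("model_score: loglik = %.4f, dim = %d, alpha = %.4f, IC = %.4f\n",
              x$loglik, x$dim, x$alpha, x$ic))
  invisible(x)
}

#' Score change of a single-edge move
#'
#' For adding edge `(a, b)` with conditioning set `S` (the set returned by
#' [edge_addable()]), the deviance change is `-2 N I(a; b | S)` and the
#' nominal dimension change is `(r_a - 1) (r_b - 1) prod_{s in S} r_s`;
#' observed mode replaces level-count products by counts of distinct
#' observed configurations, via the inclusion-exclusion
#' `n(abS) - n(aS) - n(bS) + n(S)`. Removal flips both signs. The IC change
#' is `d_deviance + alpha * d_dim`.
#'
#' @param m A [marker_matrix()].
#' @param f Optional clique forest (interface compatibility; unused).
#' @param a,b Endpoints of the perturbed edge.
#' @param S Conditioning set from [edge_addable()] / [edge_removable()].
#' @param alpha Penalization constant.
#' @param direction `"add"` or `"remove"`.
#' @param dim_mode `"nominal"` or `"observed"`.
#' @return Object of class `score_delta`: list with `d_deviance`, `d_dim`,
#'   `d_ic` and `separator`.
#' @export
delta_score <- function(m, f = NULL, a, b, S, alpha,
                        direction = c("add", "remove"),
                        dim_mode = c("nominal", "observed")) {
  direction <- match.arg(direction)
  dim_mode <- match.arg(dim_mode)
  S <- as.integer(S)
  d_dev <- -2 * m$n_rows * cmi(m, a, b, S)
  if (dim_mode == "nominal") {
    r <- m$levels
    d_dim <- (r[a] - 1) * (r[b] - 1) * prod(r[S])
  } else {
    nobs <- function(set) {
      if (length(set) == 0L) return(1L)
      length(joint_code(m$values[, set, drop = FALSE])$counts)
    }
    d_dim <- nobs(c(a, b, S)) - nobs(c(a, S)) - nobs(c(b, S)) + nobs(S)
  }
  if (direction == "remove") {
    d_dev <- -d_dev
    d_dim <- -d_dim
  }
  structure(
    list(d_deviance = d_dev, d_dim = d_dim,
         d_ic = d_dev + alpha * d_dim, separator = sort(S)),
    class = "score_delta"
  )
}
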