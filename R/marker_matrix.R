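#' SNP marker matrix
#'
#' Container for a complete (no missing values) matrix of SNP codes with one
#' row per observation and one column per marker, markers ordered by
#' physical position. Two kinds are supported: unphased genotypes coded
#' 0/1/2 (ALT-allele counts) and phased haplotypes coded 0/1 (ALT
#' indicator, two rows per individual).
#'
#' @param values Integer matrix, N rows by p columns, no missing entries.
#' @param kind `"genotype"` or `"haplotype"`.
#' @param marker_ids Optional character vector of p marker names; defaults
#'   to `snp1..snpP`.
#' @param positions Optional non-negative integer vector of base-pair
#'   positions, nondecreasing.
#' @return An object of class `marker_matrix` with fields `values`, `kind`,
#'   `levels` (per-column count of distinct observed codes), `marker_ids`,
#'   `positions` and `n_rows`.
#' @examples
#' m <- marker_matrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 2), "genotype")
#' m$levels
#' @export
marker_matrix <- function(values, kind = c("genotype", "haplotype"),
                          marker_ids = NULL, positions = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(is.na(values))) stop("marker matrix contains missing values")
  if (!is.integer(values)) {
    iv <- suppressWarnings(as.integer(values))
    if (any(iv != as.numeric(values))) stop("non-integer codes in matrix")
    values <- matrix(iv, nrow = nrow(values), ncol = ncol(values))
  }
  rng <- if (kind == "genotype") c(0L, 2L) else c(0L, 1L)
  if (length(values) && (min(values) < rng[1L] || max(values) > rng[2L])) {
    stop(sprintf("codes out of range %d..%d for kind '%s'",
                 rng[1L], rng[2L], kind))
  }
  p <- ncol(values)
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(p))
  if (length(marker_ids) != p) stop("'marker_ids' length must equal p")
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != p) stop("'positions' length must equal p")
    if (any(positions < 0L)) stop("positions must be non-negative")
    if (is.unsorted(positions)) {
      stop("columns must be in nondecreasing position order")
    }
  }
  levels <- apply(values, 2L, function(x) length(unique(x)))
  if (p == 0L) levels <- integer()
  structure(
    list(values = values, kind = kind, levels = as.integer(levels),
         marker_ids = as.character(marker_ids), positions = positions,
         n_rows = nrow(values)),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d observations x %d SNPs (%s)\n",
              x$n_rows, ncol(x$values), x$kind))
  invisible(x)
}

#' Number of markers
#' @param m A `marker_matrix`.
#' @return Integer column count.
#' @export
n_markers <- function(m) ncol(m$values)

# column subset preserving metadata (used by the blockwise algorithm)
mm_subset <- function(m, cols) {
  marker_matrix(m$values[, cols, drop = FALSE], m$kind,
                marker_ids = m$marker_ids[cols],
                positions = if (is.null(m$positions)) NULL else
                  m$positions[cols])
}

#' Read a SNP matrix from a delimited text table
#'
#' One row per observation, one column per SNP, whitespace- or
#' tab-delimited, with an optional header line of marker ids (detected when
#' the first line is not numeric).
#'
#' @param path File path.
#' @param kind `"genotype"` (codes 0/1/2) or `"haplotype"` (codes 0/1).
#' @return A [marker_matrix()].
#' @export
read_table_matrix <- function(path, kind = c("genotype", "haplotype")) {
  kind <- match.arg(kind)
  first <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  tab <- utils::read.table(path, header = has_header,
                           colClasses = "character",
                           check.names = FALSE)
  ids <- if (has_header) colnames(tab) else NULL
  num <- suppressWarnings(vapply(tab, as.numeric, numeric(nrow(tab))))
  num <- matrix(num, nrow = nrow(tab))
  if (any(is.na(num))) stop("non-numeric cell in table")
  if (any(num != round(num))) stop("non-integer cell in table")
  marker_matrix(matrix(as.integer(num), nrow = nrow(tab)), kind,
                marker_ids = ids)
}

#' Validate a marker matrix
#'
#' Report-only check used before model selection: counts monomorphic
#' columns (retained with a warning downstream, since any edge incident to
#' a one-level column has zero score gain and zero dimension change),
#' missing entries and code violations. Missing data are a hard error for
#' all model-fitting functions; imputation is delegated to external tools.
#'
#' @param m A `marker_matrix` (or a raw matrix plus `kind` for checking
#'   un-validated input).
#' @param kind Code kind, used only when `m` is a raw matrix.
#' @return A list of class `validation_report` with `n_monomorphic`,
#'   `missing_count` and `errors` (character vector).
#' @export
validate_markers <- function(m, kind = c("genotype", "haplotype")) {
  if (!inherits(m, "marker_matrix")) {
    vals <- as.matrix(m)
    m <- list(
      values = vals,
      kind = match.arg(kind),
      levels = apply(vals, 2L, function(x) length(unique(x[!is.na(x)])))
    )
  }
  errors <- character()
  vals <- m$values
  missing_count <- sum(is.na(vals))
  if (missing_count > 0L) {
    errors <- c(errors, sprintf("%d missing entries", missing_count))
  }
  rng <- if (m$kind == "genotype") c(0L, 2L) else c(0L, 1L)
  bad <- which(!is.na(vals) & (vals < rng[1L] | vals > rng[2L]))
  if (length(bad) > 0L) {
    errors <- c(errors, sprintf("%d codes out of range %d..%d for kind '%s'",
                                length(bad), rng[1L], rng[2L], m$kind))
  }
  n_mono <- sum(m$levels == 1L)
  structure(
    list(n_monomorphic = n_mono, missing_count = missing_count,
         errors = errors),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation: %d monomorphic column(s), %d missing, %d error(s)\n",
              x$n_monomorphic, x$missing_count, length(x$errors)))
  for (e in x$errors) cat(" -", e, "\n")
  invisible(x)
}
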