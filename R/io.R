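#' Read a SNP matrix from a VCF file
#'
#' Reads biallelic SNP records from a VCF (v4.x) file. In genotype mode the
#' result has one row per sample, each code being the ALT-allele count
#' (0/1/2). In haplotype mode every GT field must be phased (`|`) and the
#' result has two rows per sample, one per haplotype, coded as ALT
#' indicators (0/1). All genotype calls must be present; imputation and
#' phasing are delegated to external tools. Columns are kept in file order.
#'
#' @param path Path to a VCF file.
#' @param mode `"genotype"` or `"haplotype"`.
#' @return A [marker_matrix()] with positions and marker ids from the file.
#' @export
read_vcf <- function(path, mode = c("genotype", "haplotype")) {
  mode <- match.arg(mode)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf() requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  alt <- VariantAnnotation::alt(vcf)
  multi <- which(lengths(alt) != 1L)
  if (length(multi) > 0L) {
    stop(sprintf("multiallelic record not supported: %s",
                 rownames(gt)[multi[1L]]))
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  positions <- GenomicRanges::start(rr)
  ids <- rownames(gt)
  samples <- colnames(gt)
  miss <- matrix(grepl(".", gt, fixed = TRUE), nrow(gt))
  if (any(miss)) {
    w <- which(miss, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing genotype call for sample %s at %s",
                 samples[w[2L]], ids[w[1L]]))
  }
  unph <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  if (mode == "haplotype" && any(unph)) {
    w <- which(unph, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype for sample %s at %s: haplotype mode needs phased data",
                 samples[w[2L]], ids[w[1L]]))
  }
  p <- nrow(gt)
  ns <- ncol(gt)
  a1 <- matrix(0L, ns, p)
  a2 <- matrix(0L, ns, p)
  for (i in seq_len(p)) {
    parts <- strsplit(gt[i, ], "[/|]")
    al <- suppressWarnings(vapply(parts, function(x) as.integer(x[1:2]),
                                  integer(2)))
    if (any(is.na(al)) || any(al < 0L) || any(al > 1L)) {
      stop(sprintf("invalid allele code at %s", ids[i]))
    }
    a1[, i] <- al[1L, ]
    a2[, i] <- al[2L, ]
  }
  if (mode == "genotype") {
    marker_matrix(a1 + a2, "genotype", marker_ids = ids,
                  positions = positions)
  } else {
    vals <- matrix(0L, 2L * ns, p)
    vals[seq(1L, 2L * ns, by = 2L), ] <- a1
    vals[seq(2L, 2L * ns, by = 2L), ] <- a2
    marker_matrix(vals, "haplotype", marker_ids = ids,
                  positions = positions)
  }
}

#' Write a graph to a file
#'
#' Supported formats: `edgelist`, a TSV of 1-based vertex pairs `i < j`
#' preceded by a `# p: <count>` comment line carrying the vertex count, and
#' `graphml`. Round-trips through [read_graph()] exactly.
#'
#' @param g A `chrom_graph`.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# p: %d", g$p), con)
    if (nrow(g$edges) > 0L) {
      writeLines(sprintf("%d\t%d", g$edges[, 1L], g$edges[, 2L]), con)
    }
  } else {
    nodes <- sprintf('    <node id="n%d"/>', seq_len(g$p))
    edges <- if (nrow(g$edges) > 0L) {
      sprintf('    <edge source="n%d" target="n%d"/>',
              g$edges[, 1L], g$edges[, 2L])
    } else {
      character()
    }
    xml <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="G" edgedefault="undirected">',
      nodes, edges,
      "  </graph>", "</graphml>"
    )
    writeLines(xml, path)
    xml2::read_xml(path)  # fail loudly if we produced invalid XML
  }
  invisible(path)
}

#' Read a graph written by [write_graph()]
#'
#' The format is sniffed from the content: XML input is parsed as GraphML,
#' anything else as a 1-based TSV edge list with a `# p:` header comment
#' (without one, `p` defaults to the largest endpoint).
#'
#' @param path File path.
#' @return A `chrom_graph`.
#' @export
read_graph <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && grepl("^\\s*<", first)) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, ".//node")
    edges <- xml2::xml_find_all(doc, ".//edge")
    p <- length(nodes)
    if (p == 0L) stop("GraphML file has no nodes")
    src <- as.integer(sub("^n", "", xml2::xml_attr(edges, "source")))
    tgt <- as.integer(sub("^n", "", xml2::xml_attr(edges, "target")))
    if (length(src) && (any(is.na(src)) || any(is.na(tgt)))) {
      stop("malformed GraphML edge endpoints")
    }
    return(chrom_graph(p, cbind(src, tgt)))
  }
  lines <- readLines(path)
  pline <- grep("^#\\s*p:", lines, value = TRUE)
  body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
  em <- if (length(body) > 0L) {
    parts <- strsplit(body, "\\s+")
    if (any(lengths(parts) != 2L)) stop("malformed edge list line")
    mat <- t(vapply(parts, function(x) as.integer(x), integer(2)))
    if (any(is.na(mat))) stop("malformed edge list line")
    if (any(mat < 1L)) stop("edge list must use 1-based vertex indices")
    mat
  } else {
    NULL
  }
  p <- if (length(pline) > 0L) {
    as.integer(sub("^#\\s*p:\\s*", "", pline[1L]))
  } else if (!is.null(em)) {
    max(em)
  } else {
    stop("edge list without '# p:' header and without edges")
  }
  chrom_graph(p, em)
}
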