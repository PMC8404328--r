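# Readers and writers for the external formats the workflow touches.
# Conventions fixed here once: score filters are strict (score > minScore);
# BED is 0-based half-open and GWAS positions 1-based on disk, both held
# 0-based in memory; gene identity is the bare case-sensitive symbol.

#' Read a STRING-style weighted edge list
#'
#' Expects >= 3 whitespace- or tab-separated columns: gene1, gene2,
#' combined_score (integer 0-1000). A header line is auto-detected (third
#' field not an integer). Only edges with score strictly greater than
#' \code{minScore} are kept; reversed duplicate pairs are collapsed keeping
#' the maximum score; the node set is the endpoints of the retained edges.
#'
#' @param path edge-list file.
#' @param minScore strict lower confidence cutoff (default 700, the usual
#'   high-confidence setting; 900 gives the very-high-confidence network).
#' @return A \linkS4class{GeneNetwork}.
#' @export
readNetwork <- function(path, minScore = 700) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(GeneNetwork())
  toks <- strsplit(trimws(lines), "[ \t]+")
  first <- toks[[1]]
  hasHeader <- length(first) >= 3 &&
    is.na(suppressWarnings(as.integer(first[3])))
  if (hasHeader) { toks <- toks[-1]; lineNo <- lineNo[-1] }
  if (!length(toks)) return(GeneNetwork())
  nf <- vapply(toks, length, 1L)
  if (any(nf < 3L))
    stop("malformed network row at line ", lineNo[which(nf < 3L)[1]],
         ": need >= 3 columns")
  g1 <- vapply(toks, `[`, "", 1L)
  g2 <- vapply(toks, `[`, "", 2L)
  sc <- suppressWarnings(as.integer(vapply(toks, `[`, "", 3L)))
  if (anyNA(sc))
    stop("malformed score at line ", lineNo[which(is.na(sc))[1]])
  if (any(sc < 0L | sc > 1000L))
    stop("score outside [0, 1000] at line ", lineNo[which(sc < 0L | sc > 1000L)[1]])
  if (any(g1 == g2))
    stop("self-loop at line ", lineNo[which(g1 == g2)[1]])
  keepE <- sc > minScore
  GeneNetwork(data.frame(gene1 = g1[keepE], gene2 = g2[keepE],
                         score = sc[keepE], stringsAsFactors = FALSE))
}

#' Write a GeneNetwork as an edge-list TSV
#' @param x a \linkS4class{GeneNetwork}
#' @param path output file
#' @export
writeNetwork <- function(x, path) {
  stopifnot(is(x, "GeneNetwork"))
  e <- x@edges
  names(e) <- c("node1", "node2", "combined_score")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Tab-separated with a mandatory header naming columns \code{snp},
#' \code{chr}, \code{pos} (1-based) and \code{p}. Zero p-values are rejected
#' (they break the chi-square transforms downstream); pre-floor them at the
#' smallest positive representable value if needed.
#'
#' @param path summary-statistics TSV.
#' @return A \linkS4class{GwasSummary}.
#' @export
readGwas <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "chr", "pos", "p")
  if (!all(need %in% names(d)))
    stop("GWAS header must name columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), " missing")
  if (any(d$p <= 0 | d$p > 1))
    stop("p-value outside (0, 1] for variant(s): ",
         paste(head(d$snp[d$p <= 0 | d$p > 1], 5), collapse = ", "))
  if (any(d$pos < 1))
    stop("position < 1 for variant(s): ",
         paste(head(d$snp[d$pos < 1], 5), collapse = ", "))
  GwasSummary(d$snp, d$chr, d$pos, d$p)
}

#' Write GWAS summary statistics (1-based positions on disk)
#' @param x a \linkS4class{GwasSummary}
#' @param path output TSV
#' @export
writeGwas <- function(x, path) {
  stopifnot(is(x, "GwasSummary"))
  r <- x@records
  out <- data.frame(snp = r$snp, chr = r$chr, pos = r$pos0 + 1L, p = r$p,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics matrix with case/control labels
#'
#' The matrix TSV has the feature id in the first column and one column per
#' sample; the labels TSV has columns \code{sample} and \code{group}
#' ("case"/"control") and must cover every sample column.
#'
#' @param path matrix TSV.
#' @param labelsPath labels TSV.
#' @param kind "expression" or "methylation-beta".
#' @return An \linkS4class{OmicsMatrix}; sample order follows the matrix file.
#' @export
readOmicsMatrix <- function(path, labelsPath,
                            kind = c("expression", "methylation-beta")) {
  kind <- match.arg(kind)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  feat <- as.character(d[[1]])
  if (anyDuplicated(feat))
    stop("duplicated feature id(s): ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- feat
  lab <- read.delim(labelsPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(lab)))
    stop("labels file must have columns sample, group")
  groups <- setNames(as.character(lab$group), as.character(lab$sample))
  OmicsMatrix(m, groups, kind)
}

#' Write an omics matrix (and optionally its labels) to TSV
#' @param x an \linkS4class{OmicsMatrix}
#' @param path matrix TSV path
#' @param labelsPath optional labels TSV path
#' @export
writeOmicsMatrix <- function(x, path, labelsPath = NULL) {
  stopifnot(is(x, "OmicsMatrix"))
  m <- omicsValues(x)
  out <- data.frame(feature = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labelsPath)) {
    write.table(data.frame(sample = colnames(m), group = sampleGroups(x)),
                labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one or more member genes,
#' tab-separated.
#' @param path GMT file
#' @return A \linkS4class{GeneSetCollection} (input order preserved).
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(toks, length, 1L)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1], " has no member genes")
  nm <- vapply(toks, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(toks, function(t) unique(t[-(1:2)]))
  names(sets) <- nm
  GeneSetCollection(sets, vapply(toks, `[`, "", 2L))
}

#' Write gene sets in GMT format
#' @param x a \linkS4class{GeneSetCollection}
#' @param path output GMT file
#' @export
writeGeneSets <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(seq_along(x@sets), function(i)
    paste(c(names(x@sets)[i], x@descriptions[i], x@sets[[i]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene coordinates from BED4
#'
#' Columns chrom, start, end, name; 0-based half-open intervals preserved
#' verbatim. At most one record per gene.
#' @param path BED file
#' @return A \linkS4class{GeneCoordinates}.
#' @export
readGeneCoords <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("BED4 requires columns chrom, start, end, name")
  names(d)[1:4] <- c("chrom", "start", "end", "gene")
  bad <- d$start >= d$end
  if (any(bad))
    stop("interval with start >= end for gene(s): ",
         paste(head(d$gene[bad], 5), collapse = ", "))
  GeneCoordinates(d$gene, d$chrom, d$start, d$end)
}

#' Write gene coordinates as BED4
#' @param x a \linkS4class{GeneCoordinates}
#' @param path output BED file
#' @export
writeGeneCoords <- function(x, path) {
  stopifnot(is(x, "GeneCoordinates"))
  r <- x@records
  write.table(r[, c("chrom", "start", "end", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a Module
#'
#' One gene per line, preceded by header comment lines
#' \code{# key=value} carrying the provenance (method, dataset, omic).
#'
#' @param x a \linkS4class{Module}
#' @param path module TSV
#' @export
writeModule <- function(x, path) {
  stopifnot(is(x, "Module"))
  hdr <- sprintf("# %s=%s", c("method", "dataset", "omic"),
                 c(x@method, x@dataset, x@omic))
  writeLines(c(hdr, x@genes), path)
  invisible(path)
}

#' @rdname writeModule
#' @return \code{readModule}: the \linkS4class{Module}; duplicate gene lines
#'   are de-duplicated with a warning.
#' @export
readModule <- function(path) {
  lines <- readLines(path)
  isHdr <- startsWith(lines, "#")
  prov <- c(method = "", dataset = "", omic = "")
  for (h in lines[isHdr]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L && kv[1] %in% names(prov)) prov[kv[1]] <- kv[2]
  }
  genes <- trimws(lines[!isHdr])
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes))
    warning("duplicate gene line(s) de-duplicated: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  Module(genes, method = prov[["method"]], dataset = prov[["dataset"]],
         omic = prov[["omic"]])
}
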