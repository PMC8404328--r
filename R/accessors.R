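#' Construct a GeneNetwork
#'
#' Canonicalises edges (unordered pairs stored with \code{gene1 < gene2},
#' reversed duplicates collapsed keeping the maximum score) and validates the
#' result. Self-loops are an error.
#'
#' @param edges data.frame with columns \code{gene1}, \code{gene2},
#'   \code{score} (integer 0-1000).
#' @param nodes optional character vector of nodes; defaults to the edge
#'   endpoints. May include isolated genes.
#' @return A \linkS4class{GeneNetwork}.
#' @export
GeneNetwork <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene1 = character(0), gene2 = character(0),
                        score = integer(0), stringsAsFactors = FALSE)
  } else {
    g1 <- as.character(edges$gene1); g2 <- as.character(edges$gene2)
    if (any(g1 == g2))
      stop("self-loop edge(s): ", paste(unique(g1[g1 == g2]), collapse = ", "))
    a <- pmin(g1, g2); b <- pmax(g1, g2)
    sc <- as.integer(edges$score)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      sc <- as.integer(tapply(sc, key, max)[unique(key)])
      keep <- !duplicated(key)
      a <- a[keep]; b <- b[keep]
    }
    o <- order(a, b)
    edges <- data.frame(gene1 = a[o], gene2 = b[o], score = sc[o],
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  if (is.null(nodes)) nodes <- unique(c(edges$gene1, edges$gene2))
  new("GeneNetwork", nodes = sort(unique(as.character(nodes))), edges = edges)
}

#' @describeIn GeneNetwork node (gene) symbols of the network
#' @param x a GeneNetwork
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn GeneNetwork edge table (gene1, gene2, score)
#' @export
networkEdges <- function(x) x@edges

#' Convert a GeneNetwork to an igraph graph
#'
#' Isolated nodes are preserved; edge scores become the \code{score} edge
#' attribute.
#' @param x a \linkS4class{GeneNetwork}
#' @return an undirected \code{igraph} graph
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  g <- igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                     vertices = data.frame(name = x@nodes))
  g
}

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    cat(sprintf("  score range [%d, %d]\n",
                min(object@edges$score), max(object@edges$score)))
})

#' Construct a Module
#'
#' @param genes character vector of gene symbols (de-duplicated, sorted).
#' @param method,dataset,omic provenance tags.
#' @param info optional list of method-specific metadata.
#' @return A \linkS4class{Module}.
#' @export
Module <- function(genes = character(0), method = "", dataset = "",
                   omic = "", info = list()) {
  new("Module", genes = sort(unique(as.character(genes))), method = method,
      dataset = dataset, omic = omic, info = info)
}

#' @describeIn Module member genes
#' @param x a Module
#' @export
moduleGenes <- function(x) x@genes

#' @describeIn Module number of member genes
#' @export
moduleSize <- function(x) length(x@genes)

#' @describeIn Module provenance tags as a named character vector
#' @export
moduleProvenance <- function(x)
  c(method = x@method, dataset = x@dataset, omic = x@omic)

setMethod("show", "Module", function(object) {
  cat(sprintf("Module of %d gene(s) [method=%s dataset=%s omic=%s]\n",
              length(object@genes), object@method, object@dataset, object@omic))
  if (length(object@genes))
    cat("  ", paste(head(object@genes, 8), collapse = ", "),
        if (length(object@genes) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "ModuleScore", function(object) {
  cat(sprintf("ModuleScore [%s]: T = %.4g on %d df, analytic p = %.4g\n",
              object@tag, object@statistic, object@df, object@p))
  if (!is.na(object@empiricalP))
    cat(sprintf("  empirical p = %.4g (B = %d, seed = %d)\n",
                object@empiricalP, as.integer(object@B), as.integer(object@seed)))
})

#' @describeIn ModuleScore analytic p-value
#' @param x a ModuleScore
#' @export
scoreP <- function(x) x@p

#' @describeIn ModuleScore fusion statistic T
#' @export
scoreStatistic <- function(x) x@statistic

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param groups character/factor of "case"/"control" per sample (in column
#'   order), or a named vector matched to the column names.
#' @param kind "expression" or "methylation-beta".
#' @return An \linkS4class{OmicsMatrix}.
#' @export
OmicsMatrix <- function(values, groups, kind = c("expression", "methylation-beta")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  groups <- setNames(as.character(groups), names(groups))
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("sample(s) missing from labels: ", paste(missing, collapse = ", "))
    groups <- unname(groups[colnames(values)])
  }
  if (length(groups) != ncol(values))
    stop("one group label per sample required")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = S4Vectors::DataFrame(group = groups, row.names = colnames(values)))
  new("OmicsMatrix", se, kind = kind)
}

#' @describeIn OmicsMatrix measurement kind
#' @param x an OmicsMatrix
#' @export
omicsKind <- function(x) x@kind

#' @describeIn OmicsMatrix per-sample case/control labels
#' @export
sampleGroups <- function(x)
  as.character(SummarizedExperiment::colData(x)$group)

#' @describeIn OmicsMatrix the values matrix
#' @export
omicsValues <- function(x) SummarizedExperiment::assay(x)

#' Construct a GwasSummary
#'
#' @param snp,chr,pos,p parallel vectors; \code{pos} is the 1-based position
#'   as found in summary-statistics files (stored 0-based internally).
#' @return A \linkS4class{GwasSummary}.
#' @export
GwasSummary <- function(snp, chr, pos, p) {
  new("GwasSummary",
      records = data.frame(snp = as.character(snp), chr = as.character(chr),
                           pos0 = as.integer(pos) - 1L, p = as.numeric(p),
                           stringsAsFactors = FALSE))
}

#' @describeIn GwasSummary internal record table (pos0 is 0-based)
#' @param x a GwasSummary
#' @export
gwasRecords <- function(x) x@records

setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary: %d SNP(s) on %d chromosome(s)\n",
              nrow(object@records), length(unique(object@records$chr))))
})

#' Construct GeneCoordinates
#'
#' @param gene,chrom,start,end parallel vectors; 0-based half-open intervals.
#' @return A \linkS4class{GeneCoordinates}.
#' @export
GeneCoordinates <- function(gene, chrom, start, end) {
  new("GeneCoordinates",
      records = data.frame(gene = as.character(gene), chrom = as.character(chrom),
                           start = as.integer(start), end = as.integer(end),
                           stringsAsFactors = FALSE))
}

#' @describeIn GeneCoordinates record table
#' @param x a GeneCoordinates
#' @export
coordRecords <- function(x) x@records

#' Construct a GeneSetCollection
#'
#' @param sets named list of character gene vectors.
#' @param descriptions optional character vector of set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection the named list of gene sets
#' @param x a GeneSetCollection
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(object@sets)))
})

setMethod("show", "OmicsMatrix", function(object) {
  m <- SummarizedExperiment::assay(object)
  g <- sampleGroups(object)
  cat(sprintf("OmicsMatrix (%s): %d features x %d samples (%d case / %d control)\n",
              object@kind, nrow(m), ncol(m),
              sum(g == "case"), sum(g == "control")))
})

#' @describeIn SeedSet seed gene symbols
#' @param x a SeedSet
#' @export
seedGenes <- function(x) x@genes

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d gene(s), fraction %.3g, source '%s'\n",
              length(object@genes), object@fraction, object@source))
})

setMethod("show", "PlantedTruth", function(object) {
  cat(sprintf("PlantedTruth: module of %d gene(s); signal channels: %s\n",
              length(object@module),
              paste(names(object@signalGenes), collapse = ", ")))
})

#' @describeIn PlantedTruth the planted module genes
#' @param x a PlantedTruth
#' @export
truthModule <- function(x) x@module

#' @describeIn PlantedTruth flagged signal genes for one channel
#' @param channel "expression", "methylation" or "gwas"
#' @export
truthSignalGenes <- function(x, channel) x@signalGenes[[channel]]
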