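# Three exemplar module detectors, one per algorithm class:
# clique-based (differentially expressed maximal cliques), seed-based
# (DIAMOnD connectivity expansion) and co-expression clustering.

#' Enumerate maximal cliques of a network
#'
#' Exactly the maximal cliques of size >= \code{minSize} (via the
#' Bron-Kerbosch enumeration in igraph), each sorted lexicographically, the
#' list sorted by size descending then lexicographically.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param minSize minimum clique size (default 3: bare edges excluded).
#' @param maxCliques guard against clique explosions on under-thresholded
#'   networks; exceeding it is an error advising a higher score threshold.
#' @return list of character vectors (possibly empty).
#' @export
enumerateMaximalCliques <- function(network, minSize = 3L, maxCliques = 1e5) {
  g <- asIgraph(network)
  cl <- igraph::max_cliques(g, min = minSize)
  if (length(cl) > maxCliques)
    stop("more than ", maxCliques, " maximal cliques; ",
         "raise the network score threshold")
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  if (!length(cl)) return(list())
  key <- vapply(cl, paste, "", collapse = "\r")
  sz <- vapply(cl, length, 1L)
  cl[order(-sz, key)]
}

#' Clique-based differential module detection
#'
#' Reconstruction of differentially-expressed-clique scoring: seed genes are
#' the top differential genes in the network ([selectSeedGenes()]); every
#' maximal clique is tested for seed enrichment with a one-sided
#' hypergeometric test (clique as the draw, network genes as the universe);
#' clique p-values are BH-adjusted; the module is the union of genes of
#' cliques with adjusted p below \code{cliqueAlpha}.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param diffTable differential table covering >= 1 network gene.
#' @param seedFraction seed selection fraction (default 0.05).
#' @param minCliqueSize minimum clique size (default 3).
#' @param cliqueAlpha BH-adjusted significance threshold per clique
#'   (default 0.01).
#' @param dataset,omic provenance tags for the returned module.
#' @return list with \code{module} (\linkS4class{Module},
#'   method "clique_sum") and \code{report} (data.frame with one row per
#'   clique: genes, size, seed overlap, p, p_adj, significant).
#' @export
detectCliqueSum <- function(network, diffTable, seedFraction = 0.05,
                            minCliqueSize = 3L, cliqueAlpha = 0.01,
                            dataset = "", omic = "") {
  seeds <- seedGenes(selectSeedGenes(diffTable, network, seedFraction))
  cliques <- enumerateMaximalCliques(network, minSize = minCliqueSize)
  emptyMod <- Module(character(0), method = "clique_sum", dataset = dataset,
                     omic = omic)
  if (!length(cliques)) {
    report <- data.frame(genes = character(0), size = integer(0),
                         overlap = integer(0), p = numeric(0),
                         p_adj = numeric(0), significant = logical(0))
    return(list(module = emptyMod, report = report))
  }
  N <- length(networkNodes(network))
  nSeed <- length(seeds)
  size <- vapply(cliques, length, 1L)
  overlap <- vapply(cliques, function(cl) sum(cl %in% seeds), 1L)
  p <- phyper(overlap - 1L, nSeed, N - nSeed, size, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  padj <- benjaminiHochberg(p)
  sig <- padj < cliqueAlpha
  module <- Module(unique(unlist(cliques[sig])), method = "clique_sum",
                   dataset = dataset, omic = omic,
                   info = list(nSeeds = nSeed, nCliques = length(cliques),
                               nSignificant = sum(sig)))
  report <- data.frame(genes = vapply(cliques, paste, "", collapse = ","),
                       size = size, overlap = overlap, p = p, p_adj = padj,
                       significant = sig, stringsAsFactors = FALSE)
  list(module = module, report = report)
}

# One-sided hypergeometric connectivity p-value used by DIAMOnD: the
# probability that a node of degree d has >= k links into a member set of
# size s drawn from N nodes.
.diamondP <- function(k, d, s, N) {
  phyper(k - 1L, s, N - s, d, lower.tail = FALSE)
}

#' Seed-based module expansion (DIAMOnD)
#'
#' Starting from the seed genes present in the network, iteratively adds the
#' non-member node whose link count to the current member set has the
#' smallest hypergeometric tail probability (connectivity significance),
#' without seed weighting. Ties are broken by more links to members, then by
#' lexicographically smaller symbol. The returned module is the in-network
#' seeds plus all added genes; the addition order is recorded in
#' \code{info$additionOrder}.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param seeds a \linkS4class{SeedSet} or character vector; at least one
#'   seed must be in the network.
#' @param nIterations number of genes to add (default 200).
#' @param dataset,omic provenance tags.
#' @return A \linkS4class{Module} with method "diamond".
#' @export
detectDiamond <- function(network, seeds, nIterations = 200L,
                          dataset = "", omic = "") {
  if (is(seeds, "SeedSet")) seeds <- seedGenes(seeds)
  nodes <- networkNodes(network)
  seeds <- intersect(seeds, nodes)
  if (!length(seeds)) stop("no seed gene is present in the network")
  N <- length(nodes)
  g <- asIgraph(network)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  adj <- adj[nodes, nodes]  # fixed lexicographic order
  degree <- Matrix::rowSums(adj)
  member <- nodes %in% seeds
  linksToMembers <- as.numeric(adj %*% member)
  added <- character(0)
  nIterations <- min(nIterations, N - length(seeds))
  for (it in seq_len(nIterations)) {
    s <- sum(member)
    cand <- which(!member)
    if (!length(cand)) break
    pv <- .diamondP(linksToMembers[cand], degree[cand], s, N)
    best <- cand[order(pv, -linksToMembers[cand], nodes[cand])[1]]
    added <- c(added, nodes[best])
    member[best] <- TRUE
    linksToMembers <- linksToMembers + as.numeric(adj[, best])
  }
  Module(c(seeds, added), method = "diamond", dataset = dataset, omic = omic,
         info = list(seeds = sort(seeds), additionOrder = added))
}

#' Co-expression module detection
#'
#' A deliberately plain co-expression exemplar: signed adjacency
#' \eqn{a_{ij} = ((1 + cor_{ij})/2)^{power}} over all samples, dissimilarity
#' \eqn{1 - a}, average-linkage hierarchical clustering, and a sweep over
#' \code{nHeightSteps} evenly spaced cut heights keeping the cut that
#' maximises the number of clusters of size >= \code{minModuleSize} (the
#' highest such height on ties, so clusters are as complete as possible). Among those clusters the one most enriched for
#' differential seed genes (one-sided hypergeometric, seeds = top 5 percent
#' of the matrix genes by p) is returned. Constant genes are removed first.
#'
#' @param x an \linkS4class{OmicsMatrix} with >= 4 samples.
#' @param diffTable differential table for seed selection.
#' @param power soft-threshold exponent (default 6).
#' @param nHeightSteps number of cut heights to sweep (default 20).
#' @param minModuleSize minimum cluster size (default 10).
#' @param seedFraction seed selection fraction (default 0.05).
#' @param dataset,omic provenance tags.
#' @return A \linkS4class{Module} with method "coexpression"; empty (with a
#'   warning) if fewer than \code{minModuleSize} non-constant genes remain.
#' @export
detectCoexpression <- function(x, diffTable, power = 6, nHeightSteps = 20L,
                               minModuleSize = 10L, seedFraction = 0.05,
                               dataset = "", omic = "") {
  stopifnot(is(x, "OmicsMatrix"))
  m <- omicsValues(x)
  if (ncol(m) < 4L) stop("need >= 4 samples")
  v <- apply(m, 1, var)
  m <- m[v > 0, , drop = FALSE]
  emptyMod <- Module(character(0), method = "coexpression", dataset = dataset,
                     omic = omic)
  if (nrow(m) < minModuleSize) {
    warning("fewer than minModuleSize non-constant genes; empty module")
    return(emptyMod)
  }
  a <- ((1 + cor(t(m))) / 2)^power
  h <- hclust(as.dist(1 - a), method = "average")
  heights <- seq(min(h$height), max(h$height), length.out = nHeightSteps)
  best <- NULL; bestCount <- -1L
  for (ht in heights) {
    cl <- cutree(h, h = ht)
    sizes <- table(cl)
    count <- sum(sizes >= minModuleSize)
    # ties prefer the coarsest (highest) cut: more complete clusters
    if (count >= bestCount) { bestCount <- count; best <- cl }
  }
  if (bestCount < 1L) {
    warning("no cluster reached minModuleSize; empty module")
    return(emptyMod)
  }
  seeds <- seedGenes(selectSeedGenes(diffTable, rownames(m), seedFraction))
  N <- nrow(m); nSeed <- length(seeds)
  keep <- names(which(table(best) >= minModuleSize))
  stats <- lapply(keep, function(k) {
    genes <- names(best)[best == as.integer(k)]
    ov <- sum(genes %in% seeds)
    p <- phyper(ov - 1L, nSeed, N - nSeed, length(genes), lower.tail = FALSE)
    list(genes = genes, p = p)
  })
  pvals <- vapply(stats, `[[`, 1.0, "p")
  sizes <- vapply(stats, function(s) length(s$genes), 1L)
  pick <- order(pvals, -sizes)[1]
  Module(stats[[pick]]$genes, method = "coexpression", dataset = dataset,
         omic = omic,
         info = list(seedEnrichmentP = pvals[pick], nClusters = length(stats)))
}
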