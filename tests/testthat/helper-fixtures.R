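# Shared fixture builders and independent oracles. Oracles here are written
# against the definitions (brute-force enumeration / closed forms), not
# against the package's implementation paths.

# quick network from an edge string "A-B,B-C"; all scores 901
makeNet <- function(edgeSpec, nodes = NULL, score = 901L) {
  if (!nzchar(edgeSpec)) return(GeneNetwork(nodes = nodes))
  pairs <- strsplit(strsplit(edgeSpec, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  GeneNetwork(data.frame(gene1 = vapply(pairs, `[`, "", 1),
                         gene2 = vapply(pairs, `[`, "", 2),
                         score = score, stringsAsFactors = FALSE),
              nodes = nodes)
}

# tiny omics matrix: nGenes x (nCase + nControl), signal genes shifted in cases
makeOmics <- function(nGenes = 20, nCase = 4, nControl = 4, effect = 0,
                      signalGenes = character(0), seed = 1,
                      kind = "expression") {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(nGenes))
  m <- matrix(rnorm(nGenes * (nCase + nControl)), nrow = nGenes,
              dimnames = list(genes, sprintf("S%02d", seq_len(nCase + nControl))))
  groups <- c(rep("case", nCase), rep("control", nControl))
  m[genes %in% signalGenes, groups == "case"] <-
    m[genes %in% signalGenes, groups == "case"] + effect
  if (kind == "methylation-beta") m <- plogis(m)
  OmicsMatrix(m, groups, kind)
}

# brute-force maximal cliques by power-set enumeration (bitmask)
bruteMaximalCliques <- function(net, minSize) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(net)
  if (nrow(e)) {
    adj[cbind(e$gene1, e$gene2)] <- TRUE
    adj[cbind(e$gene2, e$gene1)] <- TRUE
  }
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < minSize) next
    sub <- adj[members, members, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    # maximal: no outside node adjacent to every member
    outside <- setdiff(seq_len(n), members)
    if (length(outside) &&
        any(colSums(adj[members, outside, drop = FALSE]) == length(members)))
      next
    out[[length(out) + 1L]] <- nodes[members]
  }
  if (!length(out)) return(list())
  key <- vapply(out, paste, "", collapse = "\r")
  sz <- vapply(out, length, 1L)
  out[order(-sz, key)]
}

# brute-force BH step-up from the definition:
# adjusted_(i) = min over j >= i of min(1, p_(j) * m / j), mapped back
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(po[i:m] * m / (i:m))), 1.0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent DIAMOnD single-step oracle: scan every non-member, compute the
# hypergeometric tail of its link count to the member set, pick the minimum
# with ties broken by more links then lexicographic symbol
diamondStepOracle <- function(net, members) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  N <- length(nodes)
  s <- sum(nodes %in% members)
  best <- NULL
  for (v in setdiff(nodes, members)) {
    nb <- c(e$gene2[e$gene1 == v], e$gene1[e$gene2 == v])
    k <- sum(nb %in% members)
    d <- length(nb)
    pv <- phyper(k - 1, s, N - s, d, lower.tail = FALSE)
    cand <- list(v = v, p = pv, k = k)
    if (is.null(best) || pv < best$p ||
        (pv == best$p && (k > best$k || (k == best$k && v < best$v))))
      best <- cand
  }
  best$v
}

# one-sided Fisher enrichment p by exhaustive enumeration over all possible
# draws of |B| genes from the universe
bruteEnrichmentP <- function(setA, setB, universe) {
  obs <- length(intersect(setA, setB))
  draws <- combn(universe, length(setB))
  mean(apply(draws, 2, function(d) length(intersect(setA, d))) >= obs)
}

# F1 of a recovered module against the planted truth
moduleF1 <- function(module, truthGenes) {
  got <- if (is(module, "Module")) moduleGenes(module) else module
  tp <- length(intersect(got, truthGenes))
  if (tp == 0) return(0)
  2 * tp / (length(got) + length(truthGenes))
}

# random Erdos-Renyi GeneNetwork for oracle comparisons
randomNet <- function(n, pEdge, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < pEdge
  if (!any(keep)) return(GeneNetwork(nodes = nodes))
  GeneNetwork(data.frame(gene1 = nodes[idx[keep, 1]],
                         gene2 = nodes[idx[keep, 2]],
                         score = 901L, stringsAsFactors = FALSE),
              nodes = nodes)
}
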