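# Cross-cutting benchmark and validation statistics: Fisher's method meta
# p-values, excess-significance binomial tests, Spearman confound checks,
# Fisher's exact enrichment with cross-product odds ratios, permutation
# overlap tests with their analytic hypergeometric twin, pairwise
# study-overlap odds ratios, betweenness diagnostics and the
# method-by-dataset ranking table.

#' Fisher's method combined p-value
#'
#' \eqn{X = -2 \sum \ln p_i} referred to the upper tail of \eqn{\chi^2_{2k}}.
#'
#' @param ps non-empty vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisherMetaP <- function(ps) {
  if (!length(ps)) stop("empty p-value list")
  if (any(ps <= 0 | ps > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(ps))
  max(pchisq(X, df = 2 * length(ps), lower.tail = FALSE),
      .Machine$double.xmin)
}

#' Excess-significance binomial test
#'
#' Exact one-sided upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim Binomial(n, \alpha_0)}: the probability of observing at least
#' k significant results among n independent tests when each is significant
#' with probability \eqn{\alpha_0} by chance.
#'
#' @param k observed number of significant results (0 <= k <= n).
#' @param n number of tests.
#' @param alpha0 per-test null significance probability, in (0, 1).
#' @return the exact upper-tail p-value.
#' @export
binomialExcessP <- function(k, n, alpha0 = 0.05) {
  if (alpha0 <= 0 || alpha0 >= 1) stop("alpha0 must lie in (0, 1)")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (k == 0) return(1)
  binom.test(k, n, p = alpha0, alternative = "greater")$p.value
}

#' Spearman correlation with t-approximation p-value
#'
#' Midrank Spearman rho with the two-sided p-value from
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2} degrees of freedom
#' (the large-sample approximation; exact permutation p-values do not scale
#' to hundreds of modules).
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanRhoP <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need two vectors of equal length >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (var(x) == 0 || var(y) == 0) stop("constant vector: rho undefined")
  rho <- cor(x, y, method = "spearman")
  list(rho = rho, p = rhoToP(rho, length(x)))
}

#' @rdname spearmanRhoP
#' @param rho a Spearman correlation.
#' @param n the sample size behind it.
#' @return \code{rhoToP}: the two-sided t-approximation p-value.
#' @export
rhoToP <- function(rho, n) {
  if (n < 4L) stop("need n >= 4")
  if (abs(rho) >= 1) return(.Machine$double.xmin)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Fisher's exact enrichment of two gene sets in a universe
#'
#' Builds the 2x2 membership table (a = in both, b = in A only, c = in B
#' only, d = in neither), computes the cross-product odds ratio
#' \eqn{ad/bc} (with the Haldane-Anscombe +0.5 correction when any cell is
#' zero, flagged in the result) and the exact one-sided (enrichment) and
#' two-sided p-values.
#'
#' @param setA,setB character vectors, subsets of \code{universe}.
#' @param universe non-empty character vector of all genes considered.
#' @return list with \code{table} (named counts a, b, c, d), \code{or},
#'   \code{haldane} (whether +0.5 was applied), \code{pOneSided},
#'   \code{pTwoSided}.
#' @export
fisherExactEnrichment <- function(setA, setB, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c <- length(setB) - a
  d <- length(universe) - a - b - c
  haldane <- any(c(a, b, c, d) == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  mat <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  list(table = c(a = a, b = b, c = c, d = d), or = or, haldane = haldane,
       pOneSided = fisher.test(mat, alternative = "greater")$p.value,
       pTwoSided = fisher.test(mat)$p.value)
}

#' Permutation overlap test with analytic hypergeometric twin
#'
#' Null distribution: the overlap of B uniform draws of \code{|module|}
#' genes from the universe with \code{geneSet}. The empirical p-value is
#' \eqn{(\#\{null \ge observed\} + 1)/(B + 1)}; the analytic one-sided
#' hypergeometric tail is reported alongside, because extreme enrichments
#' lie far beyond Monte-Carlo resolution.
#'
#' @param module,geneSet character vectors; \code{module} must be a subset
#'   of \code{universe}.
#' @param universe all genes.
#' @param B number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{empiricalP}, \code{analyticP},
#'   \code{B}, \code{seed}.
#' @export
overlapPermutationP <- function(module, geneSet, universe, B = 10000L, seed) {
  if (B < 100) stop("B must be >= 100")
  universe <- unique(universe)
  if (!all(module %in% universe)) stop("module must be a subset of universe")
  geneSet <- intersect(unique(geneSet), universe)
  obs <- length(intersect(module, geneSet))
  k <- length(unique(module))
  inSet <- universe %in% geneSet
  set.seed(seed)
  null <- vapply(seq_len(B),
                 function(b) sum(inSet[sample.int(length(universe), k)]), 1L)
  emp <- (sum(null >= obs) + 1) / (B + 1)
  ana <- phyper(obs - 1L, sum(inSet), length(universe) - sum(inSet), k,
                lower.tail = FALSE)
  list(observed = obs, empiricalP = emp, analyticP = max(ana, .Machine$double.xmin),
       B = B, seed = seed)
}

#' Pairwise overlap odds ratios between gene lists
#'
#' For every unordered pair of lists, the Haldane-corrected cross-product
#' odds ratio of the 2x2 membership table over the universe, plus mean odds
#' ratios and pair counts per group combination when \code{groups} assigns
#' each list to a group (e.g. expression vs methylation studies).
#'
#' @param lists named list (>= 2) of character vectors, all subsets of
#'   \code{universe}.
#' @param universe all genes.
#' @param groups optional named character vector mapping list names to
#'   groups.
#' @return list with \code{pairs} (data.frame: listA, listB, or, and group
#'   columns if given) and \code{groupSummary} (data.frame: groupA, groupB,
#'   nPairs, meanOR; NULL without groups).
#' @export
pairwiseOverlapOR <- function(lists, universe, groups = NULL) {
  if (length(lists) < 2L) stop("need >= 2 lists")
  universe <- unique(universe)
  for (nm in names(lists))
    if (!all(lists[[nm]] %in% universe))
      stop("list '", nm, "' is not a subset of the universe")
  nm <- names(lists)
  cmb <- combn(nm, 2)
  orv <- apply(cmb, 2, function(pr) {
    A <- unique(lists[[pr[1]]]); Bv <- unique(lists[[pr[2]]])
    a <- length(intersect(A, Bv))
    b <- length(A) - a
    c <- length(Bv) - a
    d <- length(universe) - a - b - c
    if (any(c(a, b, c, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
  })
  pairs <- data.frame(listA = cmb[1, ], listB = cmb[2, ], or = orv,
                      stringsAsFactors = FALSE)
  groupSummary <- NULL
  if (!is.null(groups)) {
    ga <- groups[pairs$listA]; gb <- groups[pairs$listB]
    key <- ifelse(ga <= gb, paste(ga, gb, sep = "|"), paste(gb, ga, sep = "|"))
    pairs$groupA <- pmin(ga, gb); pairs$groupB <- pmax(ga, gb)
    agg <- split(pairs$or, key)
    groupSummary <- data.frame(
      groupA = vapply(strsplit(names(agg), "|", fixed = TRUE), `[`, "", 1),
      groupB = vapply(strsplit(names(agg), "|", fixed = TRUE), `[`, "", 2),
      nPairs = vapply(agg, length, 1L),
      meanOR = vapply(agg, mean, 1.0),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(pairs = pairs, groupSummary = groupSummary)
}

#' Mean betweenness centrality of module genes
#'
#' Mean normalised shortest-path betweenness of the module genes in the
#' network; module genes absent from the network are dropped with a warning.
#'
#' @param network a \linkS4class{GeneNetwork}.
#' @param module a \linkS4class{Module} or character vector.
#' @return mean normalised betweenness (a number in [0, 1]).
#' @export
moduleCentrality <- function(network, module) {
  genes <- if (is(module, "Module")) moduleGenes(module) else unique(module)
  nodes <- networkNodes(network)
  missing <- setdiff(genes, nodes)
  if (length(missing)) {
    warning(length(missing), " module gene(s) not in the network dropped")
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stop("no module gene is present in the network")
  g <- asIgraph(network)
  btw <- igraph::betweenness(g, v = genes, normalized = TRUE)
  mean(btw)
}

#' Build the method-by-dataset benchmark table
#'
#' From per-(method, dataset) module p-values (NA marks a missing or empty
#' module), computes per-method and per-dataset Fisher meta p-values over
#' the non-missing cells, and ranks methods and datasets by ascending
#' meta-P. Missing cells are excluded and counted.
#'
#' @param scores data.frame with columns \code{method}, \code{dataset},
#'   \code{p} (NA allowed).
#' @return list with \code{matrix} (methods x datasets p-value matrix),
#'   \code{methods} and \code{datasets} data.frames (metaP, rank, nMissing).
#' @export
buildBenchmarkTable <- function(scores) {
  stopifnot(all(c("method", "dataset", "p") %in% names(scores)))
  if (all(is.na(scores$p))) stop("all cells missing")
  methods <- sort(unique(scores$method))
  datasets <- sort(unique(scores$dataset))
  mat <- matrix(NA_real_, length(methods), length(datasets),
                dimnames = list(methods, datasets))
  mat[cbind(match(scores$method, methods), match(scores$dataset, datasets))] <-
    scores$p
  metaOver <- function(v) if (all(is.na(v))) NA_real_ else fisherMetaP(v[!is.na(v)])
  mMeta <- apply(mat, 1, metaOver)
  dMeta <- apply(mat, 2, metaOver)
  rankOf <- function(v) rank(v, ties.method = "first", na.last = "keep")
  list(matrix = mat,
       methods = data.frame(method = methods, metaP = mMeta,
                            rank = rankOf(mMeta),
                            nMissing = rowSums(is.na(mat)),
                            row.names = NULL, stringsAsFactors = FALSE),
       datasets = data.frame(dataset = datasets, metaP = dMeta,
                             rank = rankOf(dMeta),
                             nMissing = colSums(is.na(mat)),
                             row.names = NULL, stringsAsFactors = FALSE))
}
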