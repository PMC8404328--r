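# Gene-based GWAS scoring: SNP p-values are mapped to genes, fused to
# gene-level p-values, and a module score is the chi-square fusion of its
# gene p-values — the workflow's selection metric ("genomic concordance").
# SNPs are treated as independent; LD-aware correction is out of scope and
# matches the simulator, which generates no LD.

#' Map SNPs to genes by windowed closest-gene assignment
#'
#' A SNP is assigned to the gene whose window
#' \code{[start - windowBp, end + windowBp)} contains it; when several
#' windows contain it, the gene whose body is closest wins (distance 0
#' inside the body), with ties going to the gene with the smaller start and
#' then the lexicographically smaller symbol. SNPs outside every window stay
#' unassigned (count reported via a message). GWAS chromosome labels absent
#' from the coordinates are an error.
#'
#' @param gwas a \linkS4class{GwasSummary}.
#' @param coords a \linkS4class{GeneCoordinates}.
#' @param windowBp flanking window in base pairs (default 50000).
#' @return named list: gene -> numeric vector of its SNP p-values.
#' @export
mapSnpsToGenes <- function(gwas, coords, windowBp = 50000L) {
  snps <- gwasRecords(gwas)
  gr <- coordRecords(coords)
  badChr <- setdiff(unique(snps$chr), unique(gr$chrom))
  if (length(badChr))
    stop("GWAS chromosome label(s) not present in coordinates: ",
         paste(badChr, collapse = ", "))
  assignedGene <- rep(NA_character_, nrow(snps))
  assignedDist <- rep(Inf, nrow(snps))
  assignedStart <- rep(Inf, nrow(snps))
  for (ch in unique(gr$chrom)) {
    gi <- which(gr$chrom == ch)
    si <- which(snps$chr == ch)
    if (!length(si)) next
    pos <- snps$pos0[si]
    for (k in gi) {
      s <- gr$start[k]; e <- gr$end[k]; gn <- gr$gene[k]
      inWin <- pos >= s - windowBp & pos < e + windowBp
      if (!any(inWin)) next
      d <- ifelse(pos < s, s - pos, ifelse(pos >= e, pos - e + 1L, 0L))
      better <- inWin & (d < assignedDist[si] |
        (d == assignedDist[si] & (s < assignedStart[si] |
          (s == assignedStart[si] & gn < assignedGene[si] &
           !is.na(assignedGene[si])))))
      better[is.na(better)] <- FALSE
      w <- si[better]
      assignedGene[w] <- gn
      assignedDist[w] <- d[better]
      assignedStart[w] <- s
    }
  }
  unassigned <- sum(is.na(assignedGene))
  if (unassigned) message(unassigned, " SNP(s) outside all gene windows")
  ok <- !is.na(assignedGene)
  split(snps$p[ok], assignedGene[ok])
}

#' Fuse a gene's SNP p-values into one gene-level p-value
#'
#' Two fusion rules over the K mapped SNPs:
#' \describe{
#'   \item{sidak_min}{\eqn{1 - (1 - \min_i p_i)^K}, the minimum-p ("max"
#'     statistic) analogue; the default.}
#'   \item{sum_chi2}{\eqn{T = \sum_i Q_{\chi^2_1}(1 - p_i)} referred to the
#'     upper tail of \eqn{\chi^2_K}, the sum-statistic analogue.}
#' }
#' Both reduce to the SNP p-value at K = 1.
#'
#' @param snpPs numeric vector of SNP p-values (non-empty).
#' @param method "sidak_min" or "sum_chi2".
#' @return gene-level p-value in (0, 1].
#' @export
geneScore <- function(snpPs, method = c("sidak_min", "sum_chi2")) {
  method <- match.arg(method)
  if (!length(snpPs)) stop("empty SNP p-value list")
  K <- length(snpPs)
  p <- if (method == "sidak_min") {
    1 - (1 - min(snpPs))^K
  } else {
    T <- sum(qchisq(snpPs, df = 1, lower.tail = FALSE))
    pchisq(T, df = K, lower.tail = FALSE)
  }
  max(p, .Machine$double.xmin)
}

#' Gene score table from GWAS and coordinates
#'
#' Convenience wrapper: [mapSnpsToGenes()] then [geneScore()] per gene.
#'
#' @inheritParams mapSnpsToGenes
#' @param method fusion rule, see [geneScore()].
#' @return data.frame with columns \code{gene}, \code{p}, \code{K} (mapped
#'   SNP count, >= 1 for every listed gene).
#' @export
geneScoreTable <- function(gwas, coords, windowBp = 50000L,
                           method = c("sidak_min", "sum_chi2")) {
  method <- match.arg(method)
  byGene <- mapSnpsToGenes(gwas, coords, windowBp)
  data.frame(gene = names(byGene),
             p = vapply(byGene, geneScore, 1.0, method = method),
             K = vapply(byGene, length, 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analytic chi-square module score
#'
#' Fuses the gene-level p-values of the module genes:
#' \eqn{T = \sum_g Q_{\chi^2_1}(1 - p_g)} over the k module genes present in
#' the score table, referred to the upper tail of \eqn{\chi^2_k}. Module
#' genes absent from the table are dropped from k (count reported via a
#' message); a module with no scored gene is an error, distinct from p = 1.
#'
#' @param module a \linkS4class{Module} or character vector of genes.
#' @param geneScores data.frame from [geneScoreTable()].
#' @param tag label for the score (defaults to the module provenance).
#' @return A \linkS4class{ModuleScore} with the analytic p-value.
#' @export
scoreModuleAnalytic <- function(module, geneScores, tag = NULL) {
  genes <- if (is(module, "Module")) moduleGenes(module) else unique(module)
  if (is.null(tag))
    tag <- if (is(module, "Module"))
      paste(moduleProvenance(module), collapse = "/") else ""
  idx <- match(genes, geneScores$gene)
  dropped <- sum(is.na(idx))
  if (dropped) message(dropped, " module gene(s) without a gene score dropped")
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no module gene has a gene score")
  pg <- geneScores$p[idx]
  T <- sum(qchisq(pg, df = 1, lower.tail = FALSE))
  k <- length(idx)
  p <- max(pchisq(T, df = k, lower.tail = FALSE), .Machine$double.xmin)
  new("ModuleScore", tag = tag, statistic = T, df = as.integer(k), p = p)
}

#' Empirical (permutation) module score
#'
#' Monte-Carlo guard on the analytic approximation: B gene sets of the same
#' size are drawn uniformly without replacement from all scored genes, and
#' the empirical p-value is \eqn{(\#\{T_{null} \ge T_{obs}\} + 1)/(B + 1)}.
#'
#' @inheritParams scoreModuleAnalytic
#' @param B number of null draws (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return A \linkS4class{ModuleScore} carrying both the analytic and the
#'   empirical p-value.
#' @export
scoreModuleEmpirical <- function(module, geneScores, B = 10000L, seed,
                                 tag = NULL) {
  obs <- scoreModuleAnalytic(module, geneScores, tag = tag)
  k <- obs@df
  if (nrow(geneScores) <= k)
    stop("background must be strictly larger than the module")
  q <- qchisq(geneScores$p, df = 1, lower.tail = FALSE)
  set.seed(seed)
  Tnull <- vapply(seq_len(B), function(b) sum(q[sample.int(length(q), k)]), 1.0)
  emp <- (sum(Tnull >= obs@statistic) + 1) / (B + 1)
  initialize(obs, empiricalP = emp, B = as.numeric(B), seed = as.numeric(seed))
}
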