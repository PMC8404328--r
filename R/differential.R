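# Per-gene case/control differential statistics and seed-gene selection.
# The differential model is the ordinary equal-variance two-sample t-test —
# the same point estimates as a linear model with a group indicator, without
# empirical-Bayes variance shrinkage; a deliberate, documented choice to
# keep the stage self-contained.

#' Per-gene two-group differential table
#'
#' Equal-variance two-sample t-test per gene (case minus control), two-sided
#' p-values, Benjamini-Hochberg adjustment over all genes, and an
#' ascending-p rank (ties broken by larger |t|, then gene symbol). Genes
#' with zero pooled variance get t = 0 and p = 1 with a warning (a constant
#' gene therefore has effect 0 and p 1).
#'
#' @param x an \linkS4class{OmicsMatrix} with >= 2 samples per group.
#' @return data.frame with columns \code{gene}, \code{effect}, \code{t},
#'   \code{p}, \code{p_adj}, \code{rank}.
#' @export
differentialTable <- function(x) {
  stopifnot(is(x, "OmicsMatrix"))
  m <- omicsValues(x)
  g <- sampleGroups(x)
  case <- m[, g == "case", drop = FALSE]
  ctrl <- m[, g == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  ss1 <- rowSums((case - m1)^2); ss2 <- rowSums((ctrl - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  effect <- m1 - m2
  tstat <- ifelse(se > 0, effect / se, 0)
  p <- 2 * pt(-abs(tstat), df)
  zeroVar <- sp2 <= 0
  if (any(zeroVar)) {
    warning(sum(zeroVar), " gene(s) with zero pooled variance; p set to 1")
    p[zeroVar] <- 1
    tstat[zeroVar] <- 0
  }
  p <- pmax(p, .Machine$double.xmin)  # keep the (0, 1] invariant
  padj <- benjaminiHochberg(p)
  gene <- rownames(m)
  ord <- order(p, -abs(tstat), gene)
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  data.frame(gene = gene, effect = effect, t = tstat, p = p, p_adj = padj,
             rank = rank, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment (via \code{stats::p.adjust}), with input
#' validation: all p-values must be in (0, 1] and the input non-empty. The
#' input order is preserved.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differential seed genes for network module detection
#'
#' Restricts the differential table to genes present in the network, then
#' takes the top \code{ceiling(fraction * count)} genes by ascending p
#' (the "dynamic cutoff": the top 5 percent by default). Ties at the
#' boundary are broken by larger |t|, then lexicographically smaller gene
#' symbol, so selection is deterministic and invariant to input row order.
#'
#' @param table differential table from [differentialTable()].
#' @param network a \linkS4class{GeneNetwork} (or character vector of genes).
#' @param fraction selection fraction in (0, 1]; default 0.05.
#' @return A \linkS4class{SeedSet}.
#' @export
selectSeedGenes <- function(table, network, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  genes <- if (is(network, "GeneNetwork")) networkNodes(network)
           else as.character(network)
  tab <- table[table$gene %in% genes, , drop = FALSE]
  if (!nrow(tab)) stop("no differential-table gene is present in the network")
  n <- ceiling(fraction * nrow(tab))
  ord <- order(tab$p, -abs(tab$t), tab$gene)
  new("SeedSet", genes = sort(tab$gene[ord][seq_len(n)]),
      fraction = fraction, source = "differential")
}

#' Aggregate probe-level differential statistics to genes
#'
#' Gene p-value is the Sidak-corrected minimum probe p,
#' \eqn{1 - (1 - \min_i p_i)^K} over the gene's K probes; effect and t are
#' taken from the minimum-p probe. BH adjustment and ranks are recomputed at
#' the gene level. Probes absent from the map are dropped (count reported
#' via a message).
#'
#' @param probeTable differential table over probes (column \code{gene}
#'   holds the probe id).
#' @param probeGeneMap data.frame with columns \code{probe}, \code{gene}.
#' @return gene-level differential table, same columns as
#'   [differentialTable()].
#' @export
aggregateProbes <- function(probeTable, probeGeneMap) {
  if (!all(c("probe", "gene") %in% names(probeGeneMap)))
    stop("probeGeneMap must have columns probe, gene")
  idx <- match(probeTable$gene, probeGeneMap$probe)
  unmapped <- sum(is.na(idx))
  if (unmapped)
    message(unmapped, " unmapped probe(s) dropped")
  tab <- probeTable[!is.na(idx), , drop = FALSE]
  gene <- probeGeneMap$gene[idx[!is.na(idx)]]
  if (!nrow(tab)) stop("no probe maps to a gene")
  sp <- split(seq_len(nrow(tab)), gene)
  rows <- lapply(names(sp), function(gn) {
    i <- sp[[gn]]
    K <- length(i)
    best <- i[which.min(tab$p[i])]
    pGene <- 1 - (1 - min(tab$p[i]))^K
    data.frame(gene = gn, effect = tab$effect[best], t = tab$t[best],
               p = max(pGene, .Machine$double.xmin),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjaminiHochberg(out$p)
  ord <- order(out$p, -abs(out$t), out$gene)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
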