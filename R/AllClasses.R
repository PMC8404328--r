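#' @import methods
#' @importFrom stats pchisq phyper pt qchisq rbinom rchisq rnorm runif var
#'   cor hclust cutree as.dist plogis qlogis fisher.test binom.test p.adjust
#'   setNames
#' @importFrom utils read.delim write.table head combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' GeneNetwork: an undirected weighted gene-gene interaction graph
#'
#' Container for a STRING-style interaction network. Edges are unordered gene
#' pairs with an integer confidence score in \code{[0, 1000]}. The node set
#' may include isolated genes (e.g. all simulated genes), but every edge
#' endpoint must be a node.
#'
#' @slot nodes character vector of gene symbols (unique, non-empty strings).
#' @slot edges data.frame with columns \code{gene1}, \code{gene2},
#'   \code{score}; pairs are stored canonically with \code{gene1 < gene2}.
#'
#' @seealso [readNetwork()], [asIgraph()], [networkNodes()], [networkEdges()]
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "data.frame"),
  prototype(nodes = character(0),
            edges = data.frame(gene1 = character(0), gene2 = character(0),
                               score = integer(0),
                               stringsAsFactors = FALSE)))

setValidity("GeneNetwork", function(object) {
  e <- object@edges
  msg <- character(0)
  if (!all(c("gene1", "gene2", "score") %in% names(e)))
    return("edges must have columns gene1, gene2, score")
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node names")
  if (any(!nzchar(object@nodes)))
    msg <- c(msg, "empty node name")
  if (nrow(e)) {
    if (any(e$gene1 == e$gene2))
      msg <- c(msg, "self-loop edge present")
    if (any(e$gene1 > e$gene2))
      msg <- c(msg, "edges not in canonical gene1 < gene2 order")
    if (anyDuplicated(paste(e$gene1, e$gene2, sep = "\r")))
      msg <- c(msg, "duplicate edge")
    if (!all(c(e$gene1, e$gene2) %in% object@nodes))
      msg <- c(msg, "edge endpoint not in node set")
    if (any(e$score < 0L | e$score > 1000L))
      msg <- c(msg, "edge score outside [0, 1000]")
  }
  if (length(msg)) msg else TRUE
})

#' Module: a gene set with provenance
#'
#' A (possibly empty) set of gene symbols together with tags recording how it
#' was produced: the detection method, the dataset it came from and the omic.
#' Extra method-specific detail (e.g. the DIAMOnD addition order or a
#' consensus rule) is carried in \code{info}.
#'
#' @slot genes character vector of unique gene symbols (may be empty).
#' @slot method,dataset,omic single character provenance tags ("" if unset).
#' @slot info list of optional method-specific metadata.
#' @export
setClass("Module",
  representation(genes = "character", method = "character",
                 dataset = "character", omic = "character", info = "list"),
  prototype(genes = character(0), method = "", dataset = "", omic = "",
            info = list()))

setValidity("Module", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in module")
  for (s in c("method", "dataset", "omic"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must be length 1", s))
  if (length(msg)) msg else TRUE
})

#' ModuleScore: chi-square enrichment score of a module
#'
#' The result of fusing gene-level GWAS p-values over the genes of a module:
#' statistic \eqn{T = \sum_g Q_{\chi^2_1}(1 - p_g)} on \code{df} degrees of
#' freedom (one per scored gene) with its analytic upper-tail p-value, and an
#' optional empirical permutation p-value.
#'
#' @slot tag single character label (usually the module provenance).
#' @slot statistic numeric chi-square fusion statistic T.
#' @slot df integer, number of module genes that had a gene score.
#' @slot p analytic upper-tail p-value in (0, 1].
#' @slot empiricalP empirical p-value (NA unless computed).
#' @slot B number of null draws behind \code{empiricalP} (NA if analytic only).
#' @slot seed RNG seed used for the empirical p-value (NA if analytic only).
#' @export
setClass("ModuleScore",
  representation(tag = "character", statistic = "numeric", df = "integer",
                 p = "numeric", empiricalP = "numeric", B = "numeric",
                 seed = "numeric"),
  prototype(tag = "", statistic = NA_real_, df = 0L, p = NA_real_,
            empiricalP = NA_real_, B = NA_real_, seed = NA_real_))

setValidity("ModuleScore", function(object) {
  msg <- character(0)
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    msg <- c(msg, "analytic p outside (0, 1]")
  if (!is.na(object@empiricalP)) {
    if (is.na(object@B)) msg <- c(msg, "empirical p without B")
    else if (object@empiricalP < 1 / (object@B + 1) || object@empiricalP > 1)
      msg <- c(msg, "empirical p outside [1/(B+1), 1]")
  }
  if (length(msg)) msg else TRUE
})

#' OmicsMatrix: case/control omics measurements
#'
#' A \linkS4class{SummarizedExperiment} holding one features-by-samples assay
#' with a mandatory \code{group} column ("case"/"control") in \code{colData}
#' and a declared measurement kind. Methylation beta values must lie in
#' \code{[0, 1]}. At least two samples per group are required, as every
#' downstream differential test needs a within-group variance.
#'
#' @slot kind either "expression" (log-scale intensities) or
#'   "methylation-beta" (beta values in \code{[0, 1]}).
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  representation(kind = "character"),
  prototype(kind = "expression"))

setValidity("OmicsMatrix", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L ||
      !object@kind %in% c("expression", "methylation-beta"))
    return("kind must be 'expression' or 'methylation-beta'")
  m <- SummarizedExperiment::assay(object)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd))
    return("colData must contain a 'group' column")
  g <- as.character(cd$group)
  if (!all(g %in% c("case", "control")))
    msg <- c(msg, "group labels must be 'case' or 'control'")
  if (sum(g == "case") < 2L || sum(g == "control") < 2L)
    msg <- c(msg, "need >= 2 samples per group")
  if (object@kind == "methylation-beta" &&
      (any(m < 0) || any(m > 1)))
    msg <- c(msg, "methylation beta values outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GwasSummary: SNP-level association summary statistics
#'
#' Per-variant p-values with genomic location. Positions are stored 0-based
#' internally (one convention throughout the package); the on-disk TSV format
#' is 1-based and converted at read/write time.
#'
#' @slot records data.frame with columns \code{snp}, \code{chr}, \code{pos0}
#'   (0-based integer position) and \code{p} in (0, 1].
#' @export
setClass("GwasSummary",
  representation(records = "data.frame"),
  prototype(records = data.frame(snp = character(0), chr = character(0),
                                 pos0 = integer(0), p = numeric(0),
                                 stringsAsFactors = FALSE)))

setValidity("GwasSummary", function(object) {
  r <- object@records
  msg <- character(0)
  if (!all(c("snp", "chr", "pos0", "p") %in% names(r)))
    return("records must have columns snp, chr, pos0, p")
  if (anyDuplicated(r$snp))
    msg <- c(msg, sprintf("duplicate variant id(s): %s",
                          paste(unique(r$snp[duplicated(r$snp)]), collapse = ", ")))
  if (any(r$pos0 < 0L)) msg <- c(msg, "position < 1 (1-based)")
  if (any(r$p <= 0 | r$p > 1)) msg <- c(msg, "p-value outside (0, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneCoordinates: gene locations on synthetic or real chromosomes
#'
#' 0-based half-open intervals \code{[start, end)}, the BED convention,
#' with at most one record per gene.
#'
#' @slot records data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end}.
#' @export
setClass("GeneCoordinates",
  representation(records = "data.frame"),
  prototype(records = data.frame(gene = character(0), chrom = character(0),
                                 start = integer(0), end = integer(0),
                                 stringsAsFactors = FALSE)))

setValidity("GeneCoordinates", function(object) {
  r <- object@records
  msg <- character(0)
  if (!all(c("gene", "chrom", "start", "end") %in% names(r)))
    return("records must have columns gene, chrom, start, end")
  if (anyDuplicated(r$gene))
    msg <- c(msg, sprintf("duplicate gene record(s): %s",
                          paste(unique(r$gene[duplicated(r$gene)]), collapse = ", ")))
  if (any(r$start >= r$end)) msg <- c(msg, "interval with start >= end")
  if (any(!nzchar(r$chrom))) msg <- c(msg, "empty chromosome label")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene sets (GMT semantics)
#'
#' @slot sets named list of character vectors; names unique, sets non-empty.
#' @slot descriptions named character vector parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"),
  prototype(sets = list(), descriptions = character(0)))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  nm <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "set names must be unique and non-empty")
    if (any(vapply(object@sets, length, 1L) == 0L))
      msg <- c(msg, "empty gene set")
    if (length(object@descriptions) != length(object@sets))
      msg <- c(msg, "descriptions must parallel sets")
  }
  if (length(msg)) msg else TRUE
})

#' SeedSet: differential seed genes feeding network module detection
#'
#' @slot genes character vector of seed gene symbols.
#' @slot fraction the selection fraction applied (top fraction by p-value).
#' @slot source tag of the differential table the seeds came from.
#' @export
setClass("SeedSet",
  representation(genes = "character", fraction = "numeric", source = "character"),
  prototype(genes = character(0), fraction = NA_real_, source = ""))

#' SimulationConfig: study conditions for the synthetic-data generator
#'
#' Defaults define the package's reference synthetic study: a 1000-gene
#' network with a planted 50-gene dense module, 40 cases vs 40 controls per
#' omic with a 1.5 SD effect on module genes, and GWAS SNPs with
#' noncentrality 15 at module-gene loci.
#'
#' @slot nGenes total number of genes.
#' @slot backgroundEdgeProb,moduleEdgeProb Bernoulli edge probabilities
#'   outside/inside the planted module.
#' @slot moduleSize number of planted module genes.
#' @slot perfectClique if TRUE the planted module is a complete subgraph
#'   (for exact-recovery tests) instead of a dense random one.
#' @slot nCase,nControl samples per group per omic dataset.
#' @slot effectSize case shift on signal genes, in units of \code{noiseSd}
#'   (applied on the log-odds scale for methylation).
#' @slot noiseSd residual standard deviation.
#' @slot snpsPerGeneRange integer (min, max) SNPs assigned per gene.
#' @slot gwasNcp noncentrality lambda of the chi-square(1) association signal
#'   at SNPs of signal genes; 0 means no genetic signal.
#' @slot signalGeneFraction fraction of module genes carrying signal.
#' @slot riskSetCount,riskSetSize,riskSetOverlap number, size and
#'   module-overlap fraction of the simulated risk-factor gene sets.
#' @slot genesPerChrom,geneLength,geneSpacing synthetic chromosome layout
#'   (base pairs); spacing exceeds geneLength + 2 x the default 50 kb scoring
#'   window so gene windows do not overlap by default.
#' @slot scoreThreshold working confidence threshold; simulated edge scores
#'   are drawn uniformly above it.
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", backgroundEdgeProb = "numeric",
                 moduleSize = "integer", moduleEdgeProb = "numeric",
                 perfectClique = "logical",
                 nCase = "integer", nControl = "integer",
                 effectSize = "numeric", noiseSd = "numeric",
                 snpsPerGeneRange = "integer", gwasNcp = "numeric",
                 signalGeneFraction = "numeric",
                 riskSetCount = "integer", riskSetSize = "integer",
                 riskSetOverlap = "numeric",
                 genesPerChrom = "integer", geneLength = "integer",
                 geneSpacing = "integer", scoreThreshold = "integer"),
  prototype(nGenes = 1000L, backgroundEdgeProb = 0.005,
            moduleSize = 50L, moduleEdgeProb = 0.6, perfectClique = FALSE,
            nCase = 40L, nControl = 40L, effectSize = 1.5, noiseSd = 1,
            snpsPerGeneRange = c(1L, 5L), gwasNcp = 15,
            signalGeneFraction = 1,
            riskSetCount = 5L, riskSetSize = 100L, riskSetOverlap = 0.3,
            genesPerChrom = 100L, geneLength = 10000L, geneSpacing = 200000L,
            scoreThreshold = 700L))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@moduleSize >= object@nGenes)
    msg <- c(msg, "moduleSize must be < nGenes")
  for (s in c("backgroundEdgeProb", "moduleEdgeProb", "signalGeneFraction",
              "riskSetOverlap"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, sprintf("%s outside [0, 1]", s))
  if (object@moduleEdgeProb < object@backgroundEdgeProb)
    msg <- c(msg, "moduleEdgeProb must be >= backgroundEdgeProb")
  if (length(object@snpsPerGeneRange) != 2L ||
      object@snpsPerGeneRange[1] < 1L ||
      object@snpsPerGeneRange[1] > object@snpsPerGeneRange[2])
    msg <- c(msg, "snpsPerGeneRange must be (min, max) with 1 <= min <= max")
  if (object@gwasNcp < 0) msg <- c(msg, "gwasNcp must be >= 0")
  if (object@riskSetSize > object@nGenes)
    msg <- c(msg, "riskSetSize must be <= nGenes")
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth emitted by the simulator
#'
#' Records the planted module and, per signal channel, which genes carry the
#' differential or genetic signal, plus the membership of the simulated
#' risk-factor sets and the derived seeds used per component. This is the
#' oracle every recovery test compares against.
#'
#' @slot module character vector of planted module genes.
#' @slot signalGenes named list (expression, methylation, gwas) of flagged
#'   gene vectors, each a subset of the module.
#' @slot riskMembership named list of risk-set gene vectors.
#' @slot seeds named numeric vector of derived per-component seeds.
#' @export
setClass("PlantedTruth",
  representation(module = "character", signalGenes = "list",
                 riskMembership = "list", seeds = "numeric"),
  prototype(module = character(0), signalGenes = list(),
            riskMembership = list(), seeds = numeric(0)))
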