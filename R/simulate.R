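# Synthetic planted-module study generator. One master seed fixes every
# component through documented derived seeds, so a whole multi-omic study
# (network, expression, methylation, coordinates, GWAS, risk sets) is
# reproducible from a single integer.

#' Create a simulation configuration
#'
#' All arguments default to the package's reference study conditions; see
#' \linkS4class{SimulationConfig} for the meaning of each parameter.
#'
#' @param nGenes,backgroundEdgeProb,moduleSize,moduleEdgeProb,perfectClique
#'   network parameters.
#' @param nCase,nControl,effectSize,noiseSd omics parameters.
#' @param snpsPerGeneRange,gwasNcp GWAS parameters.
#' @param signalGeneFraction fraction of module genes flagged as carrying
#'   signal in every channel.
#' @param riskSetCount,riskSetSize,riskSetOverlap risk-factor set parameters.
#' @param genesPerChrom,geneLength,geneSpacing,scoreThreshold layout and
#'   score parameters.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 1000L, backgroundEdgeProb = 0.005,
                             moduleSize = 50L, moduleEdgeProb = 0.6,
                             perfectClique = FALSE,
                             nCase = 40L, nControl = 40L,
                             effectSize = 1.5, noiseSd = 1,
                             snpsPerGeneRange = c(1L, 5L), gwasNcp = 15,
                             signalGeneFraction = 1,
                             riskSetCount = 5L, riskSetSize = 100L,
                             riskSetOverlap = 0.3,
                             genesPerChrom = 100L, geneLength = 10000L,
                             geneSpacing = 200000L, scoreThreshold = 700L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), backgroundEdgeProb = backgroundEdgeProb,
      moduleSize = as.integer(moduleSize), moduleEdgeProb = moduleEdgeProb,
      perfectClique = perfectClique,
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      effectSize = effectSize, noiseSd = noiseSd,
      snpsPerGeneRange = as.integer(snpsPerGeneRange), gwasNcp = gwasNcp,
      signalGeneFraction = signalGeneFraction,
      riskSetCount = as.integer(riskSetCount),
      riskSetSize = as.integer(riskSetSize), riskSetOverlap = riskSetOverlap,
      genesPerChrom = as.integer(genesPerChrom),
      geneLength = as.integer(geneLength),
      geneSpacing = as.integer(geneSpacing),
      scoreThreshold = as.integer(scoreThreshold))
}

# Component indices for derived seeds; fixed so that the mapping
# master seed -> per-component seed is stable across versions.
.seedComponents <- c(network = 1L, flags = 2L, expression = 3L,
                     methylation = 4L, coords = 5L, gwas = 6L, risk = 7L)

#' Derive a per-component RNG seed from a master seed
#'
#' Deterministic integer mixing (all arithmetic exact in doubles, result
#' below 2^31) so each simulator component gets an independent, reproducible
#' stream.
#' @param master master seed (integer).
#' @param component one of "network", "flags", "expression", "methylation",
#'   "coords", "gwas", "risk".
#' @return an integer seed.
#' @export
deriveSeed <- function(master, component) {
  k <- .seedComponents[[component]]
  lo <- as.numeric(master) %% 65536
  hi <- as.numeric(master) %/% 65536
  as.integer((lo * 30269 + hi * 30307 + k * 104729) %% 2147483563)
}

.geneNames <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a random network with a planted dense module
#'
#' Background gene pairs are connected independently with
#' \code{backgroundEdgeProb}; pairs inside the planted module with
#' \code{moduleEdgeProb} (or all of them when \code{perfectClique} is TRUE).
#' Edge confidence scores are drawn uniformly above the working threshold.
#' The planted-module membership and the per-channel signal-gene flags
#' (\code{round(signalGeneFraction * moduleSize)} genes per channel, the same
#' genes for every channel) are returned as the ground truth.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param seed master seed; per-component seeds are derived internally.
#' @return list with elements \code{network} (\linkS4class{GeneNetwork},
#'   all genes as nodes) and \code{truth} (\linkS4class{PlantedTruth}).
#' @export
generateNetwork <- function(config, seed) {
  validObject(config)
  n <- config@nGenes
  genes <- .geneNames(n)
  set.seed(deriveSeed(seed, "network"))
  moduleGenes <- sort(sample(genes, config@moduleSize))
  inMod <- genes %in% moduleGenes
  # all unordered pairs via column-expansion; n ~ 1000 so ~5e5 pairs
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  pModPair <- inMod[i] & inMod[j]
  prob <- ifelse(pModPair,
                 if (config@perfectClique) 1 else config@moduleEdgeProb,
                 config@backgroundEdgeProb)
  keep <- runif(length(prob)) < prob
  scores <- as.integer(config@scoreThreshold + 1L +
    floor(runif(sum(keep)) * (1000L - config@scoreThreshold)))
  net <- GeneNetwork(data.frame(gene1 = genes[i[keep]], gene2 = genes[j[keep]],
                                score = scores, stringsAsFactors = FALSE),
                     nodes = genes)
  set.seed(deriveSeed(seed, "flags"))
  nSignal <- round(config@signalGeneFraction * config@moduleSize)
  signal <- sort(sample(moduleGenes, nSignal))
  truth <- new("PlantedTruth", module = moduleGenes,
               signalGenes = list(expression = signal, methylation = signal,
                                  gwas = signal),
               riskMembership = list(),
               seeds = c(master = as.numeric(seed)))
  list(network = net, truth = truth)
}

#' Generate a case/control omics matrix with signal on flagged genes
#'
#' Expression: values ~ Normal(0, noiseSd), with cases shifted by
#' \code{effectSize} on the flagged genes. Methylation: the same model on
#' the log-odds scale, mapped back through the logistic function so beta
#' values stay in \code{[0, 1]}; per-gene baselines are drawn uniformly in
#' logit space so genes differ in mean methylation.
#'
#' @param truth \linkS4class{PlantedTruth} from [generateNetwork()].
#' @param config a \linkS4class{SimulationConfig}.
#' @param kind "expression" or "methylation-beta".
#' @param seed master seed (the per-kind component seed is derived from it).
#' @param dataset optional integer offset so several independent datasets of
#'   the same kind can be generated from one master seed.
#' @return An \linkS4class{OmicsMatrix}.
#' @export
generateOmics <- function(truth, config, kind = c("expression", "methylation-beta"),
                          seed, dataset = 1L) {
  kind <- match.arg(kind)
  validObject(config)
  if (config@nCase < 2L || config@nControl < 2L)
    stop("need nCase >= 2 and nControl >= 2")
  comp <- if (kind == "expression") "expression" else "methylation"
  set.seed(deriveSeed(seed, comp) + as.integer(dataset) - 1L)
  genes <- .geneNames(config@nGenes)
  nS <- config@nCase + config@nControl
  groups <- c(rep("case", config@nCase), rep("control", config@nControl))
  flagged <- genes %in% truth@signalGenes[[comp]]
  noise <- matrix(rnorm(length(genes) * nS, sd = config@noiseSd),
                  nrow = length(genes))
  shift <- outer(ifelse(flagged, config@effectSize, 0), groups == "case")
  if (kind == "expression") {
    m <- noise + shift
  } else {
    base <- qlogis(runif(length(genes), 0.1, 0.9))
    m <- plogis(base + noise + shift)
  }
  rownames(m) <- genes
  colnames(m) <- sprintf("%s_%s%02d", ifelse(groups == "case", "case", "ctrl"),
                         substr(kind, 1, 4), seq_len(nS))
  colnames(m) <- make.unique(colnames(m))
  OmicsMatrix(m, groups, kind)
}

#' Generate non-overlapping gene coordinates on synthetic chromosomes
#'
#' Genes are laid out left to right, \code{genesPerChrom} per chromosome,
#' each of length \code{geneLength}, spaced \code{geneSpacing} apart (wider
#' than gene length + 2 x the default scoring window, so windows are
#' disjoint). The assignment of genes to slots is a seeded permutation.
#'
#' @param network a \linkS4class{GeneNetwork}; every node gets coordinates.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @return A \linkS4class{GeneCoordinates} (0-based half-open).
#' @export
generateGeneCoords <- function(network, config, seed) {
  genes <- networkNodes(network)
  if (!length(genes)) stop("network has no nodes")
  set.seed(deriveSeed(seed, "coords"))
  genes <- sample(genes)
  n <- length(genes)
  slot <- seq_len(n) - 1L
  chromIdx <- slot %/% config@genesPerChrom
  within <- slot %% config@genesPerChrom
  start <- within * config@geneSpacing
  GeneCoordinates(genes, sprintf("chr%d", chromIdx + 1L),
                  start, start + config@geneLength)
}

#' Generate GWAS summary statistics with signal at flagged genes
#'
#' Each gene receives K ~ Uniform\{snpsPerGeneRange\} SNPs at uniform
#' positions inside its body. Null SNPs get p ~ Uniform(0, 1); SNPs of
#' GWAS-flagged genes get the upper-tail central chi-square(1) p-value of a
#' noncentral chi-square(1, lambda) draw, the standard association-signal
#' model under independence (no LD is simulated).
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param coords \linkS4class{GeneCoordinates} covering every gene.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @return A \linkS4class{GwasSummary}.
#' @export
generateGwas <- function(truth, coords, config, seed) {
  if (config@gwasNcp < 0) stop("gwasNcp must be >= 0")
  r <- coordRecords(coords)
  set.seed(deriveSeed(seed, "gwas"))
  rng <- config@snpsPerGeneRange
  K <- sample(seq(rng[1], rng[2]), nrow(r), replace = TRUE)
  gene <- rep(r$gene, K)
  chr <- rep(r$chrom, K)
  start <- rep(r$start, K)
  len <- rep(r$end - r$start, K)
  pos0 <- start + floor(runif(length(gene)) * len)
  isSignal <- gene %in% truth@signalGenes$gwas & config@gwasNcp > 0
  p <- runif(length(gene))
  if (any(isSignal)) {
    x <- rchisq(sum(isSignal), df = 1, ncp = config@gwasNcp)
    p[isSignal] <- pchisq(x, df = 1, lower.tail = FALSE)
  }
  p <- pmax(p, .Machine$double.xmin)
  snp <- sprintf("rs_%s_%d", gene, unlist(lapply(K, seq_len)))
  GwasSummary(snp, chr, pos0 + 1L, p)
}

#' Generate risk-factor gene sets overlapping the planted module
#'
#' Each of \code{riskSetCount} sets draws
#' \code{round(riskSetSize * riskSetOverlap)} genes (capped at the module
#' size) from the planted module and the remainder uniformly from non-module
#' genes, without replacement — emulating per-risk-factor lists of top
#' differentially methylated genes that share genes with the disease module.
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @return A \linkS4class{GeneSetCollection}; membership is also recorded in
#'   the returned collection's sets.
#' @export
generateRiskSets <- function(truth, config, seed) {
  if (config@riskSetSize > config@nGenes)
    stop("riskSetSize must be <= nGenes")
  genes <- .geneNames(config@nGenes)
  nonMod <- setdiff(genes, truth@module)
  set.seed(deriveSeed(seed, "risk"))
  nOv <- min(round(config@riskSetSize * config@riskSetOverlap),
             length(truth@module))
  sets <- lapply(seq_len(config@riskSetCount), function(i) {
    ov <- if (nOv > 0) sample(truth@module, nOv) else character(0)
    rest <- sample(nonMod, config@riskSetSize - nOv)
    sort(c(ov, rest))
  })
  names(sets) <- sprintf("risk_factor_%d", seq_along(sets))
  GeneSetCollection(sets, rep("simulated risk-factor DMG list", length(sets)))
}

#' Simulate a complete multi-omic study and write it to disk
#'
#' Generates the network, one or more expression and methylation datasets,
#' gene coordinates, GWAS summary statistics and risk-factor gene sets from
#' one master seed, and writes network.tsv, expr_<i>.tsv, meth_<i>.tsv,
#' labels.tsv, coords.bed, gwas.tsv, risk_sets.gmt and truth.json under
#' \code{outDir}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed master seed.
#' @param outDir output directory (created if absent).
#' @param nDatasetsPerOmic independent datasets per omic (default 2).
#' @return (invisibly) a list with all generated in-memory objects.
#' @export
simulateStudy <- function(config, seed, outDir, nDatasetsPerOmic = 2L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateNetwork(config, seed)
  coords <- generateGeneCoords(gen$network, config, seed)
  gwas <- generateGwas(gen$truth, coords, config, seed)
  risk <- generateRiskSets(gen$truth, config, seed)
  expr <- lapply(seq_len(nDatasetsPerOmic), function(i)
    generateOmics(gen$truth, config, "expression", seed, dataset = i))
  meth <- lapply(seq_len(nDatasetsPerOmic), function(i)
    generateOmics(gen$truth, config, "methylation-beta", seed, dataset = i))
  names(expr) <- sprintf("expr_%d", seq_along(expr))
  names(meth) <- sprintf("meth_%d", seq_along(meth))
  writeNetwork(gen$network, file.path(outDir, "network.tsv"))
  writeGeneCoords(coords, file.path(outDir, "coords.bed"))
  writeGwas(gwas, file.path(outDir, "gwas.tsv"))
  writeGeneSets(risk, file.path(outDir, "risk_sets.gmt"))
  for (nm in names(expr))
    writeOmicsMatrix(expr[[nm]], file.path(outDir, paste0(nm, ".tsv")),
                     file.path(outDir, paste0(nm, "_labels.tsv")))
  for (nm in names(meth))
    writeOmicsMatrix(meth[[nm]], file.path(outDir, paste0(nm, ".tsv")),
                     file.path(outDir, paste0(nm, "_labels.tsv")))
  truth <- gen$truth
  jsonlite::write_json(
    list(module = truth@module, signalGenes = truth@signalGenes,
         seed = seed),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = gen$network, truth = truth, coords = coords,
                 gwas = gwas, riskSets = risk, expression = expr,
                 methylation = meth))
}
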