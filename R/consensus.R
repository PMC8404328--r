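# Consensus construction across methods/datasets, top-module selection,
# multi-omic intersection and the end-to-end integration workflow.

#' Consensus x-of-n module
#'
#' A gene belongs to the consensus iff it appears in at least \code{minCount}
#' of the input modules. The rule is recorded in the provenance
#' (method \code{consensus_<x>of<n>}).
#'
#' @param modules non-empty list of \linkS4class{Module} objects.
#' @param minCount x, with 1 <= x <= length(modules).
#' @param omic optional omic tag for the result.
#' @return A \linkS4class{Module}.
#' @export
consensusModule <- function(modules, minCount, omic = "") {
  if (!length(modules)) stop("empty module list")
  n <- length(modules)
  if (minCount < 1 || minCount > n)
    stop("minCount must be between 1 and the number of modules")
  counts <- table(unlist(lapply(modules, moduleGenes)))
  genes <- names(counts)[counts >= minCount]
  Module(genes, method = sprintf("consensus_%dof%d", minCount, n),
         dataset = paste(vapply(modules, function(m) m@dataset, ""),
                         collapse = "+"),
         omic = omic,
         info = list(minCount = as.integer(minCount), n = as.integer(n)))
}

#' Select the top-scoring significant modules
#'
#' Keeps modules with analytic p < \code{alpha}, sorts by ascending p with
#' ties broken by smaller module size then dataset tag, and returns the
#' first \code{m} (possibly fewer).
#'
#' @param scored list of \code{list(module =, score =)} pairs
#'   (\linkS4class{Module}, \linkS4class{ModuleScore}).
#' @param m maximum number to keep (>= 1).
#' @param alpha significance threshold (default 0.05).
#' @return the selected sub-list, sorted; may be empty.
#' @export
selectTopModules <- function(scored, m = 4L, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  if (!length(scored)) return(list())
  p <- vapply(scored, function(s) s$score@p, 1.0)
  keep <- which(p < alpha)
  if (!length(keep)) return(list())
  sz <- vapply(scored[keep], function(s) moduleSize(s$module), 1L)
  ds <- vapply(scored[keep], function(s) s$module@dataset, "")
  ord <- keep[order(p[keep], sz, ds)]
  scored[head(ord, m)]
}

#' Intersect two modules
#'
#' Set intersection of the gene sets; provenance concatenates the parents.
#'
#' @param a,b \linkS4class{Module} objects.
#' @return A \linkS4class{Module}.
#' @export
intersectModules <- function(a, b) {
  Module(intersect(moduleGenes(a), moduleGenes(b)),
         method = paste0("intersect(", a@method, ",", b@method, ")"),
         dataset = paste0(a@dataset, "&", b@dataset),
         omic = paste0(a@omic, "&", b@omic))
}

#' Run the multi-omic integration workflow
#'
#' The full pipeline, per omic and dataset: differential table, module
#' detection, GWAS chi-square scoring; then per omic: selection of the top
#' \code{m} significant modules, a sweep of the consensus threshold x over
#' 1..(number of selected modules) keeping the consensus with the smallest
#' GWAS p (ties prefer the larger, stricter x); finally the intersection of
#' the two per-omic consensus winners is scored and reported. With
#' \code{consensus = "fixed:x"} the sweep is replaced by the given x.
#'
#' @param datasets named list of omics; each element a named list of
#'   \linkS4class{OmicsMatrix} datasets. Exactly the omic names given are
#'   integrated (two for a multi-omic module).
#' @param network a \linkS4class{GeneNetwork}.
#' @param gwas a \linkS4class{GwasSummary}.
#' @param coords a \linkS4class{GeneCoordinates}.
#' @param detector "clique_sum" (default), "diamond" or "coexpression".
#' @param m top modules per omic (default 4).
#' @param alpha module significance threshold (default 0.05).
#' @param consensus "sweep" (default) or "fixed:x".
#' @param seedFraction differential seed fraction (default 0.05).
#' @param windowBp,scoreMethod gene-scoring parameters, see
#'   [geneScoreTable()].
#' @param seed integer seed recorded in the report (the default pipeline is
#'   deterministic; the seed feeds any empirical scoring added downstream).
#' @return An \code{IntegrationReport}: list with \code{records} (one row
#'   per omic/dataset stage), \code{perOmic} (top modules, consensus choice
#'   and winner per omic), \code{finalModule}, \code{finalScore},
#'   \code{integrated} flag and \code{message}.
#' @export
runMultiomicWorkflow <- function(datasets, network, gwas, coords,
                                 detector = c("clique_sum", "diamond",
                                              "coexpression"),
                                 m = 4L, alpha = 0.05, consensus = "sweep",
                                 seedFraction = 0.05, windowBp = 50000L,
                                 scoreMethod = "sidak_min", seed = 1L) {
  detector <- match.arg(detector)
  gs <- geneScoreTable(gwas, coords, windowBp, scoreMethod)
  records <- list()
  perOmic <- list()
  for (omic in sort(names(datasets))) {
    dsList <- datasets[[omic]]
    scored <- list()
    for (dsName in sort(names(dsList))) {
      mat <- dsList[[dsName]]
      dt <- differentialTable(mat)
      mod <- switch(detector,
        clique_sum = detectCliqueSum(network, dt, seedFraction,
                                     dataset = dsName, omic = omic)$module,
        diamond = detectDiamond(network,
                                selectSeedGenes(dt, network, seedFraction),
                                dataset = dsName, omic = omic),
        coexpression = detectCoexpression(mat, dt,
                                          seedFraction = seedFraction,
                                          dataset = dsName, omic = omic))
      sc <- if (moduleSize(mod) == 0 ||
                !any(moduleGenes(mod) %in% gs$gene)) NULL
            else suppressMessages(scoreModuleAnalytic(mod, gs))
      records[[length(records) + 1L]] <- data.frame(
        omic = omic, dataset = dsName, method = detector,
        size = moduleSize(mod),
        p = if (is.null(sc)) NA_real_ else sc@p,
        stringsAsFactors = FALSE)
      if (!is.null(sc))
        scored[[length(scored) + 1L]] <- list(module = mod, score = sc)
    }
    top <- selectTopModules(scored, m = m, alpha = alpha)
    if (!length(top)) {
      perOmic[[omic]] <- list(top = list(), consensus = NULL,
                              consensusP = NA_real_, minCount = NA_integer_)
      next
    }
    mods <- lapply(top, `[[`, "module")
    xs <- if (startsWith(consensus, "fixed:")) {
      as.integer(sub("fixed:", "", consensus))
    } else seq_along(mods)
    bestMod <- NULL; bestP <- Inf; bestX <- NA_integer_
    for (x in xs) {
      cm <- consensusModule(mods, x, omic = omic)
      if (moduleSize(cm) == 0 || !any(moduleGenes(cm) %in% gs$gene)) next
      cp <- suppressMessages(scoreModuleAnalytic(cm, gs))@p
      # ties prefer the stricter (larger) threshold: <= keeps the later x
      if (cp <= bestP) { bestP <- cp; bestMod <- cm; bestX <- x }
    }
    perOmic[[omic]] <- list(top = top, consensus = bestMod,
                            consensusP = if (is.null(bestMod)) NA_real_ else bestP,
                            minCount = bestX)
  }
  records <- do.call(rbind, records)
  winners <- Filter(Negate(is.null), lapply(perOmic, `[[`, "consensus"))
  if (length(winners) < length(datasets)) {
    return(structure(list(records = records, perOmic = perOmic,
                          finalModule = Module(character(0),
                                               method = "multiomic"),
                          finalScore = NULL, integrated = FALSE,
                          message = "no integration possible", seed = seed),
                     class = "IntegrationReport"))
  }
  final <- Reduce(intersectModules, winners)
  finalScore <- if (moduleSize(final) > 0 &&
                    any(moduleGenes(final) %in% gs$gene))
    suppressMessages(scoreModuleAnalytic(final, gs)) else NULL
  structure(list(records = records, perOmic = perOmic, finalModule = final,
                 finalScore = finalScore, integrated = TRUE, message = "ok",
                 seed = seed),
            class = "IntegrationReport")
}

#' @export
print.IntegrationReport <- function(x, ...) {
  cat("IntegrationReport:", x$message, "\n")
  cat(sprintf("  %d stage record(s) over %d omic(s)\n",
              nrow(x$records), length(x$perOmic)))
  if (x$integrated) {
    cat(sprintf("  final module: %d gene(s)", moduleSize(x$finalModule)))
    if (!is.null(x$finalScore))
      cat(sprintf(", GWAS p = %.3g", x$finalScore@p))
    cat("\n")
  }
  invisible(x)
}
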