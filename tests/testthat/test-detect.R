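# Module detectors: clique enumeration, clique-sum, DIAMOnD, co-expression.

test_that("maximal cliques on hand-checkable graphs", {
  # triangle plus pendant edge
  net <- makeNet("A-B,A-C,B-C,C-D")
  cl <- enumerateMaximalCliques(net, minSize = 2)
  expect_equal(cl, list(c("A", "B", "C"), c("C", "D")))
  # K4 is its own unique maximal clique
  k4 <- makeNet("A-B,A-C,A-D,B-C,B-D,C-D")
  expect_equal(enumerateMaximalCliques(k4, minSize = 3), list(c("A", "B", "C", "D")))
  # edgeless graph
  expect_equal(enumerateMaximalCliques(GeneNetwork(nodes = c("A", "B")), 2),
               list())
  expect_error(enumerateMaximalCliques(k4, minSize = 2, maxCliques = 0),
               "threshold")
})

test_that("clique enumeration equals brute-force power-set checking", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    net <- randomNet(n, runif(1, 0.2, 0.7), seed = i)
    minSize <- sample(2:3, 1)
    expect_identical(enumerateMaximalCliques(net, minSize),
                     bruteMaximalCliques(net, minSize))
  }
})

test_that("clique-sum recovers a planted perfect clique from flagged seeds", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- simulationConfig(nGenes = 100L, moduleSize = 10L,
                            backgroundEdgeProb = 0.02, moduleEdgeProb = 1,
                            perfectClique = TRUE, nCase = 20L, nControl = 20L,
                            effectSize = 3)
    gen <- generateNetwork(cfg, s)
    x <- generateOmics(gen$truth, cfg, "expression", s)
    dt <- differentialTable(x)
    mod <- detectCliqueSum(gen$network, dt)$module
    if (all(truthModule(gen$truth) %in% moduleGenes(mod))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("clique-sum handles no-signal and empty-clique cases", {
  net <- makeNet("A-B,A-C,B-C,C-D,D-E")
  # seeds are D,E (smallest p) and no clique contains them both
  tab <- data.frame(gene = c("A", "B", "C", "D", "E"), effect = 0,
                    t = c(0.1, 0.1, 0.1, 5, 5),
                    p = c(0.9, 0.9, 0.9, 1e-6, 1e-6), stringsAsFactors = FALSE)
  res <- detectCliqueSum(net, tab, seedFraction = 0.2, minCliqueSize = 3)
  expect_s4_class(res$module, "Module")
  expect_equal(moduleProvenance(res$module)[["method"]], "clique_sum")
  # invariance to diff-table row order
  res2 <- detectCliqueSum(net, tab[sample(5), ], seedFraction = 0.2)
  expect_equal(moduleGenes(res2$module), moduleGenes(res$module))
  # an edgeless network yields an empty module, not an error
  res3 <- detectCliqueSum(GeneNetwork(nodes = c("A", "B", "D")), tab,
                          seedFraction = 0.5)
  expect_equal(moduleSize(res3$module), 0L)
})

test_that("DIAMOnD base cases and tie-breaking", {
  # zero iterations: module = seeds in network
  net <- makeNet("C-L1,C-L2,C-L3,C-L4")
  m0 <- detectDiamond(net, c("C", "NOT_PRESENT"), nIterations = 0)
  expect_equal(moduleGenes(m0), "C")
  expect_error(detectDiamond(net, "NOT_PRESENT"), "seed")
  # star centre as seed: all leaves tie, lexicographically smallest added first
  m1 <- detectDiamond(net, "C", nIterations = 1)
  expect_equal(m1@info$additionOrder, "L1")
  # grows by exactly one gene per iteration, superset of in-network seeds
  m3 <- detectDiamond(net, "C", nIterations = 3)
  expect_equal(moduleSize(m3), 4L)
  expect_true("C" %in% moduleGenes(m3))
  expect_equal(m3@info$additionOrder, c("L1", "L2", "L3"))
})

test_that("DIAMOnD greedy choice equals an exhaustive hypergeometric scan", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    net <- randomNet(n, runif(1, 0.08, 0.3), seed = 1000 + i)
    seeds <- sample(networkNodes(net), 3)
    members <- seeds
    got <- detectDiamond(net, seeds, nIterations = 3)@info$additionOrder
    for (step in seq_along(got)) {
      expect_equal(got[step], diamondStepOracle(net, members))
      members <- c(members, got[step])
    }
  }
})

test_that("co-expression detector recovers a planted correlation block", {
  jaccards <- vapply(1:10, function(s) {
    set.seed(s)
    nPer <- 20; nS <- 16
    # two correlated blocks plus independent noise genes
    blockOf <- function(r) {
      shared <- rnorm(nS)
      t(vapply(seq_len(nPer), function(i)
        sqrt(r) * shared + sqrt(1 - r) * rnorm(nS), numeric(nS)))
    }
    m <- rbind(blockOf(0.8), blockOf(0.8), matrix(rnorm(20 * nS), 20))
    rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
    colnames(m) <- sprintf("S%02d", seq_len(nS))
    x <- OmicsMatrix(m, rep(c("case", "control"), each = nS / 2))
    block1 <- rownames(m)[1:nPer]
    # flag block-1 genes as differential so seed enrichment picks that block
    tab <- data.frame(gene = rownames(m), effect = 0, t = 1,
                      p = ifelse(rownames(m) %in% block1, 1e-5, 0.9),
                      stringsAsFactors = FALSE)
    mod <- detectCoexpression(x, tab, minModuleSize = 10)
    got <- moduleGenes(mod)
    length(intersect(got, block1)) / length(union(got, block1))
  }, 1.0)
  expect_gte(median(jaccards), 0.8)
})

test_that("co-expression detection is deterministic and tags provenance", {
  x <- makeOmics(nGenes = 40, nCase = 5, nControl = 5, seed = 12)
  tab <- differentialTable(x)
  a <- detectCoexpression(x, tab, minModuleSize = 5)
  b <- detectCoexpression(x, tab, minModuleSize = 5)
  expect_identical(moduleGenes(a), moduleGenes(b))
  expect_equal(moduleProvenance(a)[["method"]], "coexpression")
  # constant genes are removed; too few genes left -> empty module + warning
  m <- omicsValues(x)
  m[1:35, ] <- 1
  expect_warning(e <- detectCoexpression(OmicsMatrix(m, sampleGroups(x)), tab,
                                         minModuleSize = 10),
                 "minModuleSize")
  expect_equal(moduleSize(e), 0L)
})

test_that("independent-noise matrices rarely produce seed-enriched modules", {
  ps <- vapply(1:100, function(s) {
    x <- makeOmics(nGenes = 50, nCase = 5, nControl = 5, seed = 3000 + s)
    tab <- differentialTable(x)
    mod <- detectCoexpression(x, tab, minModuleSize = 8)
    if (moduleSize(mod) == 0) 1 else mod@info$seedEnrichmentP
  }, 1.0)
  expect_gte(mean(ps > 0.05), 0.9)
})
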