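# Benchmark statistics: meta-P, binomials, Spearman, enrichment, overlap,
# centrality, ranking table.

test_that("Fisher's method matches its chi-square closed forms", {
  # single p is unchanged: chi2(2) tail of -2 ln p is p itself
  expect_equal(fisherMetaP(0.2), 0.2)
  # (0.1, 0.1): X = 9.2103, p = exp(-X/2) (1 + X/2)
  X <- -2 * sum(log(c(0.1, 0.1)))
  expect_equal(X, 9.21034, tolerance = 1e-5)
  expect_equal(fisherMetaP(c(0.1, 0.1)), exp(-X / 2) * (1 + X / 2))
  expect_equal(fisherMetaP(c(0.1, 0.1)), 0.05605, tolerance = 1e-4)
  expect_equal(fisherMetaP(c(1, 1, 1)), 1)
  # k identical p's equal the chi2(2k) tail at -2k ln p
  for (k in c(2, 5, 8)) {
    p <- 0.037
    expect_equal(fisherMetaP(rep(p, k)),
                 pchisq(-2 * k * log(p), 2 * k, lower.tail = FALSE))
  }
  expect_error(fisherMetaP(numeric(0)), "empty")
})

test_that("binomial excess test agrees with brute-force summation", {
  brute <- function(k, n, a)
    sum(vapply(k:n, function(i) choose(n, i) * a^i * (1 - a)^(n - i), 1.0))
  set.seed(23)
  for (i in 1:20) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    expect_equal(binomialExcessP(k, n, 0.05), brute(k, n, 0.05),
                 tolerance = 1e-10)
  }
  expect_equal(binomialExcessP(0, 10), 1)
  expect_equal(binomialExcessP(2, 6, 0.05),
               1 - 0.95^6 - 6 * 0.05 * 0.95^5, tolerance = 1e-12)
  expect_error(binomialExcessP(2, 6, 0), "alpha0")
  expect_error(binomialExcessP(7, 6), "k")
})

test_that("Spearman rho and its t-approximation behave", {
  x <- 1:20
  expect_equal(spearmanRhoP(x, x^2)$rho, 1)  # monotone -> rho 1
  set.seed(3)
  y <- rnorm(20)
  res <- spearmanRhoP(x, y)
  expect_equal(res$p, rhoToP(res$rho, 20))
  expect_error(spearmanRhoP(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearmanRhoP(1:3, 1:3), "length")
})

test_that("Fisher exact enrichment: counts, odds ratio and exact p", {
  # perfect independence table (2,2,2,2)
  u <- sprintf("g%d", 1:8)
  e <- fisherExactEnrichment(u[1:4], u[c(1, 2, 5, 6)], u)
  expect_equal(unname(e$table), c(2, 2, 2, 2))
  expect_equal(e$or, 1)
  expect_equal(e$pTwoSided, 1)
  # one-sided p equals exhaustive enumeration on small universes
  set.seed(77)
  for (i in 1:5) {
    uni <- sprintf("u%02d", 1:12)
    A <- sample(uni, 5)
    B <- sample(uni, 4)
    e2 <- fisherExactEnrichment(A, B, uni)
    expect_equal(e2$pOneSided, bruteEnrichmentP(A, B, uni), tolerance = 1e-10)
  }
  # A subset of B: one-sided p is the hypergeometric point-mass sum
  A <- u[1:2]; B <- u[1:5]
  e3 <- fisherExactEnrichment(A, B, u)
  expect_equal(e3$pOneSided, bruteEnrichmentP(A, B, u), tolerance = 1e-10)
  expect_true(e3$haldane)  # a = |A| zeroes the A-only cell
  expect_error(fisherExactEnrichment("a", "b", character(0)), "universe")
})

test_that("permutation overlap test is bounded, reproducible and near analytic", {
  set.seed(1)
  uni <- sprintf("g%03d", 1:200)
  mod <- sample(uni, 30)
  gset <- c(sample(mod, 10), sample(setdiff(uni, mod), 30))
  r1 <- overlapPermutationP(mod, gset, uni, B = 2000, seed = 11)
  r2 <- overlapPermutationP(mod, gset, uni, B = 2000, seed = 11)
  expect_identical(r1$empiricalP, r2$empiricalP)
  expect_gte(r1$empiricalP, 1 / 2001)
  mcsd <- sqrt(r1$analyticP * (1 - r1$analyticP) / 2000)
  expect_lt(abs(r1$empiricalP - r1$analyticP), 3 * mcsd + 1 / 2001)
  expect_error(overlapPermutationP(mod, gset, uni, B = 50, seed = 1), "B")
  expect_error(overlapPermutationP(c(mod, "NOT"), gset, uni, B = 200, seed = 1),
               "subset")
})

test_that("pairwise overlap ORs produce the right pair counts and null mean", {
  uni <- sprintf("g%03d", 1:300)
  set.seed(4)
  lists <- c(lapply(1:11, function(i) sample(uni, 40)),
             lapply(1:9, function(i) sample(uni, 40)))
  names(lists) <- c(sprintf("expr%02d", 1:11), sprintf("meth%02d", 1:9))
  groups <- setNames(rep(c("expression", "methylation"), c(11, 9)),
                     names(lists))
  res <- pairwiseOverlapOR(lists, uni, groups)
  expect_equal(nrow(res$pairs), 190L)
  gs <- res$groupSummary
  expect_equal(gs$nPairs[gs$groupA == "expression" & gs$groupB == "expression"], 55L)
  expect_equal(gs$nPairs[gs$groupA == "methylation" & gs$groupB == "methylation"], 36L)
  expect_equal(gs$nPairs[gs$groupA == "expression" & gs$groupB == "methylation"], 99L)
  # identical lists: large but finite OR via the Haldane correction
  ident <- pairwiseOverlapOR(list(a = uni[1:20], b = uni[1:20]), uni)
  expect_true(is.finite(ident$pairs$or) && ident$pairs$or > 100)
  expect_error(pairwiseOverlapOR(list(a = "zzz", b = uni[1:3]), uni), "subset")
})

test_that("independent random lists have mean pairwise OR near 1", {
  uni <- sprintf("g%03d", 1:400)
  meanORs <- vapply(1:100, function(s) {
    set.seed(s)
    lists <- lapply(1:4, function(i) sample(uni, 60))
    names(lists) <- paste0("l", 1:4)
    mean(pairwiseOverlapOR(lists, uni)$pairs$or)
  }, 1.0)
  expect_lt(abs(mean(meanORs) - 1), 3 * sd(meanORs) / sqrt(length(meanORs)) + 0.05)
})

test_that("module centrality matches hand-computed betweenness", {
  # path A-B-C: B intermediates the single pair
  expect_equal(moduleCentrality(makeNet("A-B,B-C"), "B"), 1)
  # leaves have betweenness 0
  expect_equal(moduleCentrality(makeNet("A-B,B-C"), c("A", "C")), 0)
  # centre of a 5-node star
  star <- makeNet("C-L1,C-L2,C-L3,C-L4")
  expect_equal(moduleCentrality(star, "C"), 1)
  expect_warning(v <- moduleCentrality(star, c("C", "NOT")), "dropped")
  expect_equal(v, 1)
  expect_error(suppressWarnings(moduleCentrality(star, "NOT")), "no module gene")
})

test_that("benchmark table ranks methods by meta-P and tolerates missing cells", {
  s <- data.frame(method = "m1", dataset = "d1", p = 0.02,
                  stringsAsFactors = FALSE)
  bt <- buildBenchmarkTable(s)
  expect_equal(bt$methods$metaP, 0.02)
  expect_equal(bt$datasets$metaP, 0.02)
  # systematically smaller p's rank first; NA cells excluded and counted
  set.seed(10)
  grid <- expand.grid(method = c("good", "bad"), dataset = paste0("d", 1:6),
                      stringsAsFactors = FALSE)
  grid$p <- ifelse(grid$method == "good", runif(6, 0, 0.01), runif(6, 0.2, 1))
  grid$p[grid$method == "bad" & grid$dataset == "d1"] <- NA
  bt2 <- buildBenchmarkTable(grid)
  expect_equal(bt2$methods$method[bt2$methods$rank == 1], "good")
  expect_equal(bt2$methods$nMissing[bt2$methods$method == "bad"], 1L)
  # row order of the input does not change ranks
  bt3 <- buildBenchmarkTable(grid[sample(nrow(grid)), ])
  expect_identical(bt2$methods, bt3$methods)
  expect_error(buildBenchmarkTable(data.frame(method = "m", dataset = "d",
                                              p = NA_real_)), "missing")
})
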