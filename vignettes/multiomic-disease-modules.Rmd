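---
title: "Detecting and scoring multi-omic disease modules with modflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring multi-omic disease modules with modflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modflow)
```

## The problem

Complex diseases perturb many interacting genes at once, across several
regulatory layers. A *disease module* is a cohesive set of genes in a
gene–gene interaction network whose joint perturbation associates with the
disease. Many algorithms propose such modules from case/control omics data,
but their outputs differ widely, and a module is only useful if it can be
validated against *independent* evidence. modflow implements a complete,
self-contained version of one validation-driven workflow:

1. per-dataset differential analysis of case/control expression or
   methylation matrices;
2. network module detection from differential seed genes, with one exemplar
   per algorithm family (clique-based, seed-expansion, co-expression);
3. module scoring by *genomic concordance*: gene-based GWAS p-values fused
   into a chi-square module score, so that modules enriched for
   disease-associated variants score well;
4. consensus construction across datasets within each omic, selection of the
   best-scoring consensus, and intersection across omics into a multi-omic
   module;
5. benchmark statistics for comparing methods and datasets (Fisher's method
   meta p-values, excess-significance binomial tests, enrichment odds
   ratios, permutation overlap tests, betweenness diagnostics).

Because the interesting claims are about *recovery* — does the workflow find
the genes that truly carry signal? — the package ships a synthetic-data
generator that plants a known module and emits matched network, omics, GWAS
and risk-factor data. Every downstream stage is tested against that planted
truth.

## The synthetic study

`simulationConfig()` fixes the reference study conditions:

* a network of 1000 genes; background gene pairs connected independently
  with probability 0.005 (mean degree about 5, the sparse regime of
  high-confidence interactomes after thresholding), and the 50 planted
  module genes connected with probability 0.6 — a dense community, *not* a
  perfect clique, so clique-based detection recovers it only partially, as
  with real data. A `perfectClique` toggle exists for exact-recovery tests.
  Edge confidence scores are drawn uniformly above the working threshold
  (700), mirroring score-thresholded interaction databases.
* two omics with 40 cases vs 40 controls each; signal genes are shifted by
  1.5 standard deviations in cases. For methylation the shift acts on the
  log-odds of the beta value and is mapped back through the logistic
  function, which keeps beta values in [0, 1] under any shift and makes the
  effect size comparable across genes with different baseline methylation.
* GWAS summary statistics with 1–5 SNPs per gene; SNPs of signal genes draw
  their test statistic from a noncentral chi-square(1) with noncentrality 15
  (a strongly powered association, two-sided z about 3.9 on average), null
  SNPs are Uniform(0, 1). No linkage disequilibrium is simulated, which is
  exactly the regime in which the scorer's independence assumption is valid.
* five risk-factor gene sets of 100 genes, 30% drawn from the module — the
  realistic situation where lifestyle-factor gene lists share part, but not
  all, of a disease module.

One master seed drives everything through fixed per-component derived seeds
(`deriveSeed()`), so a complete study is reproducible from a single integer.

What the simulator does *not* emulate: LD blocks and allele frequencies,
batch effects, cell-type composition, gene-length biases, and correlated
background co-expression. Tests passing on these data therefore demonstrate
algorithmic correctness and calibration under the stated model, not
performance on real cohorts.

## Differential analysis and seed genes

`differentialTable()` performs the ordinary equal-variance two-sample t-test
per gene — the same point estimates as a linear model with a group
indicator. We deliberately omit empirical-Bayes variance moderation: it
keeps the stage self-contained and its null calibration exact, at the cost
of some power at very small sample sizes. Genes with zero pooled variance
get t = 0 and p = 1 (never NaN), with a warning. p-values are BH-adjusted
(`benjaminiHochberg()`, the standard step-up) and ranked ascending with ties
broken by larger |t|, then gene symbol, so results are reproducible and
independent of input row order.

`selectSeedGenes()` implements the dynamic cutoff: the top 5% (by default)
of genes by p-value. The table is restricted to network genes *before*
counting, because the seeds exist to drive network methods; applying the
fraction to all measured genes and intersecting afterwards would make the
effective seed count depend on array coverage. This ordering is a design
choice of this package; with full-coverage data the two orders coincide.

For methylation arrays, `aggregateProbes()` collapses probe-level statistics
to genes with the Šidák-corrected minimum probe p-value,
$p_g = 1 - (1 - \min_i p_i)^K$ over the gene's $K$ probes. The rule is exact
under independent null probes, conservative under positive dependence, and
keeps a single interpretable representative probe (the minimum-p one) for
effect and t.

## Module detection

**Clique-based** (`detectCliqueSum()`): every maximal clique of the network
(size ≥ 3; bare edges carry no community information) is tested for seed
enrichment with a one-sided hypergeometric test against the network gene
universe, p-values are BH-adjusted across cliques, and the module is the
union of cliques significant at 0.01. The published clique scorers this
reconstructs are described only at the level of "differentially expressed
cliques"; maximal cliques + hypergeometric seed enrichment + BH + union is
our documented reconstruction of that idea. Whether the original used exact
or permutation clique scoring does not change this surface; the
hypergeometric test covers both readings.

**Seed-based** (`detectDiamond()`): DIAMOnD-style expansion. At each
iteration the non-member node with the smallest hypergeometric tail
probability of its link count into the current member set joins the module.
We implement the unweighted variant (seed weight 1) and specify tie-breaking
fully — more links to members first, then the lexicographically smaller
symbol — because the original leaves ties unspecified and reproducibility
requires a total order. Every greedy step is tested against an independent
exhaustive scan.

**Co-expression** (`detectCoexpression()`): signed adjacency
$a_{ij} = ((1+\mathrm{cor}_{ij})/2)^6$, average-linkage clustering of
$1 - a$, and a sweep over 20 evenly spaced cut heights keeping the cut with
the most clusters of at least 10 genes; among those clusters the one most
enriched for seed genes is returned. This deliberately replaces topological
overlap and dynamic tree cutting with plain adjacency and a height sweep:
the exemplar's role in the workflow is to represent the co-expression family
with transparent, dependency-free numerics. On ties in the cluster count the
*highest* qualifying height wins — the coarsest cut — because lower cuts can
split a genuine module into fragments that still clear the minimum size,
and fragments score worse than whole modules downstream.

## GWAS scoring

`mapSnpsToGenes()` assigns each SNP to the gene whose ±50 kb window contains
it, choosing the closest gene body on overlaps (ties: smaller start, then
symbol). Positions are handled 0-based half-open internally; GWAS input is
1-based and BED is 0-based, both converted at the boundary — one convention
inside the package eliminates a classic off-by-one source.

`geneScore()` fuses a gene's SNP p-values either as the Šidák-corrected
minimum (default; the "max statistic" analogue) or as a chi-square sum
statistic; both reduce to the SNP p-value for single-SNP genes. Which
variant the original pipeline used is not documented, so both are exposed.

`scoreModuleAnalytic()` computes
$T = \sum_g Q_{\chi^2_1}(1 - p_g)$ over the module genes present in the
score table and refers it to $\chi^2_k$. Genes without scores are dropped
from $k$ rather than imputed (their absence is a coverage fact, not
evidence), with the count reported. Under the simulator's independence the
analytic null is exact; `scoreModuleEmpirical()` provides a same-size
resampling guard with empirical p $(\#\{T_\mathrm{null} \ge T_\mathrm{obs}\}+1)/(B+1)$,
which stays valid under dependence between gene scores. One subtlety worth
recording: the empirical p is calibrated *conditionally on the realised
score pool*, while the analytic p is marginal; with small gene pools the two
differ by the pool's sampling error, which is why the calibration tests draw
fresh null tables per replicate.

## Consensus and integration

`consensusModule()` keeps genes present in at least x of n input modules.
`runMultiomicWorkflow()` runs the whole pipeline: per omic it selects the
top 4 significant modules by GWAS p (ties prefer smaller modules: same
evidence from fewer genes is stronger), sweeps the consensus threshold x
over 1..n, scores every consensus and keeps the minimum-p one. The original
workflow fixed its thresholds (3/4 transcriptomic, 2/4 methylomic) after
inspection; the sweep automates exactly that inspection, and the fixed rule
remains available via `consensus = "fixed:x"`. Threshold ties prefer the
larger x — the smaller, higher-confidence module. The final module is the
intersection of the two per-omic winners and is therefore contained in each,
an invariant the tests assert. An omic with no significant module yields
"no integration possible" rather than an error: that is a legitimate
scientific outcome of a null study.

## Benchmark statistics

All cross-cutting statistics live in one place: Fisher's method
(`fisherMetaP()`), the exact upper-tail binomial excess-significance test
(`binomialExcessP()`), Spearman correlation with the t-approximation
p-value (`spearmanRhoP()`/`rhoToP()`; the approximation matches printed
values at n in the hundreds, where exact permutation nulls are impractical),
Fisher's exact enrichment with the cross-product odds ratio
(`fisherExactEnrichment()`; the Haldane–Anscombe +0.5 correction is applied
only when a cell is zero and is flagged), the permutation overlap test with
its analytic hypergeometric twin (`overlapPermutationP()`; extreme
enrichments lie beyond any feasible Monte-Carlo resolution, so the analytic
tail is always reported alongside), pairwise study-overlap odds ratios with
group summaries (`pairwiseOverlapOR()`), betweenness diagnostics
(`moduleCentrality()`) and the method-by-dataset ranking table
(`buildBenchmarkTable()`, where empty-module cells contribute no p-value to
meta-P rather than p = 1 — an empty module is absence of a result, not a
null result; the alternative convention can be applied by pre-filling).

## Numerical and degenerate-input choices

* p-values are floored at the smallest positive double wherever a transform
  could underflow to 0, preserving the (0, 1] contract.
* Zero p-values in GWAS input are rejected at read time (they break the
  chi-square transforms); pre-floor them if a tool emits hard zeros.
* Score filtering is strict (score > threshold) everywhere, and one
  convention is documented rather than mixing ≥ and >.
* All orderings that affect results (seed selection, DIAMOnD ties, clique
  sorting, report records) have total tie-break rules ending in gene symbol.
* Empty modules are legal values throughout; operations that cannot produce
  a meaningful score on them raise errors distinct from p = 1.

## Problem sizes used by the test-suite

The unit and property suites run the reference study (1000 genes, module 50,
40 vs 40, noncentrality 15) for recovery, 100-seed batches of reduced
studies (300 genes) for null false-module rates, and 1000-replicate draws
for calibration checks — sizes chosen so the whole suite gives stable
verdicts in about a minute on a laptop while keeping every binomial/KS
acceptance band at least three standard deviations wide.

## Known limitations

* No LD-aware gene scoring: on real GWAS with correlated SNPs the gene and
  module scores are anti-conservative; use the empirical scorer with an
  appropriate null or an external LD-aware tool for real data.
* The co-expression exemplar is intentionally minimal and should not be
  read as a WGCNA replacement.
* Identifier mapping is out of scope: gene identity is the bare
  case-sensitive symbol, and mismatched namespaces between files are the
  user's responsibility.
* Two omics are integrated; the interface takes named omic groups, so
  extending to more omics is a matter of iterated intersection, but this is
  untested territory.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulationConfig(nGenes = 300, moduleSize = 20,
                        backgroundEdgeProb = 0.01, nCase = 20, nControl = 20,
                        genesPerChrom = 50)
gen <- generateNetwork(cfg, seed = 1)
coords <- generateGeneCoords(gen$network, cfg, seed = 1)
gwas <- generateGwas(gen$truth, coords, cfg, seed = 1)
datasets <- list(
  expression = list(e1 = generateOmics(gen$truth, cfg, "expression", 1)),
  methylation = list(m1 = generateOmics(gen$truth, cfg, "methylation-beta", 1)))
report <- runMultiomicWorkflow(datasets, gen$network, gwas, coords, seed = 1)
report
intersect(moduleGenes(report$finalModule), truthModule(gen$truth))
```
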