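---
title: "Connectivity-constrained subnetwork decomposition of single-cell expression"
author: "adiponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-constrained subnetwork decomposition of single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiponet)
```

## The problem

Single-cell RNA-seq of differentiating preadipocytes shows strong
transcriptional heterogeneity, but the axes of that heterogeneity are hard
to interpret gene-by-gene. `adiponet` addresses this with two
complementary techniques:

1. **Network module detection.** The z-scored expression matrix is
   decomposed into a small number of rank-1 terms whose gene supports are
   required to induce *connected* subgraphs of a protein–protein
   interaction (PPI) network. Each term is a candidate protein complex or
   pathway ("module") with a per-cell activity profile; modules are ranked
   by the residual error left after removing their term.
2. **Phenotype projection.** Metabolic phenotypes measured on clonally
   expanded preadipocyte lines (basal oxygen consumption OCR, extracellular
   acidification ECAR, radiolabeled glucose uptake, and post-differentiation
   *PPARG* expression) are converted into per-gene Spearman correlation
   vectors and projected onto individual cells, giving every cell a
   phenotype-association score that can be compared between clusters.

## Model and estimator

Let $Y \in \mathbb{R}^{N \times G}$ hold $N$ single-cell profiles (rows) over
$G$ network genes, after the pipeline raw counts $\to \log_2(\mathrm{UMI}+1)
\to$ per-gene z-score. The working hypothesis is that $Y$ is approximately a
sum of a few module terms,

$$Y \approx \sum_k a_k\, b_k^\top,$$

with two biological constraints: the support $S_k = \operatorname{supp}(b_k)$
induces a connected subgraph of the PPI network, and a gene may appear in
several modules (its expression is then a linear mixture of their
activities — one activating, another repressing, and so on).

For a *fixed* support $S$ the least-squares rank-1 term is the leading
singular triplet of the column-restricted matrix $Y_{:,S}$:
$\hat a = \sigma_1 u_1$, $\hat b = v_1$ (zero outside $S$). Its quality is
scored by the residual error over the **full** matrix,

$$r(S) \;=\; \sqrt{\;\lVert Y\rVert_F^2 \;-\; \sigma_1(Y_{:,S})^2\;},$$

which makes residuals of different modules directly comparable: a module
explaining more variance gets a smaller residual regardless of its size.
Two consequences are used as invariants throughout the test suite:
$r(S)^2 + \sigma_1(Y_{:,S})^2 = \lVert Y\rVert_F^2$ exactly, and
$S \subseteq S'$ implies $r(S') \le r(S)$ (adding columns cannot decrease
$\sigma_1$). The loading sign is fixed by $\sum_g b_g \ge 0$ so that fits
are deterministic.

$\sigma_1^2$ is computed as the top eigenvalue of the restricted Gram
matrix $G_{S,S} = (Y^\top Y)_{S,S}$, which is precomputed once — each
candidate support then costs $O(|S|^3)$ instead of a fresh SVD.

## Search

Maximizing $\sigma_1$ over connected subgraphs is NP-hard, so detection
uses a greedy seed-and-expand search with multi-seed restarts:

* **Growth.** From $S = \{\text{seed}\}$, repeatedly add the network
  neighbor of $S$ that most decreases $r(S)$; stop when the best relative
  gain drops below `minGain` (default `1e-4`) or $|S|$ reaches `maxSize`
  (default 80).
* **Pruning.** Then repeatedly remove the cheapest gene whose removal keeps
  $S$ connected, while that removal costs less than `minGain` relative
  residual. Pruning makes the stopping rule symmetric: because larger
  supports always have smaller residuals, a restart that reaches a strong
  module through a few uninformative "path" genes would otherwise beat the
  clean module in restart selection and carry its path into the result.
  With pruning, the reported support no longer depends on whether the seed
  lay inside the module or merely near it.
* **Restarts and ranking.** `detectModules()` runs the search from the
  `nSeeds` (default 50) highest-variance unclaimed genes, keeps the
  lowest-residual module, subtracts its fitted term (deflation), and
  repeats for `K` rounds. Deflation is what lets genes participate in
  several modules. Every reported module is *refit on the original matrix*
  restricted to its support, so the ranked residuals share one scale.
* **Determinism.** All ties (candidate additions, removals, restart
  selection) break by smaller support and then lexicographic gene id;
  identical inputs give bit-identical decompositions.

An exhaustive enumerator of connected induced subgraphs
(`bruteForceBestModule()`, ESU-style, with an enumeration budget) serves as
the optimality oracle on small instances; on random 8–12-node graphs the
multi-seed greedy search attains a residual within 1% of the optimum in the
large majority of trials (tested).

### A note on the relative gain threshold

`minGain` is relative to the current residual, and the residual of a
z-scored matrix grows with $\sqrt{GN}$ while the contribution of a single
uninformative gene to $\sigma_1^2$ is $O(1)$. The threshold therefore
corresponds to an absolute $\sigma_1^2$ increment of roughly
$2 r^2 \cdot \texttt{minGain}$: at the package's reference scale
(~200 genes × 300 cells) this sits comfortably above chance contributions,
while on very small matrices the same relative threshold admits borderline
genes. Analyses on matrices far from the reference scale should revisit
`minGain` accordingly.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `minDetected` | 1000 | QC: a cell is kept iff it has ≥ this many genes with a positive count ("detected"); a cell with exactly 1000 is kept. |
| `constantGenePolicy` | `"drop"` | Genes constant across cells carry no signal and break the unit-SD scaling; they are dropped (or zeroed). |
| `K` | 3 | Modules to extract. |
| `maxSize` | 80 | Support cap per module. The detected module of interest in the motivating analysis had 30 connected genes while downstream enrichment used an 80-gene set; both sizes are reachable through this parameter rather than hard-coded. |
| `nSeeds` | 50 | Restarts per round, from the highest-variance unclaimed genes. |
| `minGain` | 1e-4 | Relative residual improvement required to grow (and to survive pruning). |
| `nBins` | 5 | Equal-count marker bins in `markerTrend()`. |
| `nExtreme` | 7 | Clones per cluster in the extreme-clone phenotype ANOVA. |
| `kRange` | 2–10 | Candidate k for k-medoids clone clustering; `kStar` maximizes average silhouette width. |

## Normalization choices

* z-scores use the sample SD (divisor $n-1$); retained genes satisfy
  per-gene mean within $10^{-8}$ of 0 and SD within $10^{-6}$ of 1, and the
  `ExpressionMatrix` validity method enforces this.
* The matrix is stored gene × cell; the cells × genes orientation used by
  the decomposition is produced internally.
* z-scoring happens *before* restriction to network genes
  (`alignToGraph()`), so a gene's z-score is defined by all cells that
  survived QC, not by the network's gene coverage.
* SIF input unions all interaction types into one unweighted undirected
  edge set; self-loops are dropped (a single-gene interaction cannot
  contribute to between-gene connectivity) but their node is kept.

## Phenotype integration

Per phenotype, `phenotypeVectors()` computes the Spearman correlation of
every gene with the phenotype across clones, using pairwise-complete
observations and average ranks (single-cell zeros make ties the norm, so
the tie convention matters and is fixed). `projectToCells()` then
rank-correlates that per-gene vector with each cell's profile over the
shared genes; constant cell profiles yield `NA` with a warning.
`compareClusterProjections()` runs a one-way ANOVA of the projection scores
between clusters within each day and controls the family-wise error rate
with Bonferroni, $\mathrm{FWER} = \min(1, m\,p)$ over all
(day × phenotype) tests; cells are treated as independent observations.

Clone structure is estimated two ways: k-medoids (PAM) with the silhouette
criterion over `kRange` for the major clusters, and average-linkage
hierarchical clustering on correlation distance ($1-$Pearson) cut at 5 for
subclusters. The distance/linkage pair is a declared default, not an
inference from the motivating study, whose choices are unstated. Donor
effects in clonal profiles can be removed by `subjectCenter()` — a
per-subject mean-centering that stands in for model-based subject
normalization without reproducing it. "Most extreme" clones (undefined in
the source analyses) are defined here as those with the largest absolute
projection along the centroid-difference axis measured from the midpoint
between the two cluster centroids — the clones that separate the clusters
most strongly.

## The synthetic generator

`simulationSpec()` fixes the study conditions under which everything is
validated:

* **PPI graph** (`simulatePPI`): each planted support is wired with a
  random spanning tree (connectivity guaranteed) plus extra within-module
  edges (prob. 0.3), over an Erdős–Rényi background (prob. 0.02).
* **Counts** (`simulateCounts`): latent log2 mean = baseline
  ($\mathcal N(1.5, 1.5^2)$ per gene) + $\sum_k a_k b_k^\top$ with
  $a_k \sim \mathcal N(0, \text{activitySD}^2)$ per cell and loadings of
  magnitude ≈ `loadingScale` with random signs; counts are negative
  binomial (dispersion 0.3 — overdispersion is the regime the z-score
  pipeline must survive) scaled by gamma-distributed per-cell library-size
  factors (shape 10, mean `librarySizeMean`).
* **Latent path** (`simulateActivityMatrix`): the same linear structure
  with unit-SD Gaussian noise, i.e. exactly the model the detector assumes.
  Detection properties (planted-support recovery at 10 genes × 300 cells,
  order-one loadings, unit noise) are measured on this path; the count path
  is validated separately and needs a higher loading scale because count
  noise and depth variation erode the SNR.
* **Clones** (`simulateClones`): 35 clones from two centroids separated by
  5 noise-SDs on 40 informative genes; each of the four phenotypes reads
  out one 15-gene program with a per-clone activity $t \sim \mathcal N(0,1)$
  (phenotype = effect × $t$ + unit noise).

Defaults are chosen once to mirror the scale of the motivating data
(hundreds of cells, tens of clones, ~10–30-gene modules); they are not
adjusted per test. Everything is deterministic given `rngSeed`, and each
generator offsets the seed so combined pipelines do not reuse a stream.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, gene-length or GC biases, or dropout beyond what the negative
binomial produces. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical model, not robustness to every
artifact of real single-cell data.

## Numerical choices and degenerate inputs

* $\sigma_1^2$ via symmetric eigendecomposition of the restricted Gram
  matrix; residuals clamp $\lVert Y\rVert_F^2 - \sigma_1^2$ at 0 before the
  square root.
* A zero restricted matrix returns zero activity, uniform loading, and
  residual $\lVert Y\rVert_F$.
* The exhaustive oracle treats residuals within $10^{-9}$ (relative) as
  tied and resolves ties by smaller support, then lexicographic order.
* Lexicographic comparisons use C-locale (radix) ordering everywhere, so
  results do not depend on the session locale.
* Equal-count binning in `markerTrend()` orders cells by marker value with
  ties broken by cell order, then splits into contiguous chunks.
* `compareClusterProjections()` drops clusters with fewer than 2 scored
  cells and skips (with a message) days left with fewer than 2 clusters.
* In `extremeCloneTest()`, a selected clone missing a phenotype value is
  replaced by the next-most-extreme clone of its cluster, with a message.

## Problem sizes used in the checks

The packaged validation runs at the reference scale: 200 genes × 300 cells
for recovery (40 replicates), 8–12-node graphs for the 50 oracle
comparisons, 1000 replicates for the null FWER rate of the projection
ANOVA and 100 for its power at a 1-SD shift, 30–35 clones for the
clustering checks. These sizes were chosen so that each property is
measured in the regime the method targets while the whole suite stays
quick to run.

## Known limitations

* **Sequencing depth.** The pipeline deliberately stops at
  log2(UMI+1) + z-score, with no per-cell depth normalization. On
  unnormalized counts the library-size factor induces a weak correlation
  across *all* genes; with a large `maxSize` the search can assemble a
  large "depth module" whose $\sigma_1$ beats a small planted module. Keep
  `maxSize` near the expected module scale on count data, or normalize
  depth upstream.
* **Residual ranking favors size.** Because $r(S)$ decreases monotonically
  in $S$, supports of different sizes are not penalized for complexity
  beyond the `minGain` rule; module ranking should be read together with
  module size.
* **Greedy search** carries no optimality guarantee; the oracle-equivalence
  test bounds the gap only on small instances.
* **ANOVA on projections** treats cells as independent, which overstates
  the effective sample size if cells share library or batch structure.
* The accession-derived cell counts of the motivating study (e.g. QC
  retention in its two differentiation experiments) require the original
  GEO data and are outside the package's scope; the QC *rule* (strictly
  fewer than `minDetected` detected genes removes a cell) is what the
  package reproduces and tests.

## A minimal run

```{r example, eval = FALSE}
spec <- simulationSpec(rngSeed = 1L)
sim  <- simulatePPI(spec)
cnt  <- simulateCounts(spec, sim$supports)

z   <- zscoreGenes(logTransform(qcFilterCells(cnt$matrix, minDetected = 50)))
al  <- alignToGraph(z, sim$graph)
dec <- detectModules(al$matrix, al$graph, K = 1, maxSize = 20)
modules(dec)[[1]]

cl   <- simulateClones(spec)
pcs  <- phenotypeVectors(cl$matrix, cl$pheno)
proj <- projectToCells(pcs$glucose_uptake, cl$matrix)
```
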