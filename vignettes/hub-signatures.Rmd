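---
title: "Methods: frequency-weighted hub signatures of tumor aggressiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-weighted hub signatures of tumor aggressiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubsig)
```

## The model

The package works from three inputs: (i) per-sample sets of upregulated
genes, each sample labeled with a cancer type and an aggressiveness
class (H = highly aggressive, L = less aggressive); (ii) an undirected
protein–protein interaction graph whose per-gene degree is the gene's
*connection number*; (iii) gene membership lists for the WNT signaling
pathway and its cross-linked pathways.

The central statistic is multiplicative. For gene $g$ and sample group
$c$ (a class or a cancer type),

$$\mathrm{NormCount}(g,c) = \frac{n(g,c)}{N(c)}, \qquad
  \mathrm{NormConnections}(g,c) = \mathrm{NormCount}(g,c)\, k(g),$$

where $n(g,c)$ counts the group's samples in which $g$ is upregulated,
$N(c)$ is the group size and $k(g)$ the connection number in the *full*
interactome. The rationale: the interactions a protein actually realizes
are taken as proportional to how often it is available (upregulated), so
the product acts as a PPI score; a hub matters only to the extent that
it is recurrently switched on in a class. The implied assumptions are
worth stating: upregulation is treated as binary per sample, degrees are
taken from a single static interactome, and samples are treated as
exchangeable within a group (no per-patient covariates).

## Upregulation calling

`callUpregulated()` reduces a tumor/control count pair to a call set in
three steps: counts are divided by coding-sequence length and put on a
per-million scale (so sequencing depth cancels in the ratio); the
per-gene statistic is $\log_2$ of the (pseudocount-stabilized) ratio;
and the pair's *critical value* is the upper-tail bound of that pair's
own log-differential distribution at $\alpha = 0.025$,
$\bar{x} + z_{1-\alpha}\,s$. Genes strictly above the threshold are
called upregulated.

Two rules are provided because the choice is genuinely open: the
parametric normal-tail rule (default) and the empirical
$(1-\alpha)$-quantile. We default to the parametric rule because it uses
the stated $\alpha$ semantics directly and, under the package's
negative-binomial null, it is well calibrated (the acceptance suite
measures a mean called fraction of $\approx$ 0.0255 at $\alpha = 0.025$
over 200 simulated pairs of 2,000 genes). The quantile rule by
construction calls a fixed fraction $\approx \alpha$ and is the fallback
when the parametric rule degenerates (zero variance). The pseudocount
defaults to 0.5; it only matters for genes with near-zero rates, where
it shrinks the log ratio toward 0 rather than $\pm\infty$.

## Filtering and the hub boundary

`varianceFilter()` keeps genes whose cross-class variance of normalized
counts strictly exceeds 0.005 and *always* keeps class-exclusive genes
(upregulated in one class only), which receive normalized count 0 in the
absent class. Numerical choices:

- Variance over two values uses the unbiased ($n-1$) estimator, so it
  equals $(x_H - x_L)^2 / 2$. The estimator is not dictated by the
  method description; we chose the unbiased form and expose the
  threshold, so the choice is transparent and adjustable.
- The quantity filtered defaults to `norm_count`. The method can also be
  read as filtering connection-weighted values, so
  `on = "norm_connections"` is available; the two modes select different
  sets and neither is claimed canonical.

`hubBoundarySearch()` looks for the inclusive boundary $(c^*, f^*)$ in
(normalized connections, normalized count) space that maximizes the
number of H-class genes with $\mathrm{NormConnections} \ge c^*$ and
$\mathrm{NormCount} \ge f^*$ subject to **zero** L-class genes
qualifying — the exclusive-hub region of the aggressive class.
Candidates are the observed H values, which is exhaustive: any optimal
boundary can be tightened to observed values without changing the
qualifying set (the test suite verifies equality with a brute-force
grid over all observed pairs). Ties are broken toward larger $c^*$, then
larger $f^*$, and reported thresholds are tightened to the minima over
the qualifying genes, making the result unique and deterministic.
Thresholds are inclusive ($\ge$); with observed-value candidates an
exclusive convention would only shift thresholds to neighboring observed
values. When no exclusive region exists the boundary is returned empty
with objective 0 rather than as an error.

`classScore()` totals normalized connections over a gene list per class
(absent gene = 0) and reports the H-relative difference
$(H - L)/H \times 100$.

## Group statistics

`kruskalByPathway()` and `pairwiseWilcoxon()` compare connection counts
of upregulated genes across cancer types within each pathway, via
`stats::kruskal.test` (tie-corrected H, $\chi^2$ approximation with
$k-1$ df) and `stats::wilcox.test` (exact for small untied samples,
normal approximation with continuity correction otherwise — R's own
switch). The Bonferroni multiplier is the number of pairs actually
tested within the pathway, and adjusted p-values are capped at 1.

By default one observation is contributed per upregulated-gene
*occurrence* (a gene upregulated in 30 samples of a type contributes 30
observations), matching distributions of per-sample connection
frequencies; `perOccurrence = FALSE` collapses to one observation per
distinct gene, since the original description does not say whether
recurrences were pooled. Genes in several pathways contribute to each.

## Ordination and clustering

`runPCA()` is `stats::prcomp` — SVD of the column-centered (not scaled)
cancer-type × gene normalized-connection matrix. Centering on / scaling
off is the default of that function, which the method names without
flags; both are exposed. Because singular vectors are sign-ambiguous,
each component is flipped so its largest-magnitude loading is positive,
making loadings and coordinates reproducible across platforms. A
constant matrix is flagged (zero variance) rather than an error.

Gene contributions use the squared-loading convention of standard PCA
visualization practice: $\mathrm{contrib}(g,k) = 100\,
\ell_{gk}^2 / \sum_g \ell_{gk}^2$ (sums to 100 per component). The share
of *total* variance weights contributions by the component variance
proportions over the retained components (default 3), and the *captured*
share rescales by their cumulative proportion. This convention is chosen
because it reproduces the worked rule that a gene carrying 50 % of a
component holding 70 % of the variance carries 35 % of the total.

`hierarchicalCluster()` defaults to manhattan distance on the feature
matrix rows with complete linkage. The linkage is not dictated by the
method description; complete linkage is the conservative default for
compact classes and is configurable. Clustering on retained PC
coordinates (`on = "pcs"`) is exposed as an alternative input, mirroring
the use of leading components as a denoised representation. The reported
purity is the size-weighted majority-class fraction of the two top-level
branches; 1.0 means the two-branch cut is exactly the H/L split.

One ambiguity is resolved explicitly: normalized counts for the PCA rows
use *per-cancer-type* denominators (each row is a cancer type), while
the variance filter that selects the columns works on *per-class*
denominators. Per-type rows are the geometry being ordinated; the
class-level filter defines the gene set.

## Classification

`trainRFC()` wraps `randomForest::randomForest` with mtry = 8 candidate
features per split and ntree = 50 trees, Gini-impurity splitting, and
OOB evaluation only — each sample is predicted by the roughly one third
of trees whose bootstrap omitted it, so no held-out split is made.
Features are the full-interactome connection numbers where a gene is
upregulated in the sample and 0 otherwise; class-normalized feature
values are deliberately not the default, since the classifier consumes
*individual samples*, not class summaries. The forest is stochastic, so
an explicit seed is required and recorded in the result; with 50 trees
the probability that a sample is never OOB is $(2/3)^{50} \approx
2\times10^{-9}$, which we ignore. Class imbalance (125 vs 135 in the
default design) is left untouched. Importance ranking is by mean
decrease in Gini, ties broken lexicographically for determinism.

## Network mapping

`extractSubnetwork()` induces the subgraph of the interactome on the
selected genes; the major component is the largest, with an explicit
deterministic tie rule (lexicographically smallest sorted member set).
`excludeLowConnectivity()` removes genes below a full-interactome degree
threshold before network interpretation; the default of 10 is a
heuristic reconstruction — the analysis this mirrors discarded genes of
degree 3 and 7 while keeping one of degree 21, and any value in (7, 21]
reproduces that behavior.

`bridgePaths()` searches the *full* interactome for routes from a gene
outside the major component to the component, through intermediary
proteins. Listed genes that are themselves outside the major component
are excluded from the search interior, so intermediaries are always
novel proteins. The default policy returns all shortest connecting
paths; `policy = "all"` enumerates every simple path within the
intermediary bound (default 6), since more than one route can be
biologically meaningful and the selection rule among paths is not fixed
by the method description. Edge direction is ignored throughout
(physical interactions are treated as undirected).

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised and tested:

- **Interactome**: preferential attachment (2 edges per new gene, 1,500
  genes by default), giving the connected, heavy-tailed degree structure
  of signaling networks. The attachment loop is implemented directly so
  that the saturated case (fewer existing genes than edges requested)
  and seeded edge-set determinism are exactly specified.
- **Pathways**: 8 named pathways of 60 genes sharing a common core so
  every pair overlaps by the requested fraction (default 0.2),
  emulating cross-linked pathway membership.
- **Cohort**: six pseudo-tissues with the sample counts 27/48/50 (H:
  STAD, LUSC, LIHC) and 31/56/48 (L: KIRP, THCA, PRAD) — 125 H and 135 L
  samples. Per gene and sample, upregulation is an independent Bernoulli
  draw at a class-specific frequency: baseline U(0.02, 0.35) shared by
  both classes; genes at or above the 90th degree percentile planted as
  H-enriched hubs (H frequency U(0.6, 0.95) vs L U(0.05, 0.3), ranges
  disjoint so enrichment is strict); 6 % of non-hub genes H-exclusive
  and 2.5 % L-exclusive (frequency exactly 0 in the other class),
  mirroring the observed proportions of class-exclusive genes (148 and
  59 of 783).
- **Paired counts**: negative binomial with dispersion 0.1, per-gene
  mean log-normal (meanlog = log 300 per kb) scaled by a CDS length
  drawn from U(500, 5000) bp, and a planted fraction of genes with tumor
  mean multiplied by the fold change (default 4).

These are stand-in distributions: real cohorts have correlated genes,
per-patient effects, library-size artifacts and annotation noise, none
of which the generator emulates. Passing tests therefore demonstrate
that the *implementation* recovers planted structure under its stated
model — frequencies converge to the design, planted hubs surface in the
exclusive-boundary and Gini rankings, PCA/clustering separate the
planted classes — not that the method would perform identically on real
tumor data.

## Problem sizes and determinism

The shipped tests run the statistical suites at deliberate scales: null
calibration over 200 simulated pairs of 2,000 genes; boundary-search
brute-force equivalence on 150-gene tables; class-separation checks over
40 cohort replicates of 260 samples on an 800-gene interactome;
label-permutation baselines over 20 forests; bridging-path brute force
on 40–50-node graphs. All randomness flows through explicit seeds
(`withr::with_seed`), so every generator, forest and pipeline run is
exactly reproducible, and `runPipeline()` writes a manifest with every
parameter, derived stage seed and output digest.

## Known limitations

- Upregulation calling is per-pair and marginal: no shared dispersion
  estimation across samples, no multi-factor design — by design, since
  each tumor is thresholded against its own control.
- The variance filter compares exactly two class values; with only two
  groups the "variance" is a scaled squared difference, and the 0.005
  threshold is meaningful on the normalized-count scale only.
- PCA on six rows yields at most five informative components;
  proportions beyond the leading components are fragile to single rows.
- The exclusive-boundary objective returns one region; when several
  disjoint regions tie, the deterministic tie rule picks one and the
  alternatives are not reported.
- Interactome degree is treated as fixed truth; degree measurement bias
  in interaction databases propagates directly into every score.
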