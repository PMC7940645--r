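---
title: "Persistent homology of metabolic connectivity networks: methods and design"
author: "phnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent homology of metabolic connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phnet)
```

## The problem

Regional glucose uptake measured with FDG-PET fluctuates together across
subjects in regions that work together; the between-subject covariance of
regional uptake ("metabolic connectivity") is therefore used as a proxy for
functional association between brain regions. In neurodegenerative disease,
the question is not only *which* regional pairs decouple, but how the
network as a whole falls apart. `phnet` answers this with zero-dimensional
persistent homology: instead of fixing one arbitrary connectivity
threshold, it sweeps all thresholds and tracks how connected components of
the network merge.

The package operates on subject-by-ROI tables of regional metabolic values,
one table per diagnostic group, restricted to neurotransmitter *pathway
networks* — subsets of regions belonging to one projection system. Seven
default pathways ship with the package: two dopaminergic (striatocortical,
mesolimbic) and five cholinergic (Ch1–3, Ch4 medial, Ch4 lateral
perisylvian, Ch4 lateral capsular, Ch5–6).

## The model

For one group and one pathway with $p$ ROIs, Pearson's correlation $r_{ij}$
is computed across subjects for every ROI pair, and converted to a
dissimilarity

$$d_{ij} = 1 - |r_{ij}|,$$

so that strong coupling of either sign counts as proximity. The *graph
filtration* at level $\lambda \in [0, 1]$ contains every edge with
$d_{ij} \le \lambda$ (closed threshold, so the component count
$\beta_0(\lambda)$ is right-continuous). As $\lambda$ grows from 0 to 1 the
network evolves from $p$ isolated regions to one connected component.

All level-0 persistence objects derive from a single Kruskal sweep over the
sorted dissimilarities:

* **Minimum spanning tree (MST).** Its $p-1$ edge weights are exactly the
  thresholds at which components merge.
* **Betti-0 curve.** $\beta_0(\lambda)$ is piecewise constant; its
  breakpoints are the distinct MST weights and the count drops by the
  number of MST edges at each value. Breakpoints are computed exactly from
  the MST, never from a sampled $\lambda$ grid (grids are for plotting
  only).
* **Barcode.** One bar per ROI component, all born at 0; the $p-1$ finite
  deaths equal the MST weights as a multiset, and the last surviving
  component's death is recorded at the filtration ceiling.
* **Single-linkage ultrametric (SLD).** The minimax path distance — the
  smallest $\lambda$ at which two ROIs join one component; its dendrogram
  visualises the merge hierarchy.
* **SIP AUC.** The area under $\beta_0$ over $[0, 1]$:
  $$\mathrm{AUC} = \int_0^1 \beta_0(\lambda)\,d\lambda
    = 1 + \sum_{e \in \mathrm{MST}} w_e,$$
  a connected-component aggregation cost. Larger values mean slower, less
  efficient network integration. The identity on the right is verified at
  object construction (tolerance $10^{-9}$) and in the test suite on
  random inputs.

Alongside the topological summaries, three conventional weighted graph
indices are computed on an edge-filtered network: characteristic path
length (CPL, mean weighted shortest-path length over connected pairs),
network diameter (ND, the maximum finite shortest-path length) and
eigenvector centrality (EC, principal-eigenvector importance).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `mode` (distance) | `"absolute"` | $d = 1-\lvert r\rvert$; `"signed"` uses $(1-r)/2$ |
| `ceiling` (filtration) | 1 | upper integration limit of the Betti-0 curve |
| `threshold` (edge filter) | 0.5 | retain pairs with $d_{ij} \le$ threshold |
| `rule` (edge filter) | `"threshold"` | or `"density"`: strongest $k$ fraction |
| `nPermutations` | 10,000 | label permutations per group comparison |
| `alpha` | 0.001 | fixed significance flag threshold |

Design choices behind them, made where the underlying convention was
genuinely open:

* **Anticorrelation.** The absolute-value transform means strong negative
  coupling counts as proximity. A signed sensitivity mode is provided, but
  it maps $r$ through $(1-r)/2$ rather than $1-r$: this keeps distances in
  $[0,1]$, so the unit filtration ceiling and the AUC identity remain
  valid and signed and absolute analyses stay comparable.
* **Filtration ceiling.** Distances are bounded by 1 by construction, and
  integrating to a fixed 1 (rather than the largest observed merge value)
  makes SIP AUC comparable across networks of equal size; the alternative
  is available via `ceiling = "max"`.
* **Non-metricity.** $1-|r|$ need not satisfy the triangle inequality.
  Nothing downstream assumes it does: the MST, $\beta_0$, SLD and shortest
  paths are all well defined for general dissimilarities.
* **Ties.** Kruskal edges are ordered by (weight, smaller ROI index,
  larger ROI index). Under exact ties the MST edge *set* can be
  non-unique, but every exposed quantity — total weight, $\beta_0$,
  barcode, SLD — is tie-invariant.
* **Edge filtering for graph metrics.** A fixed distance threshold
  (default 0.5) with a density-based alternative; the rule applied is
  recorded in the output. Path lengths use $d$ as edge length; EC uses the
  similarity $1-d$ as edge weight, since centrality presumes larger =
  stronger.
* **Disconnected pairs.** Excluded from CPL/ND and counted, rather than
  imputed with a ceiling value: imputation creates threshold-dependent
  discontinuities, and the count is itself diagnostic. With no connected
  pair the metric is reported as undefined (`NA`), never 0.
* **EC scalarisation.** For group testing the EC vector is reduced to its
  mean over scored nodes (`ecMean`); on disconnected graphs only the
  largest component is scored (with a warning).

## Permutation inference

Group differences in any registered network statistic (SIP AUC, CPL, ND,
mean EC) are tested by subject-label permutation: subjects of the two
groups are pooled, labels are reshuffled preserving group sizes, and the
statistic is recomputed *from the correlation matrix onward* for every
permutation — the only null construction consistent with group-level
network statistics. The two-sided add-one p-value
$p = (1 + \#\{|\Delta^\ast| \ge |\Delta|\})/(1 + B)$ can never be 0, and
the whole table is bit-reproducible given a seed. Following the fixed
significance convention of the analysis this package implements, the
comparison table flags $p < 0.001$ without further multiplicity
adjustment; Bonferroni and Benjamini–Hochberg columns are available as
clearly marked extensions (`adjust = TRUE`).

Because the test conditions on the pooled sample it is exact under
exchangeability even though the MST-based statistics are biased by group
size (see below); calibration is verified in the acceptance suite by
simulation (type-I error at $\alpha = 0.05$, 200 replicate null cohorts,
1000 permutations each).

## The synthetic cohort generator

No patient-level data are distributed with the analysis this package
implements, so validation rests on a synthetic generator that emulates its
study design: four diagnostic groups — early Alzheimer's disease (AD,
$n=16$), mild cognitive impairment (MCI, $n=18$), subjective cognitive
decline (SCD, $n=16$) and healthy controls (HC, $n=23$).

Each group draws subjects from a multivariate normal with a
block-exchangeable correlation matrix: ROIs are partitioned into pathway
blocks (the default layout is the union of the seven shipped pathways,
each ROI assigned to the first pathway listing it); the latent correlation
is `within[g]` inside a block and `between` (default 0.10) across blocks.
Independent Gaussian measurement noise with sd `noiseSd` (default 0.5) is
added, which attenuates observable correlations by $1/(1+\sigma^2)$; all
ROI means are equal across groups (baseline 1, mimicking
cerebellum-normalised SUVR), so group differences are carried *only* by
connectivity strength. The defaults order the groups
MCI (0.35) < AD (0.45) < SCD (0.60) < HC (0.70) in within-pathway
strength, encoding the interpretation that disease progressively
attenuates metabolic coupling. Multivariate normality is the minimal
choice — the Pearson-correlation pipeline only sees second moments — and
positive semi-definiteness of every implied covariance is verified by an
eigenvalue check at construction. One master seed drives deterministic
per-group streams, so adding a group never perturbs the others.

What the generator does *not* emulate: PET image formation, partial-volume
effects, spatial smoothing (which induces distance-dependent correlation),
site or scanner effects, mean hypometabolism (group mean differences), or
heavier-than-Gaussian tails. Passing tests therefore demonstrate
correctness of the pipeline's mathematics and calibration of its
inference, not robustness to those real-data features.

## Known limitations, and an honest negative result

The SIP AUC equals $1 +$ the MST total — a sum of *minimum* order
statistics of the estimated dissimilarities. At cohort sizes of 16–23
subjects the sampling noise of a single Pearson coefficient is large
(sd $\approx 0.2$), with two consequences the package's own simulations
quantify:

1. **Group-size bias.** Smaller groups overshoot more at the selected
   extremes, so their MST totals are biased downward; two groups with
   identical population connectivity but different $n$ have systematically
   different expected SIP AUC. The permutation test remains exact despite
   this (both the observed and permuted statistics carry the same bias
   structure), but *descriptive* cross-group AUC comparisons at unequal
   $n$ should be read with care.
2. **Low separability at realistic effect sizes.** With the default
   generator strengths (0.35/0.45/0.60/0.70) and the study's group sizes,
   the expected SIP AUC reproduces the MCI > AD > SCD > HC ordering, but
   cohort-to-cohort noise is of the same magnitude as the adjacent-group
   gaps: the *per-cohort* joint ordering holds in only roughly 60% of
   simulated cohorts (the acceptance suite computes the exact fraction),
   and permutation power for adjacent contrasts is correspondingly
   modest. Reliable per-cohort recovery of the full four-group ordering
   would need substantially larger cohorts or stronger connectivity
   separation.

Other limitations: only zero-dimensional homology is computed (no loops or
voids); no partial correlation or Fisher transformation; the default
pathway parcellation is deliberately coarse and editable (the mapping of
projection systems onto named parcels — especially the "remaining"
association cortices of the Ch4 lateral capsular division — is a
granularity choice, supplied as an overridable YAML config, not an
anatomical ground truth).

## Numerical and reproducibility notes

* Breakpoints, barcodes and SLD entries are exact functions of the sorted
  input dissimilarities; no grid sampling or iterative solver is involved.
  EC uses a dense symmetric eigendecomposition and is checked against the
  eigen-equation at $10^{-8}$.
* Subject tables are written at full double precision (`%.17g`), so
  write-then-read round-trips are bit-identical.
* Every run-level command writes a checksum manifest; re-running
  `simulate → analyze → compare` from one saved config reproduces every
  output byte (the wall-time-stamped log is excluded from the manifest).
* Problem sizes used by the validation suite: 1000 random matrices
  ($4 \le p \le 20$) for the SIP/MST identity; exhaustive oracles at
  $p \le 8$ (minimax paths) and $p \le 12$ (shortest paths); 200 replicate
  null cohorts × 1000 permutations for calibration; 100 simulated
  four-group cohorts for ordering recovery.

## A minimal example

```{r example}
spec <- syntheticSpec(c("patients", "controls"), c(16, 23),
                      layout = c(pathway = 8),
                      within = c(0.45, 0.70), between = 0.1,
                      noiseSd = 0.5, seed = 7)
cohort <- generateCohort(spec)
d <- toDistance(pearsonMatrix(cohort$patients))
ph <- persistentHomology(d)
ph
sipAUC(ph)
res <- permutationTest(cohort$patients, cohort$controls, "sipAUC",
                       nPermutations = 200, seed = 1)
res
```
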