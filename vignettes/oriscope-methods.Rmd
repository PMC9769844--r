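---
title: "Models and methods behind oriscope"
author: "oriscope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oriscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscope)
library(SummarizedExperiment)
```

# Scope

`oriscope` analyses experimental-evolution data from bacteria whose
chromosomes carry one or several replication origins: replication
activity from sequencing coverage, growth rate and relative fitness
from OD600 curves, populational mutation summaries, and transcriptome
divergence quantified as centroid distances in classical MDS space and
regressed on relative fitness.  Every stage has a matching synthetic
generator, so the whole pipeline can be validated against analytic
ground truths without sequencing data.  This vignette explains the
models, the tunable parameters, and the numerical choices; it states no
result that the package's tests and acceptance script do not themselves
compute.

# The steady-state replication model

In an exponentially growing culture, loci replicated early are present
in more cells than loci replicated late.  With synchronous origin
firing and forks annihilating where they meet, the replication time of
position $x$ on a circular chromosome of length $L$ is

$$t(x) \;=\; \min_j \, d(o_j, x) / v,$$

where $d$ is the shorter circular arc to origin $o_j$ and $v$ the fork
speed (bp/min).  Steady-state theory for age-structured exponential
cultures then gives the expected relative copy number

$$c(x) \;=\; m(x)\, 2^{\,(t_{\max} - t(x))/\tau},$$

with $\tau$ the doubling time, $t_{\max}$ the replication time of the
last-replicated locus (the C period for a single origin), and $m(x)$ an
optional segmental-duplication multiplier.  The ori/ter copy-number
ratio is therefore $2^{C/\tau}$: the quantity every replication index
below estimates.  Only ratios are meaningful; the package anchors the
latest-replicated locus at 1.

`ChromosomeSpec()` holds this geometry.  Its defaults — fork speed
30 kb/min (500 nt/s) and doubling time 67 min — are illustrative values
in the range reported for *E. coli* K-12 on glucose minimal medium; no
strain-specific calibration is implied, and both parameters are always
explicit arguments in analyses.  Assumptions deliberately excluded from
the model: asynchronous or stochastic origin firing, replication -
transcription conflict kinetics, and cell-cycle age structure beyond
the $2^{(C-t)/\tau}$ formula.

The coverage simulator (`simulateCoverage()`) places `nReads` reads
multinomially with window probabilities proportional to $c$ at the
window midpoint times the window width.  Because windows (1 kb by
default) are three orders of magnitude smaller than the chromosome, the
midpoint approximation to the within-window integral is negligible.
The multinomial (``poisson``) mode conserves the total read count
exactly; the negative-binomial mode adds gamma-Poisson overdispersion
per window and does not.  Counts become mean per-base coverage via a
nominal read length (100 bp, matching short-read data).

# Replication indices

`normalizeCoverage()` divides each window by the total coverage, the
usual between-sample normalization for copy-number landscapes.  "Total
coverage" is implemented as the sum of per-window means: any constant
denominator only rescales the profile, and this choice gives the
testable invariant that normalized profiles sum to one.

`loessSmooth()` is a locally weighted polynomial regression with
tricube weights — local degree 2, non-robust fitting, neighbourhood of
$\lceil \mathrm{span} \cdot n \rceil$ windows — the default behaviour
of the LOESS smoother in standard statistical environments, with
span 0.3 as the conventional setting for single-origin profiles.  It is
implemented directly (and verified in the tests against a pointwise
weighted-least-squares oracle at $10^{-10}$) rather than through a
library smoother, because duplication masking requires prediction on an
irregular training grid and circular chromosomes require wrap-around
padding, neither of which library smoothers expose cleanly.

Two numerical facts about LOESS on these landscapes matter for
interpretation:

* **Cusp flattening.** The copy-number landscape has cusps at origins
  and fork-meeting points.  A local quadratic with tricube weights
  underestimates a cusp peak by a factor that grows with the span times
  the log-slope; at span 0.3 and $C/\tau = 1$ this is a few percent.
  At a one-sided boundary of a monotone profile the local fit is nearly
  exact, so placing the terminus at the coordinate edges (origin
  centred) gives the cleanest single-origin ratio.
* **Resolution rule.** The smoothing half-width is
  $\mathrm{span}\cdot L/2$.  For multi-origin chromosomes it should
  stay below half the smallest arc between adjacent extrema, otherwise
  neighbouring peaks and troughs are averaged together.  For three
  origins at 365 kb, 1,240 kb and 3,925 kb on a 4.6-Mb chromosome the
  smallest arc is 875 kb, so spans at or below about 0.19 resolve all
  six extrema; the package's multi-origin analyses use span 0.15 with
  `circular = TRUE` (the native origin sits near the coordinate
  boundary).

The indices:

* `ptrLoess()` — LOESS maximum over LOESS minimum; the ori/ter ratio
  of a single-origin chromosome.
* `multiOriIndex()` — sum of the LOESS values at the $k$ peak loci
  divided by the LOESS value at the termination site (global LOESS
  minimum unless supplied).  For a single-origin comparator strain the
  homologous insertion loci can be passed as pseudo-peaks, keeping the
  statistic comparable across strains.  LOESS values (not raw windows)
  are used at the peak loci, consistent with the single-origin
  procedure.  On a flat profile the index equals $k$, not 1.
* `irepLike()` — slope of the sorted, trimmed log2 profile against
  rank fraction, returned as $2^{\text{slope}}$; a deliberately
  simplified re-implementation of the iRep estimator (none of the
  original pipeline's filtering heuristics are reproduced).
* `bptr()` — ratio of median raw copy number around the
  median-filtered maximum versus minimum; a simplified peak-to-trough
  estimator.

All three estimate $2^{C/\tau}$ on single-origin chromosomes and are
validated together on a $C/\tau$ grid; their concordance (pairwise
Pearson correlation across growth conditions) is recomputed by the
acceptance script.

`detectDuplication()` forms the ratio of each window to the LOESS
baseline, masks windows above the 95th percentile of that ratio, refits
once so a real duplication cannot inflate its own baseline, and calls
maximal runs whose 21-window rolling median stays at or above the
ratio threshold (default 1.7) for at least 50 kb.  The single refit is
the minimal bias correction; thresholds are free parameters exposed in
the interface.  A centred rolling median crosses the threshold within
about one window of a true step edge, which is why planted-boundary
recovery at 1-kb windows is accurate to a few kb.

# Growth and fitness

`growthRate()` slides a window of 5 consecutive points over the log OD
curve, excludes readings at or below the OD floor (0.01, the blank
region of a plate reader), and returns the steepest slope among windows
whose $R^2 \ge 0.99$, in h$^{-1}$.  This is a transparent stand-in for
dedicated growth-rate tools built on the same sliding log-linear
principle; window size, $R^2$ gate and floor are exposed because
published analyses rarely state them.  When no window passes the gate
the best-$R^2$ slope is returned with a warning flag rather than an
error, so batch processing degrades gracefully.

`relativeFitness()` divides by the wild-type ancestor rate measured in
the same batch.  `generations()` is $\log_2$ of the density ratio per
culture cycle, summed over serial transfers by
`cumulativeGenerations()`.

`monotoneFitnessTrajectory()` enforces the biological expectation that
relative fitness does not decrease over a short adaptive evolution:
values are first projected onto the nearest non-decreasing sequence by
pool-adjacent-violators (`stats::isoreg`), then interpolated with a
shape-preserving monotone cubic Hermite spline
(`stats::splinefun(method = "monoH.FC")`).  The contractual properties
are exact interpolation of the projected knots and monotonicity on any
evaluation grid; the Fritsch-Carlson cubic was chosen over a quadratic
spline because it guarantees both for non-decreasing knots, including
ties produced by the projection.

# Transcriptome dissimilarity

`medianRatioSizeFactors()` is the median-of-ratios estimator (geometric
mean reference over genes positive in all samples); it is cross-checked
in the tests against an independent reference implementation.
`rlogLike()` is `log2(count / sizefactor + 1)`: a deliberately simple
variance-damping transform whose only contract is to feed Euclidean
distances into MDS.  It is *not* a shrinkage rlog; with few replicates
and low counts the two transforms differ most for weakly expressed
genes, which is one reason printed DEG counts from shrinkage-based
pipelines are out of scope here.

`deTest()` is a lightweight negative-binomial Wald test: median-of-
ratios normalization, group means with pseudocount 0.5, pooled
method-of-moments dispersion floored at 0.01, delta-method standard
error of the log2 fold change, two-sided normal p-values and
Benjamini-Hochberg q-values.  A gene is a DEG when $q < 0.05$ and the
normalized-mean fold change exceeds 1.5 in either direction — the
conventional thresholds for this kind of data.  Genes with zero counts
in every sample of both groups are excluded before testing and reported
with `tested = FALSE`.  The test's null false-positive rate and its
power on planted four-fold changes are recomputed by the acceptance
script; it is a screening test, not a replacement for a full
shrinkage-based DE framework.

`classicalMds()` is Torgerson scaling: double-centre the squared
Euclidean distance matrix, eigendecompose, scale eigenvectors by the
square roots of the positive eigenvalues.  For distances generated by
points in at most $m$ dimensions the embedding is exact, which gives
the $10^{-8}$ distance-recovery oracle used in the tests.  Eigenvector
sign and order among tied eigenvalues are arbitrary, so tests and
downstream statistics compare only distances, never raw coordinates.
When fewer than $m$ positive eigenvalues exist the embedding is
truncated and flagged rather than padded.

`centroidDissimilarity()` averages each population's replicate
coordinates in the 3-D embedding and measures the Euclidean distance to
the centroid of that population's own lineage ancestor (a wild-type
population is compared with the wild-type ancestor, a multi-origin
population with the multi-origin ancestor).  `fitnessRegression()`
regresses dissimilarity on relative fitness by OLS; dissimilarity is
the response because fitness is the experimentally controlled axis,
and $R^2$ is orientation-invariant for simple regression anyway.
Ancestors sit at dissimilarity 0 by construction; whether they enter
the regression is a flag (`includeAncestors`, default `FALSE`), because
with two lineages the two ancestors occupy different fitness values and
would both be pinned at zero.

# The count-matrix generator

`simulateCounts()` plants a single direction of transcriptome change
whose length scales with fitness gain: a fixed random subset $S$
(fraction $f$) of genes receives effects $\delta_g \sim N(0,1)$, and
sample $j$ of population $p$ has negative-binomial mean

$$\mu_{gj} = s_j \, q_g \, 2^{\,\kappa (W_p - 1) \delta_g \,\mathbf{1}[g \in S]},$$

with baselines $q_g$ log-normal, library factors $s_j$ log-uniform on
$[0.5, 2]$, and dispersion $\alpha$.  Because all populations share the
same $\delta$, their expression centroids lie on a line through the
ancestor with distances proportional to $W_p - 1$ — the simplest
mechanism that makes centroid dissimilarity linear in fitness gain, and
therefore the right null instrument for testing the regression
machinery.

Defaults, chosen once as realistic for bulk RNA-seq of isogenic
bacterial populations: 2,000 genes (desk-scale; a full genome has about
4,600), baseline median 150 counts with log-sd 1.2, dispersion 0.01
(technical-replicate scale), $f = 0.15$ and $\kappa = 1.5$ — at the
largest default fitness gain (0.45) a planted gene shifts by
$0.675\,\delta_g$ log2 units, i.e. typical DEG effect sizes, and the
DEG fraction lands near the ~10-15% seen in evolved-population
transcriptomes.  The default population panel is one lineage with an
ancestor at $W = 1$ and five evolved populations at
$W \in \{1.10, 1.16, 1.25, 1.35, 1.45\}$, two replicates each,
mirroring the size of a six-population evolution experiment.

What the generator deliberately does **not** emulate: gene-gene
correlation structure (operons, regulons), population-specific
directions of adaptation, GC or length biases, and batch effects.
Passing the end-to-end recovery test therefore shows that the
statistical machinery is sound under the stated model, not that real
transcriptomes satisfy the model.

# Variant summaries

`readVariantTable()` ingests tab-separated populational variant tables
(lineage, gene, annotation, mutation, allele frequency, description),
classifies rows as SNP or DIP from the mutation string, and extracts
codon changes from annotations like `R69H (CGC→CAC)`.
`classifyEffect()` translates both codons with the standard genetic
code; a change is nonsense exactly when the alternative codon is a stop
and the reference is not.  Effect classification uses only the printed
codon pair — re-deriving codons from genome coordinates is out of
scope.  `filterByAF()` makes the threshold comparison explicit
(`>=` by default, `>` on request) because published filters mix "over
10%" with "at least 50%" phrasing; "fixed" means an allele frequency of
exactly 100 as printed, with no clonality modelling.  A transcription
of a published six-lineage mutation table ships in
`inst/extdata/table1_variants.tsv` as a worked example and test
fixture.

# Problem sizes and determinism

The validation suite runs at desk scale, chosen so the full pipeline is
exercised in minutes: 4.6-Mb chromosomes at 1-kb windows with $10^6$
reads for profile recovery ($10^8$ reads only for the law-of-large-
numbers check on a 0.5-Mb chromosome), 20 replicate simulations for the
end-to-end regression, 2,000-gene matrices for DE calibration.  Every
stochastic generator takes an explicit seed and restores the caller's
RNG state, so identical seeds give bit-identical tracks, curves and
matrices and no call leaks global state.  Known degenerate inputs are
errors, not silent results: all-zero coverage, empty segments,
nonpositive troughs, groups with fewer than two replicates, lineages
without an ancestor.

# Known limitations

* The replication model assumes synchronous firing and constant fork
  speed; real multi-origin strains may fire origins asynchronously,
  which would blunt peaks relative to the model.
* LOESS-based quantities carry the span-dependent cusp bias described
  above; comparisons across samples are safe (the bias is shared), but
  absolute $2^{C/\tau}$ readouts at span 0.3 are a few percent low.
* The DE test has no shrinkage and modest power at low counts; it is
  calibrated, not optimal.
* The rlog approximation and classical MDS make the dissimilarity
  statistic exactly reproducible, but numeric values are not
  interchangeable with those from shrinkage transforms.
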