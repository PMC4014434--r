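---
title: "Haplotype-based eQTL mapping and the estimation of allelic series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based eQTL mapping and the estimation of allelic series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapqtl)
```

## The mapping design

hapqtl implements expression-QTL mapping for a two-panel multiparental
recombinant inbred line (RIL) resource.  Each panel descends from eight
inbred founders (A1-A7 or B1-B7 plus one founder, AB8, shared by both
panels); after roughly fifty generations of free recombination and
subsequent inbreeding, every RIL genome is a fine-grained mosaic of founder
haplotypes.  Phenotypes are measured on F1 trans-heterozygotes from pA
females crossed to pB males, so each cross carries one pA and one pB
haplotype at every locus and inbreeding depression never enters the
phenotype.  What the mapper observes is not the mosaic itself but a
per-position probability vector over the eight founders of each panel, the
output of a haplotype-inference HMM in the real resource.

The genome scan regresses each transcript's abundance on those
probabilities.  At a scan position the model is

$$y_i \;=\; \mu + \sum_{j=1}^{8} G^{A}_{ij}\,\beta^{A}_{j}
              + \sum_{j=1}^{8} G^{B}_{ij}\,\beta^{B}_{j} + e_i ,$$

where $G^{A}_{ij}$ is the probability that cross $i$ inherited founder $j$
maternally.  Because each panel's probabilities sum to one, the design has
two linear dependencies with the intercept; fits use a rank-revealing QR /
pseudo-inverse, the overall genotype F test has $\mathrm{rank}-1 = 14$
numerator degrees of freedom, and evidence is expressed as
$\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$.  Founder
effects are identified only up to a per-panel constant; every reported
statistic (F, LOD, $R^2$) is invariant to that indeterminacy.

Significance is experiment-wise: cross labels are permuted once per
permutation and applied to the *entire* expression matrix, preserving the
correlation structure among transcripts, and the threshold is the 95th
percentile of the maximum LOD over all transcripts and positions.  A
separate, slightly lower threshold is computed for the cis windows
(positions within 1.5 cM of a transcript's start site); restricting the
permutation maxima to a subset of positions can only lower the cutoff, so
the cis threshold sits at or below the genome-wide one.

## Estimating the number of functional alleles

At a mapped peak the eight-plus-eight founder haplotype means are
estimated from the 16-column regression (minimum-norm solution, centered
within panel), sorted, and every partition of the sorted haplotypes into
$k$ *contiguous* blocks is fitted for $k \in \{2,\dots,8\}$ plus the full
model in which all haplotypes (AB8 counted separately per panel) get their
own effect.  For $m$ retained haplotypes this yields
$\sum_{k=2}^{8}\binom{m-1}{k-1} + 1$ models - 16384 at $m = 16$.
Haplotypes occurring fewer than 5 times at probability $> 0.95$ are
excluded, because their means are too unstable to order.

Within a candidate grouping, founder probabilities are summed *within each
panel*: a block's pA members contribute one dosage column and its pB
members another, each with its own coefficient, matching the printed
grouped model ($\beta_{A,c}$ and $\beta_{B,d}$ are distinct parameters).
A $k$-block model therefore carries $n_a + n_b - 1$ estimable genotype
parameters, not $k - 1$.  We verified the alternative single-effect
parameterization (dosages summed across panels; available via
`estimate_allele_number(effects = "shared")`): it halves the per-refinement
penalty and visibly inflates the estimator's overestimation rate relative
to the expected bias profile below, which is why the per-panel coding is
the default.

The best model is the one with the smallest overall F-test P value
(`min_p`); the lowest-AIC variant is computed from the same sweep.  Ties
break toward fewer alleles, the conservative direction.  All fits share
one Gram matrix per peak, so a full 16384-model sweep costs a fraction of
a second (compiled kernel in `src/`).

## The synthetic resource

No real genotypes or arrays ship with the package; `dspr_synth`-style
generators build everything:

* **Genome** — five chromosome arms, 118.8 Mb / 281 cM, linear cM-bp
  relation within an arm, scan grid every 10-200 kb depending on purpose
  (10 kb is the convention for resolution studies; coarser grids keep unit
  tests fast).
* **Mosaics** — founder states follow a Markov chain with switch
  probability $1 - e^{-\rho\Delta}$ between grid neighbours; the default
  $\rho = 0.25$ breakpoints/cM reflects the ~25-fold map expansion of a
  50-generation intercross.  Block lengths are therefore approximately
  exponential with mean 4 cM.
* **Genotype uncertainty** — the true founder receives probability mass
  `certainty` and the remainder spreads uniformly over the other seven.
  Phenotypes are always generated from the *true* haplotypes; the mapper
  sees only the probabilities.  The default `certainty = 0.98` reflects
  that HMM haplotype assignment in such panels resolves most of the genome
  at posterior $> 0.95$; values at or below 0.95 would interact with the
  retention filter's strict $> 0.95$ rule.
* **Phenotypes** — a QTL assigns each of the 15 founder genomes (AB8
  shared) to one of $k$ alleles; a cross's genetic value is the sum of its
  two allele effects (pure additivity), and environmental noise has
  variance $\sigma_g^2(1-z)/z$, so the locus explains fraction $z$ of the
  phenotypic variance in expectation.  Expression studies add a shared
  batch factor (12-plex groups), a polygenic component from random founder
  effects at background loci, and unit-variance noise.

What this emulates - and what it does not: the mosaic process is
statistically calibrated, not copied from real genomes, so long-range
linkage disequilibrium, segregation distortion, regions of suppressed
recombination (centromeres), and the X chromosome's dosage are absent.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not robustness to every
artifact of a real resource.

## The estimator simulation study

The evaluation study plants QTL of known allele number
$k \in \{2,\dots,8,15\}$ at uniform-random genome positions on fresh draws
of 600 + 600 RILs from pools of 800 per replicate subpopulation, assigns
equal-spaced effects $1..k$ uniformly at random to the founder genomes
(every allele represented; the 15-allele truth shares AB8 across panels),
draws $z$ from a Beta(1.5, 3.5) truncated to $[0.05, 0.95]$ - a stand-in
for the observed distribution of variance explained by cis-eQTL, which is
large-effect with median near 25% - and records both criteria's estimates
from one model sweep per dataset.  The desk-scale default is 200
iterations per $k$ (1600 datasets, about five minutes on one CPU);
`iterations = 1000` reproduces the original scale.

Expected behavior, which the acceptance suite checks quantitatively: the
min-P estimator underestimates in roughly 63% of iterations, is correct in
roughly 26%, and overestimates in roughly 10%; underestimation deepens as
the true allele number grows; AIC is less accurate and inflates small
allelic series (picking more than two alleles for most true-two datasets);
and both the fixed small-effect variant ($z = 0.05$) and normally
distributed effects underestimate more at every true $k$.

## Intervals, hotspots, and the remaining machinery

* **Peak calling** merges local maxima whose 3-LOD-drop intervals overlap,
  keeping the highest, iterated to a fixed point.  The 3-LOD support
  interval extends one grid point beyond the contiguous region within 3
  LOD of the peak and behaves conservatively (coverage near 1 at the
  simulated scale).  The Bayes credible interval normalizes $10^{LOD}$
  over the peak's chromosome and grows outward from the peak by largest
  posterior mass until it holds 95%; at a 10 kb grid its empirical
  coverage sits near 0.98 with roughly half the width of the LOD-drop
  interval (0.10 vs 0.22 cM median at $z = 0.3$, $n = 600$), the expected
  ordering of the two interval types.
* **Population attribution** compares pA-only, pB-only and pA+pB fits by
  AIC with rank-based parameter counts; exact ties keep the full model.
* **Heritability** is REML on $y = \mu + g + e$, $g \sim N(0, \sigma_g^2
  K)$, with the kinship matrix $K$ averaging maternal- and paternal-side
  identity probabilities over a 0.025 cM grid; the likelihood is profiled
  to one dimension over $h^2$ after a single eigendecomposition.  A
  percent-heritability-explained above 100 is flagged, never clipped.
* **Hotspots** count unique genes (never transcripts) with trans peaks in
  half-open 500 kb windows stepped by 1 kb; a window is a hotspot when its
  count strictly exceeds the smallest $d$ with
  $P(\mathrm{Pois}(\lambda) > d) < 0.05/\#\mathrm{windows}$,
  $\lambda = n_{trans}\cdot\mathrm{window}/\mathrm{genome}$; hotspot
  extents are the union of member peaks' confidence bounds.  The
  candidate-gene step builds PC1 of the regulated transcripts as a
  composite variable and ranks interval genes by correlation with it.

## Numerical choices and degenerate inputs

Rank deficiency is handled everywhere by eigenvalue/QR truncation at
machine-epsilon-scaled tolerances; perfect fits floor the residual sum of
squares at zero; uninformative genotypes (uniform probability vectors)
give LOD exactly 0.  Quantile normalization maps ranks (average ties) to
standard normal quantiles.  The PC correction residualizes on the
subpopulation factor plus the first 10 components; the residuals are
exactly orthogonal to the removed components, and the final re-quantile
normalization - restoring per-transcript normality - perturbs that
orthogonality only marginally.  Re-running the whole correction
re-estimates components on corrected data and is consequently *not* a
no-op at small sample sizes; the two constituent operations (rank-INT,
projection on fixed components) are individually idempotent, and that is
what the tests pin down.  The expression floor locates, from replicate
pairs, the contiguous run of low-expression quantile bins whose mean
absolute replicate difference exceeds 1.5 times the median of the upper
half of bins; the generator's default plants 23% of transcripts below the
floor.  Probe-model fits include an intercept and use a two-sided dosage
test; the retention rule's $> 0.95$ is strict.  The cis boundary at
exactly 1.5 cM is inclusive.  Window coordinates are half-open in bp;
GFF3 export is 1-based closed, BED 0-based half-open.

## Known limitations

The enumeration counts 16384 models at $m = 16$; the originally reported
maximum of 11337 models per eQTL is not reproducible from any contiguous
ordered-partition rule and likely reflects data-specific haplotype
retention, so it is documented here rather than asserted anywhere.
Cross-panel orderings of haplotype means are only comparable up to the
per-panel centering constant, so a truth whose allele classes are
unevenly distributed between panels can be non-contiguous in the sorted
order - one genuine source of estimator underestimation that the
simulation deliberately retains.  The centromere/telomere interval
exclusion of the original analysis is an output flag, not a filter,
because the synthetic map has no centromeres.
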