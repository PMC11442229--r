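---
title: "From categorical berries to consensus loci: methods behind cranmetaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From categorical berries to consensus loci: methods behind cranmetaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cranmetaqtl` implements a complete mapping-and-synthesis pipeline for berry
quality and yield traits in four-way outbred cranberry crosses: categorical
shape scores become quantitative "chimera" descriptors, phenotypes become
genomic BLUPs with REML heritabilities, BLUPs are scanned for QTL by
Haley-Knott regression, and QTL are condensed into consensus meta-QTL by
interval-overlap maximal cliques. A synthetic-data generator with fully known
ground truth stands in for field data, so every stage of the pipeline is
verifiable offline. This vignette records the models, the tunable parameters,
and the design decisions taken where the methodology was genuinely open.

## The synthetic study

A four-way outbred cross has a heterozygous seed parent contributing alleles
A/B and a pollen parent contributing C/D, so each progeny carries one of four
classes {AC, AD, BC, BD} at every locus. `simulate_cross()` draws the two
parental gametes independently per linkage group as two-state Markov chains.
The map function is Haldane's,

$$ r = \tfrac12\bigl(1 - e^{-2d/100}\bigr), $$

with `d` in centimorgans. No crossover-interference model is claimed in the
methodology this package follows, so the interference-free Haldane function
was chosen as the standard closed-form default; it is used consistently in
generation and in genotype-probability calculation, so the two sides of every
recovery test agree by construction.

`simulate_traits()` mirrors the across-year phenotype model (below): each
observation is

$$ y = \mu + \text{year} + \textstyle\sum_q \text{QTL contrasts}
   + g + ge + \text{row} + \text{col} + s(\text{row},\text{col}) + \epsilon. $$

A QTL with maternal effect $e_m$ adds $+e_m/2$ to A-carriers and $-e_m/2$ to
B-carriers (likewise paternal C/D, and an interaction term positive for
AC/BD), so the class-mean contrast $(AC+AD)-(BC+BD)$ equals $2 e_m$ exactly
— matching the contrast convention used in the QTL effect reports. The
polygenic term $g$ is $N(0,\sigma^2_a)$, drawn iid by default or with
covariance `polygenic_K` (normally the genomic relationship matrix) when a
GBLUP-consistent generative model is wanted; a realized-relationship model
cannot recover heritability from genetically iid effects, so
parameter-recovery studies should pass `polygenic_K = A`. The spatial surface
is a fixed first-order tilt plus a sinusoidal bump scaled by
`spatial_amplitude`, deliberately exercising both straight-line trends and
variation that row/column blocking cannot absorb. Every realised component is
returned in a truth sidecar that sums *exactly* to the emitted observations
(this identity is tested).

Default study conditions mirror the emulated material: 10 uprights per
genotype-year, three years, 168 progeny (the larger mapping population), and
a composite-map scale of 12 linkage groups × 130 markers when the full map
is requested. The field geometry of the real trials is not published, so the
layout generator uses a compact near-square grid — a free choice recorded
here once.

## Shape chimeras and their descriptors

Scored berry-shape categories (five classes, round through spindle) are
replaced by canonical binary silhouettes. The published scoring card's exact
bitmaps are not available, so the shipped templates are synthetic
approximations from a superellipse/pear profile family; they are generated in
code at a configurable raster (default 256 px², target area 12 000 px) and
normalised so all classes share area (±1 px) and centroid (±0.5 px).
Normalisation does a nearest-neighbour rescale and then removes the residual
area error *exactly* by keeping the `target_area` pixels with the largest
differential-distance-transform values — an erosion/dilation level set that
preserves topology.

The differential distance transform (DDT) of a binary image is the Euclidean
distance transform of the foreground minus that of the inverted image:
positive precisely on foreground, negative on background, growing toward
either region's interior. The per-genotype chimera combines the per-upright
DDTs and keeps pixels where the result is positive. "Combining" is
implemented as pixel-wise **summation**: with a single silhouette (or N
identical ones) the chimera is then exactly idempotent, and with mixed
silhouettes it behaves as a majority-like blend. Ties at the zero crossing go
to background (strict > 0), matching the thresholding-on-positive rule.

Six descriptors are measured on the chimera:

* `UKEC` — eccentricity $\sqrt{1-\lambda_2/\lambda_1}$ of the
  moment-matched ellipse (0 for a circle; degenerate line-like shapes get a
  flagged sentinel of 1);
* `UKLvW` — length:width as $\sqrt{\lambda_1/\lambda_2}$, ≥ 1 by
  construction;
* `UKSO` — solidity, area over the convex hull of the pixel *squares*
  (corners, not centres, so solidity ≤ 1 holds exactly);
* `UKTO` — slope-chain-code tortuosity: the outer contour is resampled into
  `m` equal-length segments (default `m = 64`; the chain-code literature
  leaves this free) and the absolute turning angles, normalised by π, are
  summed. A convex contour scores exactly 2 (one full turn); waviness adds
  on top, and doubling a boundary perturbation provably increases it;
* `UKUX`, `UKUY` — log₁₀ counts of horizontal and vertical unit moves of
  the boundary crack code. "Unsigned Manhattan chain code derivation" admits
  several readings (length, compressed length, per-axis counts); the
  per-axis unit-move count is the most literal reading of the X-axis/Y-axis
  naming and is what ships, with the identity
  $10^{UKUX}+10^{UKUY} = $ total boundary moves as its test anchor.

## Curation and correlation cliques

Categorical traits are numerically encoded through a user-supplied
category→value table (berry-shape classes are deliberately *not* encoded —
they go to the chimera pathway). The published encoding tables for the
emulated material are in unavailable supplementary data, so a neutral ordinal
default ships and every mapping is overridable.

Outlier trimming runs in a fixed order: rot-flagged records first; then an
iterated externally-studentised-residual test on the model
`value ~ population + genotype + year` (via `car::outlierTest`, removing the
single worst observation while its Bonferroni-adjusted two-sided p < 0.05,
refitting until no removal); then a 3-standard-deviation cull. The procedure
is a fixed point — re-running it removes nothing new — and falls back to the
SD rule alone, with a log entry, when the model is rank-deficient.

Pearson correlations are computed within year from genotype-year means and
averaged across years (the "month" replicate level of the emulated data is
not otherwise described; averaging across whatever within-year replicate
levels exist is the implemented reading). Traits are clustered by
**complete-linkage** agglomeration on the distance $1-|\bar r|$, cut at 0.6.
Complete linkage was chosen because it guarantees all within-cluster
$|\bar r| \ge 0.4$ at that cut, matching the "cliques of traits" intent;
the metric and cut height are arguments. Singleton clusters are dropped from
reports.

## Mixed models, REML, heritability

Within a year:
$y = \mu + Z_g g + Z_r r + Z_c c + Z_s s + \epsilon$, with
$g \sim N(0, A\sigma^2_a)$ and all other terms iid. Across years, a fixed
year effect $X_e e$ and a genotype-by-year term $Z_{ge}\,ge$ are added. The
genomic relationship matrix is VanRaden method 1,
$A = WW'/(2\sum_k p_k(1-p_k))$, on biallelic dosages (maternal-A plus
paternal-C doses from the four-way classes); monomorphic markers are dropped
with a warning.

Variance components are estimated by average-information REML with
step-halving and an EM fallback, components floored at zero, convergence at
1e−8 on the restricted log-likelihood, at most 200 iterations;
non-convergence is flagged, never silent. BLUPs (GEBVs) and their standard
errors come from the mixed-model equations at the optimum. Three points were
genuinely open and are fixed here as package policy:

* **Spatial spline.** The 2-D spline term is a tensor-product B-spline basis
  over (row, column) with iid coefficients, default 6 × 6. The original
  spline parameterisation is not restated in the methodology text, so
  equivalence is approximate by design and the basis dimension is an
  argument.
* **AIC.** Model search enumerates all subsets of {row, column, spline}
  (genotype always present), picks the lowest AIC with ties broken toward
  fewer terms, and counts k = fixed effects + estimated variance components
  — the common REML-AIC bookkeeping, recorded explicitly because the source
  methodology is silent on k.
* **GxY gate.** The genotype-by-year variance is tested by likelihood ratio
  against the boundary-correct null mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (a plain $\chi^2_1$ would be
  conservative for a variance tested at zero); the term is kept iff
  p < 0.05. With only one observation per genotype-year cell the GxY and
  residual variances are not separable, so on cell means the gate is skipped
  and GxY is absorbed into the residual — an honest limitation of fitting on
  means rather than raw uprights.

Heritability uses the narrow-sense genomic forms: within-year
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_\epsilon)$ and across $n$ years
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_{ge}/n+\sigma^2_\epsilon/n)$, both
bounded in [0, 1] for any non-negative components (tested on a grid), with a
flagged NA when the denominator is zero.

## Haley-Knott scans

Genotype-class probabilities are computed at markers and pseudomarkers
(default step 1 cM in the package, 2.5 cM in the shipped analysis) by
conditioning each parental gamete independently on its nearest informative
flanking markers under Haldane recombination — no genotyping-error parameter,
as none is specified for the emulated pipeline. At a typed marker the
observed class has probability one. The scan regresses the genotype BLUPs
(substituted for raw phenotypes, as in the emulated workflow) on the expected
maternal, paternal and interaction contrasts and reports
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$.

Significance thresholds come from genome-wide max-LOD permutation
distributions (default 1000 permutations): the 80th percentile for
single-QTL significance and the 95th for the stepwise penalty. Support
intervals take the outermost grid positions within 1.5 LOD of the peak
(leftmost peak on ties, flagged whole-group interval when flat). Effects are
the three contrasts of fitted class means — $(AC+AD)-(BC+BD)$,
$(AC+BC)-(AD+BD)$, $(AC+BD)-(AD+BC)$ — and marker variance explained is
$R^2 = 1-10^{-2\,\mathrm{LOD}/n}$.

The stepwise search is **additive-only** with a single main-effect penalty:
forward addition maximising pLOD = LOD − penalty × (#QTL), backward pruning
until pLOD stops improving, profile-LOD support intervals per retained QTL
and drop-one LODs for per-QTL R². Pairwise-interaction penalties from
two-dimensional permutation scans are deliberately out of scope: they
dominate runtime without changing the meta-QTL surface this package exists
for, and the simplification is documented rather than hidden.

## Meta-QTL synthesis

Within a trait group, every QTL is a node; an edge joins two QTL on the same
linkage group whose closed 1.5-LOD intervals intersect (touching endpoints
count — the inclusive reading of "overlap", configurable in principle and
recorded here). Each **maximal clique** becomes a meta-QTL. The engine
enumerates cliques exactly (via igraph's enumeration; per-group graphs are
interval graphs, so this is cheap) rather than using an unspecified
approximation — exactness costs nothing at these sizes and is testable
against brute-force subset enumeration. For intervals on a line the Helly
property guarantees every pairwise-overlapping clique has a non-empty common
intersection, so the synthesised extents

$$ lo = \max_i lo_i, \qquad hi = \min_i hi_i, \qquad
   \text{position} = (lo+hi)/2 $$

are always well-formed; this invariant is asserted on every randomized
fixture. Report positions are rounded **half away from zero** to 0.1 cM from
full-precision extents — the rounding that reproduces all internally
consistent published worked examples (55.75 → 55.8, 40.35 → 40.4,
30.75 → 30.8); a small number of published rows are not consistent with any
midpoint-of-printed-extents rule and are treated as upstream rounding
artefacts. Summary statistics per meta-QTL are arithmetic means (marker R²,
the three effects) and distinct-value counts (models, traits, methods,
populations, studies).

Stability filtering keeps within-trait meta-QTL present in ≥ 3 of the four
models (three single-year models plus all-years) with mean marker R² ≥ 10%
(boundary kept: ≥). Multi-trait groups declare their member traits (synonym
sets across studies are declared, never inferred) and their AND-combined
filter rules over {mean R², model count, trait count, population count,
study count}.

## Problem sizes, determinism, limitations

Every stochastic function takes an explicit seed and restores the caller's
RNG state; one master seed drives the pipeline driver, and identical
configurations produce byte-identical CSVs (tested). The shipped analysis
and the test suite run on a reduced geometry — 5 linkage groups × 12
markers, 80 cM, 168 progeny, 2.5 cM scan step, 1000 permutations — chosen as
the package's standard demonstration scale; the generator accepts the full
composite-map geometry unchanged. Monte-Carlo checks use 100 scan
simulations, 200 REML replicates and 2000 null scans.

What passing tests do and do not show: the generator produces clean
biallelic four-way classes with no genotyping error, no segregation
distortion, no missing-data structure beyond missing-at-random, and a
spatial field that is smooth by construction. Recovery results on it
validate the *machinery* — they do not certify performance on real field
data, where map error, distorted segregation and non-Gaussian trait noise
all degrade power. Reproducing the emulated populations' published QTL
counts and heritabilities would require their deposited field data and is
explicitly out of scope; the package instead anchors on worked-example
arithmetic (midpoint synthesis), closed-form oracles, and
parameter-recovery at stated conditions.
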