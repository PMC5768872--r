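---
title: "Methods: melanosome morphometrics and colour inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: melanosome morphometrics and colour inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocolr)
```

## The problem

Feather colour mechanism leaves a morphological signature in melanosomes:
black feathers carry rod-like organelles around a micron long, brown ones
shorter and stubbier rods, grey feathers long narrow rods, iridescent
feathers either narrow rods or — in several lineages — flattened platelets,
and penguin brown-black feathers carry unusually large near-spherical
melanosomes. Fossilized nanostructure molds preserve the in-plane long
axis ("length") and short axis ("diameter") of these organelles. Given a
library of extant samples with known colours and a set of fossil sampling
locations, the package asks: which colour class does each fossil sample
most resemble, are any of its nanostructures platelet-shaped (a strong
indicator of iridescence), and how robust are those calls to taphonomy and
sampling?

## Feature vectors

Each sample is summarized by eight predictors: mean length, length CV,
mean diameter, diameter CV, mean aspect ratio, aspect-ratio skew, length
skew and diameter skew. Choices a user should know about:

- CV uses the n−1 standard deviation over the mean; skewness is the
  moment (Fisher–Pearson, "type 1") estimator without small-sample bias
  correction. The estimator name is recorded in the feature table's
  metadata attribute so alternatives can be compared.
- The aspect ratio is computed per measurement (length/diameter) and then
  averaged — not the ratio of means. With right-skewed axis distributions
  the two differ; the per-measurement mean matches how shape is scored on
  individual organelles.
- Samples need at least 5 measurements (configurable); third-moment
  statistics on fewer are noise.
- Rows with length < diameter are axis-swapped with a warning rather than
  rejected: manual SEM measurement mixes the axes up far more often than
  it invents values. Rows flagged near the body cavity are excluded before
  any analysis, since internal-organ melanosomes can contaminate feather
  samples there; every exclusion is itemized.
- CVs, skews and the aspect ratio are exactly invariant under a common
  rescaling of both axes — the property the shrinkage analysis leans on —
  and the test suite asserts it to 1e-12.
- Features may be computed per sample (default) or pooled per taxon via
  the grouping key; extant libraries built from per-species patches use
  the default.

## Morphospace and the overlap statistic

Densities are Gaussian product-kernel KDEs of (length, diameter) evaluated
on a shared grid and divided by their sum, so each surface is a discrete
probability mass function; the proportional overlap of two groups is the
sum over grid nodes of the pointwise minima. Numerical choices:

- **Bandwidth.** One bandwidth per axis from the pooled data of every
  group *including the fossil*, by the Silverman normal-reference rule
  `1.06 · min(sd, IQR/1.34) · n^(−1/5)`, reused verbatim for every group.
  A shared bandwidth is what makes overlaps comparable; the rule and its
  provenance are recorded in the output. The bandwidth matrix is diagonal;
  a full matrix changes overlaps by less than the grid-refinement error in
  our checks, and a diagonal keeps the oracle closed forms usable.
- **Grid.** 151×151 nodes spanning the pooled range padded by 3 bandwidths
  per side; points outside the grid are an error (silent mass loss would
  bias overlaps downward), and the suite checks that doubling the
  resolution moves overlaps by < 0.005.
- The overlap operator is validated against the closed form for two unit
  normals offset by δ: `∩ = 2Φ(−δ/2)`, recovered within 0.01 on a 301×301
  grid.

The centroid-distance dispersion test z-scores each axis by the pooled sd
(so nanometre-scale length does not swamp diameter), computes each point's
Euclidean distance to its own group centroid, and fits a one-way linear
model of distance on group; its type-I error is nominal (0.0495 ± 0.004 at
10⁴ null replicates during development, and the suite re-checks 1000
replicates against the binomial CI). Rarefaction of variance draws
subsamples without replacement at a ladder of sizes and tracks the trace
of the (length, diameter) covariance; at the full sample size the curve
equals the full-sample statistic with zero spread by construction.

## Platelet identification

"Outside the extant morphospace" is operationalized as the highest-density
region: the density threshold is the (1 − level) quantile of the reference
points' own KDE values, so a fresh reference-distributed point is outside
with probability ≈ 1 − level (the suite checks 0.05 ± 0.02 at level 0.95).
A sample is flagged when more than half of its measurements are outside
(the majority rule is configurable; the calibration above refers to
measurements, not samples). Image evidence of stacked or moulded
nanostructures is an input flag — it is assessed on SEM images by eye, and
image analysis is out of scope. Samples where the two criteria agree are
called platelet / non-platelet outright; disagreements go to a
2-component Gaussian mixture on (log length, log diameter), the component
whose centroid has lower reference density is labelled platelet, and only
those measurements are withheld from the colour classifier. If the mixture
fails to converge the per-measurement HDR flags are used, with a warning.
Raising the HDR level can only shrink outside fractions (asserted over a
level sweep).

## Colour classification

Backward stepwise selection uses the partial Wilks' lambda F-test: at each
step the variable whose removal is least damaging (largest partial p) is
dropped if p > α = 0.05, after a pre-pass that removes the weaker member
of any variable pair with |r| > 0.95 so within-class covariances stay
invertible. The QDA uses per-class maximum-likelihood Gaussian estimates
(divisor n, which makes duplicating the training rows a no-op) with a
relative ridge of 1e-8 on each covariance diagonal — proportional rather
than trace-based, so predictions are exactly invariant under per-feature
affine rescaling. Priors are equal by default: fossil class frequencies
are unknowable in principle; training-frequency priors are available by
argument. Six training configurations cover the analysis variants:
platelet taxa pooled (1), hummingbird platelets split out (2),
non-hummingbird platelets merged into rod iridescence (3), non-platelet
fossil samples only (4), penguin brown-black as its own class (5), and
20% shrinkage-corrected fossil features (6). In configurations 1–4 and 6
the penguin class is folded into black, matching how brown-black penguin
feathers are labelled when not singled out.

Validation reports both resubstitution ("self-test") accuracy and
leave-one-out cross-validation. Variable selection is performed once on
the full training set and frozen during LOO; re-selecting per fold would
be slightly more conservative but multiplies runtime by the variable
count, and the frozen-set optimism is visible in the self-test/LOO gap the
suite monitors. Whether the original analyses re-selected per fold is not
determinable; this choice is recorded here as a limitation.

## Shrinkage and spatial autocorrelation

The taphonomic scenario assumes both axes decreased by a fraction d
(default 0.20) and corrects fossil measurements by 1/(1−d); correction is
the exact inverse of simulated shrinkage, dimensionless features are
untouched, and the sensitivity report reruns overlap, platelet calls and
classification per scenario and lists the sample-level conclusions that
change. The Mantel test correlates the strictly-lower triangles of the
z-scored feature distance matrix and the slab-coordinate (or
region-adjacency hop) distance matrix, with a one-sided permutation null
(999 permutations by default) and p = (1 + #{r* ≥ r}) / (1 + B). At very
small matrices (n = 5) sampled permutations regularly reproduce the
identity, so p is bounded well above 1/(B+1); the suite checks agreement
with exhaustive enumeration there instead.

## The synthetic-data generator

Each colour class is a bivariate lognormal over (length, diameter) —
positive, right-skewed, with closed-form mean/CV/skew that serve as
oracles; draws violating length ≥ diameter are rejected and redrawn, and a
class whose rejection rate exceeds 99% is an error. The default library
(seven classes, centred between ~600 and ~1450 nm length) is illustrative
of the nm scales involved, not fitted to real birds, and no test depends
on it matching any species. The fossil slab places 53 locations uniformly
on a 500×300 mm slab — matching the scale of a final data set of 53
fossil sampling locations — with 37 measurements per location (the
sampling density of ~2460 structures over 66 samples), a contiguous
platelet-bearing patch of 16 locations, and a spatially correlated
Gaussian-process size field (squared-exponential kernel, default range
80 mm) added to both log axes. The field is shared between axes: a smooth
size gradient preserves aspect ratio, so no field draw can make a class
geometrically impossible, and positivity is automatic on the log scale.
The field amplitude (sd 0.20 on the log scale, ≈ ±20% size modulation)
was fixed by simulation so that, with the correlation length comparable
to the slab extent, the Mantel test detects the structure with power ≥ 0.9
(500-replicate check in the suite); at the default 80 mm range the
observed Mantel r on a typical slab is ~0.1 — the same order as published
fossil-slab estimates. One integer seed governs every stream, with
per-stage sub-seeds derived deterministically from it.

What the generator does *not* emulate: measurement error and observer
bias in SEM digitization, oblique sectioning of 3D organelles,
non-lognormal outliers, within-sample mixtures outside the designated
platelet patch, and any real taxon's parameters. Passing tests therefore
demonstrate that the *methods* recover known structure under their own
assumptions, not that any particular fossil's colours are correct.

## Problem sizes and determinism

The shipped analyses use a 140-sample library (7 classes × 20 samples ×
30 measurements) and the 53-location slab; densities use 151×151 grids
(301×301 in the overlap-oracle check); Mantel tests use 999 permutations
(199 in replicated power checks); rarefaction uses 500 replicates per
size. These sizes give stable estimates while keeping each analysis script
in the seconds-to-a-minute range. Deterministic stages are byte-reproducible
given the seed; the suite byte-compares full pipeline reruns.
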