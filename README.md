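# paleocolr

Plumage colour inference from fossil melanosome morphometrics.

Melanosome size and shape correlate with the colour mechanism of the
feather they sit in: matte black, brown and grey feathers carry
characteristic rod- to sausage-shaped melanosomes, iridescent feathers
carry narrow rods or — in hummingbirds, swifts, trogons and trumpeters —
flattened platelets, and penguin brown-black feathers carry unusually
large, near-spherical ones. Measured lengths and diameters of fossilized
nanostructures can therefore be compared against a library of extant-bird
melanosomes to reconstruct which colour class a fossil feather most likely
had. `paleocolr` implements that analysis end to end for palaeontologists
working from SEM measurement tables:

- **Measurement handling** — validation (body-cavity exclusions, axis-order
  repair, minimum counts) and the eight per-sample predictors: mean length,
  length CV, mean diameter, diameter CV, mean aspect ratio, aspect-ratio
  skew, length skew, diameter skew.
- **Morphospace** — 2D Gaussian-kernel densities of (length, diameter) on a
  shared grid with one pooled Silverman bandwidth, converted to proportions;
  the *proportional overlap* between groups a and b is
  `∩(a,b) = Σ_grid min(p_a, p_b)` (1 = identical, 0 = disjoint). Plus
  centroid-distance dispersion tests and rarefaction-of-variance curves.
- **Platelet identification** — a sample is platelet-bearing when (i) its
  measurements fall outside the 95% highest-density region of the
  non-platelet extant morphospace and (ii) images show stacked/moulded
  nanostructures; when the criteria disagree a 2-component Gaussian mixture
  on log axes splits the sample's measurements.
- **Colour classification** — backward stepwise variable selection by
  partial Wilks' lambda F-tests (retain at p < 0.05, after a
  multicollinearity pre-pass), quadratic discriminant analysis
  `δ_k(x) = −½log|Σ_k| − ½(x−μ_k)ᵀΣ_k⁻¹(x−μ_k) + log π_k`, six
  training-set configurations (platelet classes pooled/split/merged,
  penguin class split, non-platelet-only, shrinkage-corrected), self-test
  and leave-one-out validation.
- **Sensitivity analyses** — taphonomic shrinkage (20% decrease in both
  axes ⇒ ×1.25 correction) propagated through every stage, and a Mantel
  permutation test of anatomical autocorrelation across the fossil slab.
- **Synthetic data** — bivariate-lognormal class models and a slab
  generator with a spatially correlated size field and designated
  platelet-bearing regions, so every stage is testable against known truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`ANALYSIS_SEED` selects the seed, default 1):

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Stage 3 identifies the platelet-bearing slab locations:

```
       mixed non_platelet     platelet
           2           35           16
sensitivity 1.000, specificity 1.000 against generator truth
```

Stage 4 prints the fossil's proportional overlap with each extant class —
highest with black (0.644) and platelet iridescence (0.302), near zero with
the penguin class (0.015). Stage 5 classifies each slab location and maps
colours onto body regions (head/neck/chest platelet-iridescent, the rest
black); leave-one-out accuracy on the training library is 1.000. Stage 6
reruns everything under 20% shrinkage (0 colour predictions change) and
stage 7 tests anatomical autocorrelation:

```
Mantel r = 0.079, one-sided p = 0.043 (999 permutations, 53 locations)
```

Equivalently, `run_pipeline(pipeline_config(list(seed = 1)))` executes all
stages in one call and writes a provenance-stamped JSON report.

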