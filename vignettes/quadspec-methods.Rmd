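---
title: "quadspec: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadspec: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models
it implements, the assumptions behind them, the numerical conventions
that make the tests exact, and the places where the design was
genuinely open and a choice had to be made. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The problem

Watercore is a physiological disorder of apples in which translucent,
water-soaked tissue accumulates near the core. Its severity is naturally
defined volumetrically — the fraction of fruit volume occupied by
watercore tissue — and graded in four levels: normal fruit (level 1),
below 3 % (level 2), 3–6 % (level 3), above 6 % (level 4). Because
watercore tissue carries more free water, diffuse *transmission* spectra
in the visible/near-infrared range show deeper water absorption around
760 nm and 970 nm, which makes non-destructive optical grading possible.

The package implements both halves of that workflow:

1. a **spectral classifier** — a 1-D CNN whose first layer uses
   quadratic neurons — that maps a transmission spectrum to a grade, and
2. a **volumetric quantifier** that turns serial cross-section masks of
   a cut fruit into the watercore volume fraction which defines the
   ground-truth grade.

## 2. The quadratic convolution

An ordinary convolutional neuron computes `x·w + b` over a sliding
window `x`. The quadratic neuron computes

```
f(x) = (x·w_r + b_r) (x·w_g + b_g) + (x∘x)·w_b + c
```

where `x∘x` is the elementwise square. The product term lets a single
neuron express interactions between bands within its receptive field,
and the squared term is an autocorrelation-like feature that is robust
to sign changes. With `w_g = 0, b_g = 1, w_b = 0, c = 0` the neuron
reduces *exactly* to the linear one — this reduction is both a unit test
and the initialization strategy (below). The activation is applied by
the enclosing layer, not inside the convolution; this keeps the raw
operator algebraically testable against a naive triple-loop oracle.

### Architecture and the canonical input length

The classifier is: quadratic conv (kernel 64, stride 8, 16 channels) →
BN → ReLU → maxpool(2/2) → conv(3, 1, 16→16) → BN → ReLU → maxpool(2/2)
→ conv(3, 1, 16→8) → BN → ReLU → flatten → dense(100) → ReLU →
dropout(0.5) → dense(4). All convolutions use same-style zero padding.

The instrument grid has 701 bands, but the architecture's documented
head flattens **512** features into the 100-unit dense layer. Under
same padding, 512 = 64 positions × 8 channels is reached only from an
input of length 2048 (2048 → 256 → 128 → 128 → 64). A 701-band input
cannot produce 512 under any standard padding, so spectra are linearly
resampled to the canonical length 2048 (`resample_to_length()`) before
entering the network. Linear interpolation (rather than zero padding)
preserves band shapes and adds no artificial step edge. The builder
verifies the declared flatten width against a shape trace and rejects
mismatches.

### Initialization

`w_r` uses fan-in-scaled (He) initialization; the quadratic extras start
at `w_g = 0, b_g = 1, w_b = 0, c = 0`, so the quadratic network *starts
exactly at its linear twin* and the product/square pathways are learned
only when the data rewards them. This stabilizes early training — a
quadratic form with random `w_g`, `w_b` amplifies activations
multiplicatively and diverges easily — and makes the reduction property
the literal starting point, which the tests exploit.

### Training

Softmax cross-entropy is minimized with RAdam (the variance-rectified
Adam; rectification keeps early steps SGD-like until the second-moment
estimate is trustworthy). L2 weight decay (1e-4) is applied to weight
matrices only, not biases or batch-norm parameters. Defaults: batch 32,
learning rate 1e-3 with a cosine anneal to one tenth over the run
(constant is selectable), dropout 0.5. The published protocol (learning
rate 0.5, 500 epochs) is preserved as `profile = "paper"` for
documentation; 0.5 is far outside usable RAdam ranges for this
architecture and frequently diverges, hence the toolkit default.
When a monitoring set is supplied, the weights with the best monitoring
accuracy are checkpointed and restored, mirroring best-epoch reporting
of accuracy curves. All randomness — initialization, shuffling,
dropout — derives from the configuration seed; identical configurations
reproduce identical weights bit for bit.

The whole network (im2col gather, three BLAS products per quadratic
layer, batch-norm, pooling, dense head, and all gradients) is written in
vectorized base R. Backpropagation is verified against central finite
differences layer by layer, and the quadratic layer's `w_r` gradient is
verified to equal the linear layer's gradient at the reduction point.

## 3. The synthetic spectrum generator

No public dataset of graded watercore transmission spectra exists, so
the generator emulates the statistical structure the classifier relies
on, as a stated world rather than a tuned one:

* **Template** (`template_spectrum`): a smooth broadband transmission
  envelope `0.15 + 0.85·exp(−((λ−680)/180)²)` attenuated Beer–Lambert
  style by two Gaussian absorbance bands at 970 nm (width 35 nm) and
  760 nm (width 25 nm, 0.45× weaker). Band absorbance is
  `0.25 + 6·ratio`, so depth grows strictly monotonically with the
  watercore fraction. Intensities stay positive by construction.
* **Grades**: level 1 has ratio exactly 0; levels 2–4 draw ratios
  uniformly from (0.001, 0.03), (0.03, 0.06) and (0.06, 0.12). The 0.12
  cap is arbitrary (severe cases) and configurable. Labels therefore
  agree with `grade_from_ratio()` by construction — a cross-module
  contract the tests assert.
* **Noise model**: per sample, a multiplicative scatter factor
  `1 + N(0, 0.05)`, an additive baseline `N(0, 0.02)`, and per-band
  noise proportional to the signal (`N(0, 0.01·I(λ))`). These magnitudes
  are typical of handheld fruit transmission measurements: scatter of a
  few percent dominated by coupling/geometry, and ~1 % relative detector
  noise. Averaging of acquisition replicates is supported (real
  protocols often average three scans) but defaults to 1.
* The wavelength grid is 350–1050 nm at 1 nm (701 bands), the
  spectrometer's stated working range. (Source texts also mention
  "300–1100 nm" for the same 701 bands, which is arithmetically
  inconsistent at 1 nm; the spectrometer range wins.)

What the generator does **not** emulate: radiative transfer in flesh,
temperature drifts, fruit-size effects, stray light, or any covariance
structure between scatter and grade. A green classification test
therefore establishes that the pipeline can learn monotone band-depth
structure under realistic scatter/noise — not field performance.
Published field accuracies cannot be reproduced here because the
original orchard data are private; the learning criterion is therefore
*directional* (quadratic ≥ linear baseline, both ≥ 0.80) rather than a
numeric reproduction.

The raw (resampled) spectra feed the network directly; the named
preprocessing operators exist for the classical chemometric pipelines
and the CLI, since the deep model's source protocol applies them only to
the traditional-method comparison.

## 4. Preprocessing and partitioning conventions

* Standard deviations are **sample (n−1)** everywhere, so examples like
  `snv(c(1,2,3)) = c(-1,0,1)` are exact.
* MSC regresses each spectrum on the set's mean spectrum by OLS and
  inverts the fit; the reference is stored and reused for held-out data.
  A single-spectrum set is its own reference and passes through
  unchanged.
* Column standardization persists its center/scale and applies them
  unchanged to new data; zero-variance columns are an error naming the
  column.
* `stratified_split` rounds the per-class training count half up and is
  seeded; `spxy_split` is deterministic (no RNG): joint distance
  `dx/max(dx) + dy/max(dy)`, seed pair at the maximum, then max–min
  (Kennard–Stone) accretion. Grade labels enter the y-distance
  ordinally (1–4) — one-hot coding would make all between-class
  distances equal and waste the response. Ties break to the lowest
  index for cross-platform determinism. If one distance component is
  degenerate (all zero) the other is used alone, with a warning; both
  degenerate is an error.

## 5. The volumetric quantifier

Real fruit are sliced into 4.5 mm sections and each cut face
photographed and segmented. The package deliberately starts *after*
segmentation: its inputs are binary masks (fruit region, watercore
region ⊆ fruit). The trained segmentation and video-interpolation
networks used upstream in the source workflow have their value in their
weights, which are not reproducible here; the implementable mathematics
is the stack → interpolate → fuse → ratio chain, and that is what the
package provides, on given masks.

* **Slicing model**: a slice photograph is modelled as one plane of its
  slab — the slab's central plane by default (`plane = "center"`), or
  the lower cut face (`plane = "face"`). The number of slices is
  `floor(depth / thickness)`.
* **Shape interpolation**: between adjacent masks, signed distance
  fields (exact Euclidean, Felzenszwalb–Huttenlocher transform) are
  blended linearly at fractions `t = i/(n+1)` and thresholded at zero.
  For concentric discs this yields exactly a disc of linearly
  interpolated radius. An empty endpoint is represented by a uniformly
  negative field whose magnitude is the companion region's inradius, so
  a region shrinks smoothly and vanishes halfway through the gap (an
  infinite-magnitude convention would make it vanish immediately).
* **Fusion**: originals and interpolants are stacked as sub-slabs of
  thickness `T/(n+1)`; each mask owns the interval up to the midpoint
  towards its neighbours and the end masks absorb the outer halves of
  the end slabs, so every reconstruction spans the full sliced depth
  `N·T` and `n_intermediate = 0` reduces exactly to naive extrusion.
  Watercore ⊆ fruit is re-enforced voxelwise after interpolation.
* **Phantoms**: ellipsoid fruit with non-overlapping ellipsoid watercore
  components, voxelized at a configurable pitch; the true ratio comes
  from the closed-form ellipsoid volumes, never from voxel counts, so
  the phantom is an independent oracle for the whole chain.
* **Grade boundaries**: `< 0.001` → 1 (traces count as normal),
  `< 0.03` → 2, `≤ 0.06` → 3 (both endpoints of 3–6 % closed),
  `> 0.06` → 4. The interval notation in the source is ambiguous at the
  endpoints; one convention is fixed and documented.

### A negative result, stated honestly

One expected property did **not** survive measurement: that SDF
interpolation (`n_intermediate = 8`) recovers the volume *ratio* of the
canonical sphere-in-sphere phantom (fruit r = 40 mm, watercore r =
20 mm, true ratio 0.125, pitch 0.5 mm, 4.5 mm slices) more accurately
than plain extrusion (`n_intermediate = 0`). Measured relative errors
are ≈ −0.2 % for extrusion and ≈ −2.7 % for interpolation; the
corresponding acceptance assertion is intentionally left failing rather
than weakened.

The reason is quadrature, not a bug. Extruding central-plane masks is a
midpoint rule applied to the area profile A(z); for smooth convex bodies
its error is second order in the slice thickness — already ~0.2 % at
4.5 mm — and the same holds for cut-face masks (a trapezoid-like rule).
Linear SDF blending instead interpolates the section *radius* linearly
in z; since r(z) = √(R² − z²) is concave, the blend systematically
underestimates section areas, and next to an empty slice the region
closes at mid-gap regardless of where the true surface closes. Both
biases are proportionally larger for the small watercore sphere than for
the fruit, so the *ratio* is underestimated by 2–3 % for any number of
intermediates, under either slicing convention, and on random
under-resolved ellipsoid phantoms as well. Interpolation does make the
reconstructed *surface* far more continuous — its upstream purpose —
but for the scalar volume fraction of well-resolved smooth bodies,
extrusion is the better estimator. Users of `quantify_stack()` who care
only about the ratio may prefer `n_intermediate = 0`; the default stays
8 because the reconstruction itself (not just the ratio) is a product of
the pipeline.

## 6. Numerical and degenerate-input conventions

* Constant spectra are degenerate-input errors for SNV/min-max; a
  zero-variance reference is one for MSC.
* Max-pooling ties take the earlier position; `max.col` prediction ties
  take the first class — both fixed for determinism.
* Batch norm uses biased variance for normalization and unbiased for
  running averages (momentum 0.1), evaluation uses running statistics.
* Ratios ≥ 1 from `watercore_ratio` (watercore filling the whole fruit)
  warn rather than error; `grade_from_ratio` rejects ratios outside
  [0, 1).
* Checkpoints are JSON at full precision; a round-trip reproduces
  predictions to numerical tolerance and embeds the full configuration.

## 7. Scaling choices in the tests

The published training protocol (500 epochs) is scaled to 40 epochs in
the acceptance benchmark — accuracy plateaus around epoch 30 on the
synthetic set — and the benchmark averages 3 seeds to damp run-to-run
variation, keeping the whole suite inside a single-CPU time budget. The
phantom acceptance test runs at the stated 0.5 mm pitch; unit tests use
1–2 mm phantoms for speed.

## 8. Known limitations

* The classifier is CPU-bound R; it trains an 800-sample benchmark in
  minutes but is not meant for large-scale hyperparameter search.
* The generator's scatter model is global per spectrum; wavelength-
  dependent scatter (which MSC/SNV only partially remove in real data)
  is not simulated.
* The volumetric module assumes registered, same-size masks; slice
  misalignment and segmentation error are out of scope.
* SPXY distances are Euclidean over whatever representation is passed
  in; no spectral distance weighting is applied.
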