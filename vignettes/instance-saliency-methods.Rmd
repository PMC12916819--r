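---
title: "Instance-level quantitative saliency for volumetric segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-level quantitative saliency for volumetric segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instasal)
```

## The problem

Semantic segmentation networks for multi-lesional diseases (the motivating
case is white-matter lesion segmentation in multiple sclerosis, from FLAIR
and MPRAGE MRI) emit one prediction per voxel. Classical pixel-attribution
methods explain a single scalar score, so applying them to segmentation
requires choosing what to explain. Aggregating *all* spatial predictions
explains the class as a whole and merges the contributions of every lesion
into one uninterpretable map. What a radiologist needs is the explanation of
*one instance*: which input voxels drove the detection and contouring of
this particular lesion?

`instasal` implements two instance-level methods and the experiments that
validate them:

* **SmoothGrad over a lesion domain.** With logits $y(x)[v]$ and a lesion
  domain $\Omega \subset \Gamma$ (one connected component of the thresholded
  probability map), gradients $\partial y(x_n)[v']/\partial x_n[v]$ are
  computed for every source voxel $v' \in \Omega$ on $N$ noise-perturbed
  copies $x_n$ of the input, and combined per voxel $v$ either by
  **mean** aggregation (averaging over $n$ and $v'$) or by the
  **signed maximum**: per repetition, keep the candidate of largest absolute
  value with its sign, then average over repetitions. One map is produced
  per input channel.
* **Instance Grad-CAM++.** The class-level formulation aggregates
  supra-threshold logits into $y' = \sum_{y[v] > t} y[v]$ and weights each
  activation map $A^k$ of a chosen layer by a single scalar
  $\omega^k = \sum_v \alpha^k[v]\,\mathrm{Relu}(\partial y'/\partial A^k[v])$.
  The instance variant replaces $y'$ by the unthresholded sum over one
  lesion domain and *removes the spatial summation*, keeping a per-voxel
  weight $\omega^k[v] = \alpha^k[v]\,\mathrm{Relu}(\partial y'/\partial A^k[v])$,
  so activation from other instances cannot leak into the map. The final
  heatmap is $\mathrm{Relu}(\sum_k \omega^k[v] A^k[v])$, upsampled to the
  input grid when the layer resolution differs.

## Why the signed maximum

Mean aggregation divides by $|\Omega|$: because gradients are local (see the
receptive-field discussion below), distant pairs of voxels inside a large
lesion contribute near-zero cross terms, and map values shrink roughly as
$1/|\Omega|$. Values are then not comparable between lesions of different
sizes. The signed maximum is size-invariant: on the per-voxel linear
reference model with channel weights $w$, the in-lesion value equals $w$
exactly for $|\Omega| \in \{1, 8, 64\}$, while the mean scales as
$w/|\Omega|$ (this is asserted in the test suite). Size-invariant values are
what makes the saliency *quantitative*: peak values can be compared across
lesions and used to flag likely detection errors.

## Reference models and derivative correctness

Saliency code is easy to get silently wrong, so every gradient path is
anchored to models with known derivatives:

* `linear_model(w, b)` — per-voxel affine map, no spatial mixing, receptive
  field 0. Gradients are input-independent: the oracle for aggregation
  algebra.
* `conv_model(kernel)` — one fixed convolution, no nonlinearity. The
  gradient of a single output voxel is the flipped kernel: the oracle for
  locality (exact zeros beyond the kernel radius) and for the equivalence of
  the single-backward mean aggregation with brute-force per-voxel averaging
  (within 1e-5).
* `tiny_cnn()` — a trainable two-level encoder–decoder (~10k parameters)
  written directly on the package's convolution kernels, with a skip
  connection, average pooling, nearest-neighbour upsampling, two decoder
  convolution blocks and a 1×1×1 logit head. Two decoder blocks matter: with
  a single one the gradient path is nearly content-independent and
  background gradients do not attenuate, washing out the peak-value contrast
  between detected lesions and control regions. Input and activation
  gradients are exact backpropagation, verified against central finite
  differences in the tests. The analytic
  receptive-field radius (6 voxels, Chebyshev) is derived from the layer
  hyperparameters and bounds the support of every saliency map, which
  justifies computing maps on a crop around $\Omega$ (margin = the radius)
  and re-embedding them — the cropped and full-volume computations agree
  exactly for the reference models.

### Higher-order derivatives and the $\alpha$ coefficients

Grad-CAM++'s $\alpha^k[v]$ uses second and third derivatives of $y'$ with
respect to $A^k[v]$. Two routes are provided:

* **exact** — nested differentiation. For the tiny CNN the logits are
  *linear* in the final decoder activations (1×1×1 head), so the exact
  higher-order derivatives are identically zero and the guarded division
  yields $\alpha = 0$: the documented degenerate case of piecewise-linear
  (ReLU) networks. The exact route is therefore validated on reference
  functionals with genuine curvature (an exponential aggregate with
  closed-form derivatives, cross-checked against finite differences at
  relative tolerance 1e-3).
* **expgrad** (default for networks) — the power-of-first-gradient route of
  the original Grad-CAM++ formulation: substituting $\exp(y')$ for the score
  turns the derivatives into powers of the first gradient $g$ and the
  exponential cancels, $\alpha = g^2 / (2 g^2 + S_A\, g^3)$. The route used
  is recorded in the heatmap metadata.

Numerical choices: the division guard sets $\alpha = 0$ where the
denominator magnitude is below 1e-8 (the aggregate is locally linear there
and the coefficient is meaningless); the activation-sum factor $S_A$
follows the literal published form (global sum of $A^k$ against the local
third derivative), with the per-location alternative behind a flag;
rectifiers are exactly $\max(0, \cdot)$; upsampling is trilinear by default
(nearest available), and is the identity at matching resolution.

## Instance extraction and example categories

Probability maps are binarized with a **strict** inequality $p > t$
(default $t = 0.3$), components are labelled under **18-connectivity**
(faces and edges, corners excluded) and components under **5 mm³** are
removed; the filter is applied to ground-truth components as well by
default (configurable). A prediction instance is a **TP** iff it overlaps
the ground-truth mask in at least one voxel, else **FP**; a ground-truth
instance with zero overlap with the prediction mask is an **FN**. Matching
is deliberately one-sided — no one-to-one assignment is defined. **TN**
examples are ten spheres of 93 mm³ (radius ≈ 2.81 mm) sampled uniformly
inside the support mask, rejecting spheres touching the ground-truth or
prediction masks (spheres may overlap each other; a cap of 10,000 rejection
attempts per sphere raises an explicit error on infeasible support). The
discrete sphere keeps its true voxel volume rather than being forced to
93 mm³ exactly. All labels and tie-breaks follow column-major scan order
(first axis fastest), and voxel indices are 1-based R array subscripts
throughout.

## The synthetic phantom

Since the clinical dataset is proprietary, the package generates phantoms
with the statistical structure the methods assume: blob lesions (spheres
with a 1-voxel cosine-taper edge, radius 1.5–3.5 mm) that are hyperintense
in channel 1 (+3 noise-SD units, FLAIR-like) and hypointense in channel 2
(−1.5, the weaker T1-like conspicuity), on a unit-variance Gaussian
background inside an ellipsoidal brain support, with constant "air" well
below brain intensities outside (so the transplantation sanity check can
distinguish in-brain from out-of-support placement). Intensities are
z-scored over the brain mask only, mirroring brain-focused normalization.

The background additionally carries a smooth low-frequency field
(SD 1.5, correlation length 8 voxels). This is deliberate: real MRI keeps
smooth regional intensity variation even after bias correction and
z-scoring, so absolute intensity alone does not identify a lesion. Without
the field, a per-voxel threshold solves the phantom task perfectly and a
trained model has no reason to look at perilesional tissue — the premise of
the context experiments would be vacuous. With it, detection must rely on
local contrast, and the trained tiny CNN reproduces the qualitative
structure reported for clinical networks: positive saliency inside the
lesion and at its edge, negative saliency in the perilesional
neighbourhood, and stronger reliance on the hyperintense channel.

What the phantom does **not** emulate: anatomy, partial-volume mixtures
beyond the taper, multi-scanner variability, bias-field artifacts with
realistic spatial structure, or lesion-shape irregularity. Passing the
benchmark therefore shows the *methods* behave as designed on a model with
genuine spatial context — it is not evidence about any clinical model.

Lesion placement guarantees each component survives the 5 mm³ /
18-connectivity filter and that instances stay separable (centre distance
at least the sum of radii + 3 voxels).

### Perilesional shell

The sign-structure analysis needs a "neighbourhood" region. The first ring
of voxels around a component still carries lesion-like intensity (the
partial-volume edge), and saliency there behaves like the lesion edge, so
`instance_shell()` skips it by default (`inner = 1`, shell = rings 2–3).
Measured per-ring on the trained phantom benchmark, ring 1 has a positive
median while rings 2–5 are negative for every lesion — the same
inside-positive / neighbourhood-negative pattern the methods are meant to
expose.

## Experiments

* **Peak distributions** (`peak_value_distributions`): per example the
  maximum and minimum of the channel-1 map; per category the median with a
  seeded 1000-resample bootstrap 95% CI; all pairwise two-sided
  Mann–Whitney tests. The U test enumerates the permutation null exactly
  for group sizes ≤ 8 (mid-ranks under ties; two-sided
  $p = \min(1, 2\min(P(U \le u), P(U \ge u)))$) and otherwise uses the
  tie-corrected normal approximation.
* **Sanity checks**: saliency of a probe domain in lesion-free tissue
  (`empty_region_check`; informative only for spatially aware models — a
  voxel-wise model produces identical magnitudes everywhere by
  construction), a single-voxel domain at a lesion's centre of mass
  (`center_of_mass_domain`), and lesion transplantation
  (`transplant_lesion`) with an optional 3 mm context shell, which copies
  intensities onto a translated footprint and provably leaves every other
  voxel untouched.
* **Context probe** (`context_probe`): iteration 0 zeroes everything except
  $\Omega$; each iteration restores original intensities on a one-step
  morphological dilation of the visible region (face-connected element by
  default, so one iteration ≈ 1 mm of context at 1 mm spacing; a
  26-connected element is available). Per iteration the mean Softmax score
  in $\Omega$ and a strict-threshold detection flag are recorded. When the
  dilated region covers the crop, the scores equal unmasked inference — an
  exact consistency check. Lesions for this experiment are selected in the
  closed volume interval [90, 120] mm³ where available. The crop margin
  defaults to the iteration count so full coverage is reachable; dilation
  is not restricted to the brain mask by default (configurable in spirit:
  the probe takes whatever domain it is given).

## Problem sizes and runtime

The benchmark runs at desk scale: 32³ phantoms, 24 training phantoms,
25 Adam epochs (~2–3 minutes on one CPU), 8 validation phantoms, SmoothGrad
with N = 3 noisy repetitions for the distribution experiments (the package
default is the standard N = 50, σ = 0.05; the reduction only widens the
per-example noise, which the ≥ 30-example groups absorb). The signed-maximum
rule requires one backward pass per source voxel per repetition —
$N \cdot |\Omega|$ passes per map — which is the dominant cost and the
reason maps are computed on receptive-field crops.

## Known limitations

* The exact Grad-CAM++ route is vacuous for ReLU networks (zero curvature
  almost everywhere); the expgrad route is the meaningful default, exactly
  as in the original formulation.
* The tiny CNN is a deliberately small stand-in: its receptive field
  (radius 6) caps how much context the probe can reveal; plateaus beyond
  ~6 mm of restored context are expected by construction, and on the easy
  phantom contrast the lesion alone can already trigger detection at
  iteration 0 (the score, not the detection, carries the context signal).
* Training determinism is guaranteed for a fixed seed and BLAS thread
  count; the validation summary is reported with the trained model rather
  than assumed.
* 2D grids are supported by a singleton third axis for all reference-model
  paths; the tiny CNN itself operates on (possibly singleton) 3D grids and
  pads odd extents internally.
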