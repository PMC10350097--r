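---
title: "Direct tract segmentation from diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct tract segmentation from diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White-matter tracts — bundles of axons connecting brain regions — are
segmented for surgical planning and for studying development and disease.
Diffusion-weighted MRI (DWI) is the only modality that delineates most of
them, but the standard computational route goes through tractography or
fiber-orientation estimation. Those intermediate models introduce their own
errors and typically demand dense multi-shell acquisitions that clinical
scans do not have.

`dwisegment` implements the alternative: a fully convolutional network that
predicts tract probability maps **directly** from single-shell,
DTI-style diffusion data (b around 750–1200 s/mm², a few dozen directions),
plus an ensemble-disagreement statistic that flags unreliable segmentations.
Everything is exercised end to end on synthetic multi-tensor phantoms with
known ground truth, so the pipeline is fully testable on a desk.

## Input representation

Measurements are first normalized by the non-diffusion-weighted signal:
every diffusion-weighted volume is divided voxel-wise by the mean of the
b=0 volumes (`b0_normalize()`). When several b=0 volumes exist we average
them before dividing — the lower-variance choice; using a single one is the
degenerate case of the same formula. The b=0 threshold defaults to
50 s/mm² (scanners often report small nonzero b-values for unweighted
volumes). The attenuation is clipped to [0, 2]: physically it cannot
exceed 1, and larger values only arise from noise in near-zero b=0 voxels.

The normalized signals `x(q_i)`, measured on unit directions `q_i`, are then
projected onto the real, even-degree (antipodally symmetric) spherical
harmonics basis of order 2 (`sh_project()`). Order 2 has
(2+1)(2+2)/2 = 6 basis functions, so **any** subset of at least 6
directions maps to exactly 6 coefficient maps — the network input is the
same size no matter how many measurements a scanner acquired, which is what
makes the method acquisition-agnostic. The basis convention (degree-major
ordering l = 0; l = 2, m = −2..2, orthonormal on the sphere) is recorded in
every output sidecar; any fixed convention works as long as training and
inference share it, and ours is stated so models and inputs stay consistent.
The least-squares fit (`fit_sh()`) optionally carries Laplace–Beltrami
regularization weighted by l²(l+1)²; the default is no regularization, since
subsets of size ≥ 6 at order 2 give a determined system. Coefficients are
computed in the scanner frame of the bvecs; no reorientation to world axes
is applied (common diffusion-MRI practice).

## q-space subset augmentation

During training, each iteration uses a random subset of 6–12 measurements
(size drawn uniformly) rather than all of them — a cheap, highly effective
augmentation that shows the network a different view of the same scan every
time and teaches it to work from undersampled clinical acquisitions. The
subsets must be well spread in q-space: clustered directions leave the SH
fit ill-conditioned.

`select_spread_subset()` maximizes the minimum pairwise angular distance
(antipodally folded, so q and −q are the same measurement) while staying
random. Two regimes:

* small pools (≤ 20,000 candidate subsets): every subset is scored exactly
  and the draw is uniform among those within 95% of the optimal spread —
  maximal coverage with retained stochasticity;
* large pools: several randomized farthest-point starts, each refined by
  steepest-ascent swaps, with the draw made among the best restarts.

We adopted this two-regime design after observing that plain randomized
farthest-point growth can land 20–30% below the optimal minimum angle on
unlucky starts; the exact/refined scheme keeps every draw near-optimal while
different seeds still produce different subsets (the diversity the
test-time ensemble needs). At inference, `test_subsets()` draws `n` subsets
of fixed size `k` the same way; `disjoint = TRUE` forbids sharing
measurements across subsets, which probes reproducibility across
independent sub-scans. The number of inference subsets is configuration;
we default to `n = 10` and use `n = 4` in the desk-scale experiments below.

## Network and training

The segmentation model (`unet3d()`) is a plain 3D U-Net-style
encoder–decoder: per resolution level two 3×3×3 convolutions with
instance normalization and ReLU, 2× average-pool downsampling, nearest
upsampling with skip concatenation, and a 1×1×1 sigmoid head. The head is
multi-label (independent sigmoids, per-channel Dice), not softmax: tracts
overlap where they cross, so voxels can carry several labels. Architecture
details (depth, width, normalization) are configuration, not contract.
Defaults follow the full-scale recipe — 96³ patches, 6 input channels,
Adam with batch size 1 and learning rate 1e-4, halved when the validation
loss fails to improve (patience in epochs) — and every knob scales down for
desk-scale work.

Forward and backward passes are implemented in the package itself: the 3×3×3
convolutions reduce to BLAS matrix products via `im2col`/`col2im` primitives
written in C++ (`src/ops.cpp`), and pooling, upsampling, normalization, the
loss and Adam live in R. Backpropagation is verified against central finite
differences in the test suite.

The loss is the smoothed soft Dice loss
`1 − (2·Σpt + ε)/(Σp + Σt + ε)` averaged over label channels (ε = 1e-5),
i.e. training maximizes the Dice similarity coefficient. Each iteration:
draw a subset from the sampler, project the chosen case to SH with only that
subset, sample a patch (half the draws centered on a random foreground
voxel, half uniform — standard for sparse labels), one optimizer step.
Validation uses one fixed subset per validation case so epochs are
comparable. Everything is seeded: same seeds, bit-identical runs.

## Ensemble inference and uncertainty

`ensemble_predict()` projects the scan with `n` different subsets, predicts
each (`sliding_window_predict()`, 50% patch overlap, overlapping tiles
averaged, reflective padding for small volumes), and averages the member
probability maps voxel-wise into the final prediction ȳ.

Member disagreement carries information: if predictions from different
measurement subsets disagree, the segmentation is unreliable. We quantify
disagreement with an earth-mover's-distance (Wasserstein-1) surrogate that
respects the full spatial probability distribution instead of binarizing:

1. each member y_k and the mean ȳ are downsampled by a factor of 4 per axis
   (separable natural cubic splines at the coarse voxel centers, clipped to
   [0, 1] because cubic interpolation overshoots);
2. each volume is normalized to unit mass (EMD compares probability
   distributions of equal mass);
3. volumes are unfolded along a serpentine (boustrophedon) path — z-outer,
   y-middle, x-inner, directions alternating by parity — so consecutive
   positions are always grid neighbours; in 1D the cumulative-sum distance
   `Σ_t |P(t) − Q(t)|` is the *exact* Wasserstein-1 distance with unit
   ground metric, and along the unfolded path it approximates 3D transport;
4. the uncertainty is `u = (1/n) Σ_k EMD(y_k, ȳ)`, per tract, and a tract is
   flagged inaccurate when `u > 0.30` (the packaged default threshold).

Two readings of the pairing distance are possible; we sum absolute
cumulative differences (for scalars the ℓ2 distance of a pair is the
absolute difference), which makes the computation coincide with exact 1D
optimal transport — the property our LP-oracle tests check. A
root-sum-of-squares variant is available via `dist = "l2"`. The unit of u is
one coarse-voxel step along the unfolded path; an empty-mass member leaves
its EMD undefined and flags the tract outright. We compute u per tract
rather than jointly over channels, matching the per-segmentation use of the
statistic, and we sum over all unfolded positions.

## Evaluation metrics

`evaluate_segmentation()` reports, per label and as an unweighted mean over
labels present in the ground truth:

* **DSC** — 2|A∩B|/(|A|+|B|); 1 when both masks are empty, 0 when exactly
  one is;
* **HD95** — the maximum of the two directed 95th percentiles of
  boundary-to-boundary distances (percentiles by linear interpolation; the
  directional convention — max rather than mean — is stated because the
  literature varies);
* **ASSD** — the mean over the pooled symmetric surface-distance multiset.

Boundaries are mask voxels minus their 6-connected erosion, distances are
between voxel centers scaled per-axis by the voxel size (anisotropy-aware,
no sub-voxel meshing). Distance metrics are *undefined* — reported missing,
never zero — when a mask is empty.

## The phantom generator

`simulate_dwi()` builds single-shell DWI with known labels: tubular tracts
(possibly crossing) rasterized from centerline control points with local
tangents; per voxel the noiseless signal is
`S(g) = s0 · mean_c exp(−b gᵀ D_c g)` over occupying compartments, with a
cylindrically symmetric tensor per tract (axial eigenvalue along the
tangent) and an isotropic background tensor; equal compartment fractions at
crossings. Rician noise applies independent Gaussian noise of
sd = s0/snr on two quadrature channels and takes the magnitude. Defaults
are chosen to mimic a DTI-style acquisition: b = 1000 s/mm², 30
quasi-uniform half-sphere directions plus 3 b=0 volumes, axial/radial
diffusivity 1.7e-3/0.3e-3 mm²/s, isotropic background ADC 1.0e-3 mm²/s
(between parenchyma and CSF), snr 20, 64³ grid with 2 tracts
(`random_phantom_spec()` varies the geometry deterministically with its
seed).

What the phantom does **not** emulate: realistic brain geometry and
atlas-scale label counts, partial-volume and T2 effects, susceptibility
distortion, motion, spatially varying noise. Passing the desk-scale tests
therefore shows the pipeline is correct and that the direct-input method
works when its assumptions hold — it does not certify accuracy on real
scans.

## Desk-scale problem sizes

The test suite and the acceptance script run the whole method at sizes
chosen for a single CPU: 32³ phantoms with 2 tracts at snr 20; a depth-2,
width-8 network on 32³ patches (≈ 90k parameters) trained for 40 epochs
(320 iterations) with learning rate 1e-3 and plateau patience 3 — the small
model converges faster at 1e-3, while the package default stays at the
full-scale 1e-4 recipe; 4-member ensembles of 6-measurement subsets; 20
phantoms per condition for the uncertainty comparison. Under these
conditions the held-out mean DSC is ≈ 0.95 and the median u at snr 5
exceeds the median at snr 40 several-fold, which are the properties the
acceptance checks assert.

## Numerical choices and degenerate inputs

* b0 divisor floored at 1e-6; attenuation clipped to [0, 2].
* SH fits solve the normal equations; under-determined fits error unless
  Laplace–Beltrami regularization is requested.
* Subset selection is deterministic given its seed; ties broken uniformly.
* Instance-norm variance floor 1e-5; He-style initialization; training
  aborts with a diagnostic on a non-finite loss.
* Validation-loss improvements smaller than 1e-6 count as plateau.
* Cubic downsampling clips to [0, 1]; unit-sum normalization rejects
  all-zero volumes (the caller records u as undefined and flags the tract).
* Surface metrics error on empty masks; single-voxel-thick arrays treat
  every mask voxel as boundary.

## Label mapping for atlas-scale use

For full-scale work with an external tract atlas (e.g. 72 bilateral tracts
merged to 41 by combining left/right sections), the merge table is data the
user supplies; a documented placeholder with the expected two-column format
ships in `inst/extdata/label_mapping_placeholder.tsv`. The package itself
is label-count-agnostic (`out_labels` is configuration).

## Known limitations

* The network runs on CPU in R; it is sized for method validation, not for
  training on hundreds of HCP-scale scans.
* The EMD surrogate measures transport along the unfolded path; it is exact
  in 1D and an upper-bound-style approximation in 3D, and u values are
  comparable only across volumes of the same (coarse) shape.
* The uncertainty threshold 0.30 is a packaged default; on data unlike the
  phantoms it should be recalibrated against observed accuracy.
* Phantom realism limits are listed above; no claim is made about
  generalization to real multi-center data from these tests alone.
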