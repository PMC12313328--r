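---
title: "Models and methods behind mechanodc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanodc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mechanodc)
```

`mechanodc` analyses dynamic deformability cytometry in an undulating
channel: a cell transits a 150 µm channel of three 50 µm sub-regions with
widths 25/50/25 µm (height 20 µm), deforms at the first constriction
entrance, relaxes to a near-sphere in the cavity, deforms again entering
the second constriction, and relaxes once more. This vignette documents the
models, parameters and numerical choices; the README shows the user-facing
workflow.

## Channel model

The axial coordinate `x` is in µm, zero at the first constriction entrance,
so the cavity spans `[50, 100)`. The *geometric* width profile is a sum of
logistic steps at the four region boundaries; `transition_scale` (default
10 µm) is the 10–90 % width of each step, chosen so that the width matches
the nominal 25/50/25 values at each region midpoint to well within 1 %.

The centreline velocity uses one-dimensional mass conservation,
`v(x) = velocity_scale · Q / (w_v(x) · h)`, but with its *own* smoothing
(`velocity_transition_scale`, default 22 µm): the flow field develops over
a length comparable to the channel width, so the centreline velocity — and
hence the shear-stress proxy `dv/dx` — varies smoothly through the whole
cavity rather than only at the walls' steps. This reproduces the V-shaped
stress profile through the cavity with a single zero crossing at its
midpoint (75 µm under defaults), while keeping the velocity contrast
`v(25)/v(75) ≈ 2` implied by the 50:25 width ratio. The default 22 µm was
set as the largest smoothing that keeps that contrast within 5 % of 2.

Two calibrations anchor the remaining free constants:

* `velocity_scale = 2.58` makes a tracer cross the alignment window
  `[−30, 170]` µm in ≈ 46 frames at 11 000 fps (≈ 27 frames over the
  150 µm channel proper, the experimentally reported sampling density).
  Physically the factor absorbs the sheath flow and the centreline-to-mean
  velocity ratio of a rectangular duct.
* `inlet_effective_width = 80` µm is the effective centreline width of the
  inlet/outlet reservoirs. A literal wide reservoir under 1-D mass
  conservation would make cells crawl through the margins and blow the
  aligned sequences past the 50-frame budget; 80 µm keeps the margin
  transit fast (as a developing entrance jet is) while still giving the
  entrance a stronger velocity jump — and so a larger first deformation
  peak — than the cavity exit.

## Cell deformation model

A cell is an area-conserving ellipse with semi-axis `a` along the channel
and `b` perpendicular; `a·b = r²` and the aspect ratio `D = a/b` is the
single shape degree of freedom. Shape follows first-order relaxation
towards a stress-set equilibrium:

    dx/dt = v(x)
    dD/dt = (D_eq(x) − D) / τ
    D_eq(x) = 1 + k·[dv/dx]₊ + c·k·[dv/dx]₋

* `k` (seconds) — deformation gain, mapping the velocity gradient to the
  equilibrium aspect ratio;
* `τ` (milliseconds) — relaxation time;
* `c = compression_ratio` (default 0.06) — cells respond only weakly to
  compressive (negative) gradients. With a symmetric response the cavity's
  strong negative gradient would drive the aspect ratio far below 1,
  whereas observed traces relax to ≈ 1 there; a small asymmetry produces
  exactly that: relaxation to a near-sphere with a slight undershoot, and a
  most-relaxed shape pinned at the stress zero crossing.

Neither `k` nor `τ` is an estimate of any real cell line's constitutive
parameters — only linear slopes are ever fitted to the traces — they are
generator knobs. The default phenotypes emulate the classic
actin/microtubule perturbation experiment with radius distributions matched
across groups (so size carries no class signal):

| phenotype | gain k (s)        | τ (ms)        | radius (µm) | emulates |
|-----------|-------------------|---------------|-------------|----------|
| hl60      | 1.4e-4 ± 2.0e-5   | 0.14 ± 0.025  | 6.0 ± 0.45  | untreated |
| hl60d     | 2.1e-4 ± 2.5e-5   | 0.10 ± 0.018  | 6.0 ± 0.45  | actin-disrupted: more deformable, faster |
| hl60n     | 0.9e-4 ± 2.5e-5   | 0.19 ± 0.040  | 6.0 ± 0.55  | microtubule-disrupted: stiffer, slower, more variable |

These values were fixed once, by requiring the simulated traces to show the
qualitative physics the device produces: first-peak aspect ratios around
1.3–1.5, a smaller second peak (the positive-stress run-up from the cavity
is shorter than at the inlet), relaxation to within 0.02 of a sphere at the
cavity midpoint, and rD/slope magnitudes of a few 10⁻¹ and a few 10⁻³ µm⁻¹
respectively, ordered hl60d > hl60 > hl60n.

**Integration.** Classical fixed-step RK4 with `substeps` (default 10)
steps per frame interval; RK4 on the relaxation equation is stable for
`dt/τ < 2.78`, and the integrator refines the step automatically to
`dt ≤ τ/2` (or errors, if refinement is disallowed) so stiff small-τ cells
integrate correctly. Against a halved-step solution the default
trajectories agree to better than 1e-6 relative. Frame-time states are
linearly interpolated from the sub-step grid.

**Rendering.** Masks are rasterised on the global 0.26 µm pixel grid
(pixel centres inside the ellipse), with segmentation noise modelled as a
smooth radial boundary perturbation: a 4-harmonic Fourier series with
Gaussian coefficients, total amplitude `boundary_noise_sd` (default
0.4 px). All randomness flows from one root seed through per-cell
sub-seeds, so datasets are byte-reproducible regardless of processing
order. Artifact injection (trajectories first appearing mid-channel;
single concave crescent frames) exercises the tracking and filter stages.

What the generator deliberately does *not* emulate: brightfield texture,
motion blur, focus variation, cell–wall contact and lubrication, cell
rotation, true 3-D flow around the cell, and segmentation failures other
than boundary noise and concavity. Passing tests therefore demonstrate the
pipeline's correctness and the protocol's statistical behaviour on a
controlled population, not performance on real recordings.

## Tracking and event filters

Detections are linked greedily frame-to-frame, nearest neighbour first,
under two gates: near-monotone forward motion (`Δx ≥ −1 µm`; cells are
advected and cannot cross on the channel axis) and displacement at most
`max_displacement` per frame of gap (default 16 µm ≈ twice the largest
per-frame advance). Tracks survive up to 3 consecutive missed frames. Ties
break deterministically (smaller Δx, then lower y). A global assignment
solver is unnecessary under these physics; the greedy match recovers
ground truth exactly on multi-cell synthetic data.

Validation drops trajectories that first appear past `x = 0` ("impossible
start") or do not cover the alignment window ("incomplete span"). Event
filters drop trajectories with any frame's convex-hull-to-mask area ratio
strictly above 1.1 (hull area counted exactly on the pixel lattice via
Pick's theorem) and trajectories whose mean radius deviates by ≥ 3
population SDs — computed on the pooled population after tracking, so the
filter is order-independent.

## Features

Ellipses are fitted by image moments (centroid from first moments, axes and
orientation from the second central moment matrix, with the 1/12 px²
pixel-variance correction); the aspect ratio is the ratio of the fitted
ellipse's extents along and perpendicular to the channel axis, so AR < 1
(compression) is representable. The R1–R4 partition anchors on the
pre-cavity AR maximum (peak 1), the cavity AR minimum (baseline) and the
downstream maximum (peak 2); `rD(x) = AR(x) − AR_baseline`; R2/R3 slopes
are OLS slopes of AR against x in µm⁻¹. Partitions with fewer than two
intervals in R2 or R3 are flagged degenerate and their features propagate
as missing. Perimeter is the crack-edge boundary length at pixel
resolution, converted to µm — a consistent (if resolution-dependent)
sequence channel. The extended set adds, for the masks at the three anchor
frames, the normalised second central moments and Hu's seven invariants
(10 descriptors × 3 regions = 30 features).

Sequences for the recurrent models use channels (AR, perimeter, rD, area),
clipped to the alignment window and post-padded with zeros to length 50
under an explicit validity mask (the padding side and value are a package
choice; the mask makes it irrelevant). Mask-image sequences are 96×96
crops centred on the mask centroid, with the rasterised fitted ellipse as a
second channel; the stored representation is 4×4 average-pooled to 24×24,
which preserves sub-pixel boundary information as fractional occupancy
while keeping the convolutional models tractable on one CPU.

## Classifiers

All model families share one protocol: shuffled, stratified 70:15:15
train/validation/test split; per-feature (or per-channel) standardisation
computed on the training partition only; hyperparameters selected on the
validation partition; accuracy reported on the held-out test partition as
the mean of the row-normalised confusion-matrix diagonal. Tuning on the
test set would leak; the validation split exists precisely for selection.
Stratified five-fold cross-validation (each fold retrained from scratch)
reports mean ± SEM.

* **Tabular**: `randomForest` (grid over `mtry`, `nodesize`) or
  `e1071::svm` (RBF; grid over cost and γ).
* **Attribution**: interventional Shapley values computed in-package —
  exact subset enumeration up to 12 features, permutation sampling above —
  against a background sample; both modes satisfy the efficiency identity
  `Σφ = f(x) − E[f(background)]` to machine precision, and importances are
  reported as mean |φ|.
* **GRU**: a gated recurrent unit implemented in vectorised R (masked
  forward pass, backpropagation through time, Adam, gradient clipping),
  16 units × 1 layer by default. The readout is the masked *mean* of the
  hidden states rather than the final state: on ≤ 50-step sequences it
  keeps gradients alive across the whole trace and lets every deformation
  phase contribute. Padded steps pass the hidden state through unchanged,
  so padding cannot masquerade as signal.
* **CNN-GRU**: a convolutional encoder (5×5 kernels, stride 2, 8 filters,
  ReLU, 2×2 max-pool, dense embedding) applied with identical weights at
  every timestep to the pooled two-channel mask frames, feeding the same
  GRU. Gradients for both engines are verified against finite differences
  in the test suite.
* **Cavity-shape control**: the same convolutional encoder with a logistic
  head on a single cavity (most relaxed) frame per cell — measuring how
  much of the classification is mere morphology. On the default
  morphology-matched phenotypes it performs at chance, confirming that the
  sequence models' accuracy comes from deformation dynamics.

The sequence trainers default to the full 175-epoch protocol with
validation-based epoch selection; the experiments bundled with the package
override this with smaller budgets. Training sizes there are deliberately
modest — hundreds of cells per phenotype,
≤ 32 units, ≤ 50 epochs — the regime where the protocol's properties
(Bayes-rate recovery, tabular-vs-sequence parity, chance-level controls)
are already measurable and every experiment runs in minutes on one CPU.
With fixed seeds every fit in the package is exactly reproducible; the
pure-R implementation has no threading nondeterminism.

## Enrichment

For a target population at prior fraction `p`, sorting the
classifier-positive stream yields a target concentration equal to the
Bayes precision `tpr·p / (tpr·p + fpr·(1−p))`; enrichment is precision
over prior, using expected-value accounting (no finite-sample
hypergeometric correction). It is 1 exactly when `tpr = fpr`, bounded by
`1/p`, roughly `tpr/fpr` while `fpr ≫ p`, strictly increasing in TPR and
decreasing in FPR and prior.

## Known limitations

* The 1-D velocity model captures the centreline stress *shape*, not its
  magnitude; the gain `k` is therefore not interpretable as a compliance.
* The single-τ response cannot produce power-law rheology or
  stress-history effects; it is the simplest model with distinct
  peak/relax/peak traces and slope phenotypes.
* Feature noise is dominated by rasterisation and boundary perturbation;
  real segmentation errors are richer (merges, splits, halos).
* Overlapping cells in one frame merge into one detection when masks
  touch; the hull filter and tracking gates catch most, not all, of these.
* The perimeter channel depends on pixel resolution through the
  crack-length definition; it is consistent within a dataset.
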