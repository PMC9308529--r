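---
title: "Simulated brain thermal imaging for stroke penumbra segmentation"
author: "thermobrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated brain thermal imaging for stroke penumbra segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermobrain)
```

## The model

Heat transfer in perfused tissue is described by the Pennes bioheat
equation,

$$\rho C_P \frac{\partial T}{\partial t} =
  \nabla \cdot (\kappa \nabla T) +
  \omega_b \rho_b C_{pb} (T_a - T) + Q_m ,$$

where $\rho$, $C_P$ and $\kappa$ are the tissue density, specific heat and
thermal conductivity, $Q_m$ is metabolic heat generation, and the perfusion
term exchanges heat with arterial blood (density $\rho_b$, specific heat
$C_{pb}$, temperature $T_a$) at the volumetric perfusion rate $\omega_b$
(ml of blood per second per ml of tissue). Because $T_a = 36.7$ °C lies
*below* typical tissue temperature, perfusion is a cooling term while
metabolism heats; normal tissue settles where the two balance, at
$T = T_a + Q_m / (\omega_b \rho_b C_{pb})$ when diffusion is negligible
(about 37.006 °C for both white and gray matter with the built-in
constants).

Acute ischemic stroke perturbs both terms. The lesion model is concentric:
an infarct core (irreversibly dead tissue) keeping 20 % of white-matter
perfusion and generating no metabolic heat, inside a penumbra shell
(hypoperfused but salvageable tissue — the segmentation target) keeping
40 % of perfusion and 70 % of metabolism. All other thermophysical
properties are inherited from white matter, so
`deriveLesionProperties(WM, 0.4, 0.7)` reproduces the penumbra row of the
built-in table ($\omega_b = 0.00147824$, $Q_m = 3162.53$) and
`(0.2, 0)` the infarct-core row.

Blood density and specific heat are not fixed by the tissue table; the
package defaults are standard literature values
($\rho_b = 1050$ kg/m³, $C_{pb} = 3800$ J/(kg·°C)), exposed through
`bloodProperties()` and the YAML property config so users can substitute
their own. All analytic cross-checks in the test suite are computed from
the configured values, so the suite is self-consistent under overrides.

## The solver

`solveBioheat()` discretizes the equation on a uniform 2D grid
(default $\Delta x = 2$ mm, matching the slice geometry it emulates) with
an explicit in time, synchronous (Jacobi) finite-difference scheme,
$\Delta t = 0.1$ s. Conductivity at the midpoint between two pixels of
piecewise-homogeneous media is the harmonic mean
$2\kappa_a\kappa_b/(\kappa_a+\kappa_b)$, which preserves flux continuity
across tissue interfaces and makes a zero-conductivity neighbour a perfect
insulator. Iteration stops when the maximum absolute node-wise change
between successive sweeps falls below `tol` (default $10^{-7}$ °C, with
$10^{-5}$ used for desk-scale runs).

Design choices worth stating explicitly:

* **Boundary handling.** Pixels outside the brain and the outer grid
  border are Dirichlet nodes held at 37 °C and excluded from updates; the
  background is given water-like conductivity so the interface flux toward
  the fixed surround is defined, and its other properties never enter the
  update. This emulates a fixed-temperature skull boundary without
  assigning physiological properties to non-tissue.
* **Convergence test.** The maximum node-wise change, not an L2 norm; a
  converged field therefore guarantees a per-pixel bound.
* **Stability.** `stabilityCheck()` evaluates the explicit-Euler limit
  $\Delta t_{\max} = \min_{ij} \rho C_P / (4\kappa_{\max}/\Delta x^2 +
  \omega_b \rho_b C_{pb})$ (about 6.6 s for the built-in table at 2 mm, so
  the 0.1 s default is comfortably stable), and `solveBioheat()` refuses
  unstable configurations.
* **All arithmetic in double precision, °C throughout.** Only temperature
  differences and Dirichlet values appear, so no Kelvin conversion is
  needed.
* **Implementation.** The sweep loop runs in compiled code; the exported
  `fdmStep()` is a vectorized base-R reference implementation of one sweep,
  and the test suite checks the two against each other bit-for-bit, against
  a dense linear solve of the steady-state equations on small grids
  (agreement to $10^{-9}$ °C and better), and against the closed-form
  homogeneous steady state.

## Transient versus steady state: the core temperature sign

A point that deserves its own section. With the built-in tissue constants,
the thermal diffusion length of the infarct core,
$\sqrt{\kappa / (\omega_b \rho_b C_{pb})} \approx 13$ mm, exceeds the 5 mm
core radius of the standard 10 mm-core / 5 mm-penumbra lesion. The fully
converged steady state therefore has the warm penumbra dominating the
core: the lesion as a whole is a net heat source, the penumbra is about
+0.034 °C above normal white matter, and the core, while a *local* minimum
of the lesion profile, sits about +0.024 °C *above* normal white matter.
This was verified three independent ways (the iterative solver, the dense
steady-state oracle, and a fine-grid radial continuum solution).

The early-time behaviour is different: before diffusive exchange floods
the core, each tissue relaxes toward its local equilibrium (36.7 °C for
the metabolically dead core), so a partially converged run — stopping at
a $10^{-5}$ °C max node change, about 1,000 sweeps — still shows the core
*below* white matter (about −0.0009 °C) with the penumbra already warm.
A max-node-change stopping rule with a 0.1 s step can thus stop while a
slow (hundreds of seconds) perfusion–diffusion mode still holds the
transient sign. The acceptance test asserts the orderings in both regimes
and the line-profile test asserts the tolerance-independent facts: the
penumbra ring is warmer than flanking white matter, and the core is a
local minimum within the lesion.

## Phantoms and thermal images

`generateBrainPhantom()` rasterizes a schematic brain — an ellipse of
white matter with a gray-matter rim and a CSF band inside a background
border — at the emulated slice geometry (96 × 110 pixels, 2 mm isotropic).
The seed jitters the ellipse size and center within a pixel so synthetic
subjects differ. The anatomy is deliberately schematic: it produces all
tissue classes with realistic property contrasts, but no gyri, no
asymmetry, no partial-volume mixing, and its lesions are perfect disks.
Tests passing on these phantoms demonstrate the correctness of the solver
and pipeline machinery, not segmentation performance on real anatomy.

`renderThermalImage()` converts a solved field to a training image:
additive zero-mean Gaussian noise with standard deviation equal to 5 % of
the dynamic range of the non-background temperatures (the "5 % noise"
convention; a mean-referenced alternative is selectable), then min-max
normalization to [0, 1], then a center crop to 96 × 96 (the low side loses
$\lfloor (\mathrm{src}-\mathrm{target})/2 \rfloor$ pixels; 110 → 96 drops
seven columns per side). Noise is applied in temperature space by default;
applying it after normalization is available as an option since either
convention is defensible. The 8-bit PNG export rounds half-up; the float
representation is canonical.

## Dataset construction

`buildManifest()` reproduces the bookkeeping of the emulated study: 28
training subjects × 19 slices = 532 images, × 6 rigid variants (identity,
three quarter-turn rotations, horizontal and vertical flips) = 3,192;
two held-out subjects contribute 38 test images. Slice selection is
operationalized as the 19 slices with the largest penumbra area, ties to
the lower index. `kfoldSplit()` partitions *subjects* (not images) into
near-equal folds, so augmented variants of one slice can never appear on
both sides of a split.

## Architecture specification and parameter accounting

`buildUnetSpec()` emits the encoder–decoder topology as a layer table:
five encoder blocks of two 3×3 same-padded conv+ReLU layers with widths
64/128/256/512/1024, 2×2 max-pooling after blocks 1–4, dropout
($p = 0.5$) after blocks 4 and 5, four decoder stages of a *learned* 2×2
stride-2 up-convolution plus skip concatenation plus two 3×3 conv+ReLU
layers, and a 1×1 sigmoid head to a single penumbra-probability channel.
At 96 × 96 input the bottleneck is 6 × 6 × 1024 and
`countParameters()` gives exactly 31,030,593 (encoder 18,842,048, decoder
including the head 12,188,545), verified in the tests against an
independent per-layer summation. Two conventions required a decision: the
output layer is one sigmoid channel (background implied as complement),
which is the only choice consistent with that parameter total, and the
up-sampling operator must be a learned transposed convolution for its
weights to appear in the total. Reported "number of layers" depends on
whether pooling/dropout/concatenation count; `layerCounts()` tabulates the
total under several conventions rather than asserting one.

The soft Dice loss is
$1 - (2\sum p t + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
smoothing $\varepsilon = 1$ by default (configurable); $\varepsilon$ keeps
the loss defined on empty masks and bounds it in [0, 1].

## The training demo

No deep-learning framework is required: the package includes a compact
convolutional-network engine in base R (im2col convolutions, 2×2
max-pooling, stride-2 transposed convolutions, inverted dropout, Adam)
whose backward pass is validated by finite-difference gradient checks in
the test suite. One check detail: a ReLU whose pre-activation is exactly
zero makes the central difference one-sided, so the checks jitter biases
off the kink — this is a property of numerical differentiation, not of the
gradients.

`trainDemo()` runs the full protocol at desk scale: a width-reduced
network (channel multiplier 1/16 by default, i.e. widths 4–64) on 32 × 32
phantom slices, subject-level k-fold training, and test predictions formed
by averaging the fold models' sigmoid outputs and thresholding at 0.5.
The full-scale recipe (Adam at $10^{-4}$, batch 22, 100 epochs) is kept as
`trainingConfig()` defaults for reference, but at a few hundred gradient
steps it barely moves the weights; the demo therefore defaults to a 5e-3
learning rate, batch 4 and 50 epochs — step size scaled up as the problem
is scaled down. On the default synthetic datasets (9 training subjects ×
3 noisy slices, 3 held-out subjects) the demo reaches a test Dice around
0.7–0.8 against an all-positive baseline near 0.1. Individual folds can
stall at this scale (a dead-ReLU failure mode of small networks); the
fold-averaged prediction is robust to a stalled member. The demo shows the
machinery learns the thermal lesion signature; it says nothing about
full-scale performance on real data.

## Evaluation

`confusionCounts()` / `segmentationMetrics()` implement the standard
pixel-level accuracy, precision, recall and Dice; undefined ratios (0/0)
are reported as missing and flagged, never coerced to 0 or 1. Per-slice
results aggregate as mean ± SD. `exclusiveAgreementPct()` quantifies what
one segmentation captures that another misses, relative to ground truth:
the percentage of true-lesion pixels found only by the first prediction,
and of true-background pixels correctly rejected by the first while the
second marks them lesion. The denominators — ground-truth lesion and
background pixel counts — are a documented interpretation chosen because
they make the percentages comparable across slices; other normalizations
are conceivable.

## Problem sizes and limitations

The shipped tests and the acceptance script use: the 96 × 110 slice
phantom (solved to $10^{-5}$ and $10^{-7}$), a 61 × 61 homogeneous block
for the closed form, 6–8 pixel grids for the dense oracle, and the 32 × 32
demo above. Known limitations: 2D slices only (no through-plane
diffusion); disk lesions only; no oligemia tissue class; the Pennes model
itself assumes uniformly perfused tissue with a single arterial
temperature, which is known to misestimate lesion temperatures in vivo —
the package models the equation, not the patient.
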