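# thermobrain

Synthetic brain thermal imaging for acute ischemic stroke segmentation
experiments, in R.

Acute ischemic stroke changes local brain temperature: reduced blood
perfusion removes a cooling pathway and dying tissue stops producing
metabolic heat. `thermobrain` simulates this signature by solving the
Pennes bioheat equation

ρ C_P ∂T/∂t = ∇·(κ ∇T) + ω_b ρ_b C_pb (T_a − T) + Q_m

on heterogeneous 2D tissue maps with an explicit finite-difference scheme
(harmonic-mean interface conductivities, synchronous updates, Dirichlet
37 °C surround), and turns the solved temperature fields into normalized
grayscale "thermal images" for segmentation work. Around the solver it
provides the full experimental scaffolding:

* **Tissue model** — built-in thermophysical constants for CSF / gray /
  white matter; penumbra and infarct-core properties derived from white
  matter by perfusion/metabolism reduction factors (40 %/70 % and
  20 %/0 %); synthetic brain phantoms at the 96 × 110 px / 2 mm slice
  geometry with concentric disk lesions.
* **Imaging pipeline** — 5 % Gaussian noise, [0, 1] min–max normalization,
  center crop to 96 × 96; PNG/NIfTI/YAML/CSV I/O.
* **Dataset machinery** — six-variant rigid augmentation
  (532 → 3,192 training images for 28 subjects × 19 slices), subject-level
  5-fold crossvalidation splits.
* **Architecture spec** — a constructible U-Net layer table (channels
  64→1024, learned 2×2 up-convolutions, skip concatenations, 1×1 sigmoid
  head) with exact parameter accounting: 31,030,593 trainable parameters
  at 96 × 96 input; soft-Dice loss.
* **Training demo** — a width-reduced U-Net trained on synthetic phantoms
  by a compact pure-R convolutional engine (gradient-checked im2col
  convolutions, max-pooling, transposed convolutions, Adam), with fold
  averaging at test time.
* **Evaluation** — accuracy / precision / recall / Dice with explicit
  handling of undefined ratios, and exclusive-agreement percentages
  comparing two segmentations against ground truth.

Intended users: researchers prototyping physics-informed augmentation for
medical image segmentation, and anyone needing a verified, dependency-light
2D bioheat solver with stroke lesion models.

## Worked example

```r
library(thermobrain)

# a synthetic slice with a 10 mm infarct core + 5 mm penumbra shell
ph  <- embedLesion(generateBrainPhantom(96, 110, spacing = 2, seed = 1),
                   lesionSpec(core_diameter = 10, penumbra_thickness = 5))
fld <- solveBioheat(ph)          # explicit FDM to max node change < 1e-7 degC
fld
#> TemperatureField: 96 x 110 pixels, range [37.0000, 37.0446] degC
#>   14869 iterations, converged=TRUE, final delta 1e-07 degC

lab <- labelMatrix(ph); t <- tempMatrix(fld)
round(c(WM   = mean(t[lab == 3]),
        pen  = mean(t[lab == 4]),
        core = mean(t[lab == 5])), 4)
#>      WM     pen    core
#> 37.0070 37.0415 37.0315
```

The penumbra is ~0.034 °C warmer than normal white matter (perfusion is
cut more than metabolism, so a heat surplus remains). At full convergence
the small core is *also* slightly warm — it is a local minimum of the
lesion but sits above white matter, because its 5 mm radius is well inside
its ~13 mm thermal diffusion length; a partially converged run (tolerance
1e-5) still shows the transient core cooling instead. The methods vignette
(`vignettes/bioheat-thermal-imaging.Rmd`) discusses both regimes.

```r
img <- renderThermalImage(fld, ph, noise = 0.05, seed = 1)  # 96x96, [0,1]
spec <- buildUnetSpec(96, 96)
countParameters(spec)
#> [1] 31030593
nrow(buildManifest(28, 19, augment = TRUE))
#> [1] 3192
```

A command-line wrapper (`inst/scripts/thermobrain`) exposes the phantom /
solve / render / evaluate steps for shell pipelines.

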