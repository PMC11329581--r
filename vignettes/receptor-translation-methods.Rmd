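---
title: "Predicting receptor autoradiography from cytoarchitecture: models and methods"
author: "ReceptorGAN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting receptor autoradiography from cytoarchitecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative in vitro receptor autoradiography maps the density of
neurotransmitter receptors (here: the muscarinic M2 acetylcholine receptor
and the ionotropic kainate glutamate receptor) across brain sections, but
is slow and expensive, so whole-brain receptor coverage is sparse. Cell-body
(Nissl) stained sections, by contrast, are abundant and digitized at high
resolution. Because receptor architecture and cytoarchitecture are linked —
laminar borders of the two modalities broadly coincide even though
densities do not correlate pixel-wise — it is plausible to *predict* a
receptor density image from a nearby cell-body stained section.

ReceptorGAN implements that cross-modality translation for macaque primary
visual (V1) and primary motor (M1) cortex as a conditional generative
adversarial network (cGAN), together with everything the translation needs
around it: registration consumption and validation, midline-guided patch
sampling across a 16x resolution gap, training, image-quality evaluation,
and section-level reconstruction. Because the original macaque material is
not publicly deposited, the package also contains a first-class synthetic
data generator that reproduces the statistical structure the pipeline
assumes, so every stage is testable end to end.

## Correspondence geometry

Autoradiography sections are nonlinearly deformed relative to their
neighboring cell-body stained reference sections. The registration itself
(a B-spline landmark + intensity optimization in an external tool) is out
of scope; this package *consumes* dense deformation fields:

* A `DeformationField` stores per-pixel displacements at receptor-modality
  resolution (the field has the same dimensions as the autoradiograph).
  Applying a field moves a point $p \mapsto p + u(p)$ with bilinear
  interpolation of $u$ between grid nodes; no extrapolation is allowed.
* Fields are inverted by the fixed-point iteration
  $v \leftarrow -u(x + v)$, which contracts whenever the displacement
  Jacobian has norm below one — guaranteed for the band-limited synthetic
  fields, whose wavelengths are at least a canvas length. The default
  tolerance is 0.05 px on the composition residual (max over grid nodes),
  with `max_iter = 100`; synthetic fields are inverted to 1e-6 px.
* Landmark protocol: ~42 anatomical landmark pairs per section pair, ten
  of which are randomly held back for validation (`splitLandmarks`);
  `landmarkResiduals` maps validation landmarks through a field and
  reports distances in px and mm. The residual of the field that generated
  the landmarks is identically zero.

**Coordinate convention.** Physical mm coordinates with the origin at the
*centre* of the top-left pixel, x rightward, y downward;
`px = mm / resolution`. All samplers (warping, patch extraction, window
filtering) share this convention, which makes round-tripping across the
16x resolution gap exact. A consequence worth knowing: a window is an
exact pixel crop only when its boundaries sit at half-integer pixel
coordinates.

## Patch sampling

The cortical midline is a natural cubic spline through control points
spaced on average 8.6 mm apart (`fitMidlineSpline`), reparameterized by
arc length via dense polyline quadrature. Square 2 mm windows are stepped
every 0.2 mm of arc from the first control point (a final partial step is
dropped), and each base position is expanded to the Cartesian product of
offsets \{-0.5, 0, +0.5\} mm in x and y — nine windows per position,
giving ~90% linear overlap between consecutive base windows. Windows are
axis-aligned in receptor space (the source protocol never rotates them to
the local midline normal).

Window corners are mapped into the cell-body stained section by applying
the two inverse deformation stages and scaling to cyto pixels
(`mapWindowToCyto`); the mapped quadrilateral is generally not
axis-aligned, so the cyto patch is resampled onto a regular square grid
(default 2048^2 for a 128^2 receptor patch) by bilinear interpolation of
both geometry and intensity. Windows that leave the canvas or fall below
98% tissue coverage are excluded with a logged reason — the automated
stand-in for the manual exclusion of damaged patches.

## Model

The generator $G:(X^{cyto}, Z) \to \hat{X}^{ar}$ maps a cell-body stained
patch plus a per-pixel standard-normal noise channel $Z$ (and, for the
conditional multi-area variant, a constant area channel $C$: V1 = 0,
M1 = 1) to a receptor patch:

* **Backbone**: four convolutions, kernel 4, stride 2, padding 1, channel
  widths 8-16-32-64, reducing 2048^2 to a 64-channel 128^2 feature map.
* **Head**: a three-level U-Net at the receptor grid (widths 64-128-256),
  nearest-neighbour upsampling, skip concatenations.
* Batch-instance normalization (BIN) and ReLU after every convolution;
  the final convolution uses tanh, so outputs live in (-1, 1) and are
  mapped back to [0, 1] for evaluation.

The discriminator stacks four (optionally five) kernel-4/stride-2/
padding-1 convolutions with plain batch normalization and LeakyReLU
(slope 0.2), then a terminal fully connected layer producing one logit
per patch; it scores receptor patches only (the adversarial objective is
written as $D(X^{ar})$, not a pix2pix-style joint conditioning on the
cyto patch). The conditional variant appends the same constant condition
channel to both networks; the parameter difference against the
unconditional variant is exactly one first-layer kernel slice.

Because no deep-learning framework is available in the target
environment, the layers, batch-instance normalization, backpropagation
and the Adam optimizer are implemented in the package itself
(RcppArmadillo im2col/GEMM convolutions). Every analytic gradient is
verified against central finite differences in the test suite.

**Batch-instance normalization.** Per channel,
$y = \gamma\,(\rho\,\mathrm{BN}(x) + (1-\rho)\,\mathrm{IN}(x)) + \beta$
with $\rho$ learnable in $[0,1]$ (initialized at 0.5 and clamped after
each update). Training uses minibatch statistics for the BN component and
maintains running means/variances (momentum 0.1); evaluation-mode
forwards (`generatorForward`, `discriminatorForward`) use the running
statistics. This matters for conditioning: instance normalization removes
per-sample constant shifts, so the condition channel survives through the
BN pathway relative to the *training* population — evaluating with batch
statistics over a uniform-condition batch would silently cancel it.

## Losses and optimization

The joint objective is $\mathcal{L}(G,D) = \mathcal{L}_{GAN}(G,D) +
\gamma\,\mathcal{L}_1(G)$ with $\gamma = 0.5$. The adversarial value is
$\mathbb{E}[\log D(X^{ar})] + \mathbb{E}[\log(1 - D(G(Z, X^{cyto})))]$,
computed through numerically stable log-sigmoid forms; the discriminator
minimizes the equivalent binary cross-entropy. Two readings of the
per-network decomposition are supported:

* default: the generator takes the *non-saturating* update (maximize
  $\log D(fake)$), the standard BCE practice — the literal minimax form
  saturates at the start of training;
* `adv_mode = "minimax"`: the literal form, behind a flag.

The reconstruction term is the patch **1-norm** — the sum of absolute
pixel differences, averaged over the batch — exactly as the loss is
written ($\Vert X^{ar} - G(Z, X^{cyto})\Vert_1$). Its gradient therefore
scales with the patch area and dominates the adversarial term, keeping
generated patches content-consistent; with a per-pixel *mean* instead,
the adversarial gradient drowns the reconstruction signal and desk-scale
training does not converge within the epoch budget. `l1Loss()` (the
reported diagnostic) remains the per-pixel mean; `trainStep` logs both.

Optimization: Adam with learning rate 0.001 and betas (0.5, 0.99) — the
0.99 is kept as printed, not the conventional 0.999 — for 250 epochs at
full scale (tests and examples use far fewer), one discriminator step per
generator step, global-norm gradient clipping at 1.0 (the clip norm is
not printed in the source; 1.0 is this package's default), batch size 8
by default. Intensities are mapped to [-1, 1] for training and back to
[0, 1] before any metric. Training is bit-reproducible under a fixed
config seed, and checkpoints restore continued training exactly.

Splits are by *section*: no section contributes patches to both training
and test sets (`makeSplits`), mirroring the published section-level
train/test assignment.

## Evaluation

Four metrics, each with the exact conventions used here:

* **z-MAE** — mean absolute error between z-scored patches, where both
  patches are standardized with the *target's* mean and sd only. A
  degenerate target (zero variance) is excluded and logged rather than
  producing infinities. For independent standard normal pairs the
  expected value is $2/\sqrt{\pi} \approx 1.128$, a Monte-Carlo test
  anchor.
* **PSNR** — $20\log_{10}(\mathrm{MAX}_P/\sqrt{\mathrm{MSE}})$ with
  $\mathrm{MAX}_P = 1$; identical patches give an $+\infty$ sentinel that
  is excluded from means with a logged count.
* **SSIM** — computed *globally* per patch (whole-patch means, variances,
  covariance), not the windowed literature variant, matching the printed
  formula; the cross term is the covariance (the printed label "standard
  deviation" is inconsistent with the standard definition). Constants
  $c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$ with $L = 1$; both choices are
  recorded in the report metadata.
* **FID** — Fréchet distance between Gaussian fits of patch embeddings,
  computed over *sets* of patches (a distributional distance is undefined
  per patch pair). The matrix square root uses a symmetric
  eigendecomposition of $S_1^{1/2} S_2 S_1^{1/2}$ with ridge
  regularization and clipping of round-off negatives. The conventional
  Inception-V3 embedder needs pretrained weights unavailable offline, so
  the packaged embedder (`builtin_cnn`) is a fixed-seed untrained
  three-layer convolutional network with mean+max channel pooling —
  random convolutional features preserve distributional differences well
  enough for relative comparisons, but FID values are **not** numerically
  comparable to Inception-based values reported elsewhere.

`aggregateReport` summarizes per-metric mean, population standard
deviation, and the least favorable patch score (max for MAE, min for PSNR
and SSIM), mirroring worst-case reporting.

## Synthetic study conditions

The generator (`SyntheticSpec`, `generateDataset`) emulates exactly the
features the pipeline relies on:

* a cortical ribbon of thickness 2 mm with a normalized depth coordinate
  (0 at the pial surface, 1 at the grey/white boundary) along a straight,
  sinusoidal or sulcus-shaped midline; the simulated slab fills the whole
  canvas, with white matter below the ribbon and a sparse zone above the
  pia, so offset windows remain inside the section;
* receptor intensity = laminar profile(depth) x smooth multiplicative
  labeling jitter (amplitude 0.1) + Gaussian noise (sd 0.02), clipped to
  [0, 1]. The profiles are quadratic in depth, $a + b\,(2d-1)^2$, chosen
  so the qualitative orderings hold: V1 profiles (both receptors) and M1
  kainate are U-shaped (low mid-depth, high toward both boundaries), M1
  M2 is inverted-U (high in the cortex centre). With noise and jitter
  disabled the render equals the profile exactly — the tests' exactness
  anchor;
* the cyto modality is rendered on a 16x finer grid as a cell-body
  speckle texture: dark dots drawn with probability given by a cell
  density profile (rising toward the grey/white boundary with a mid-depth
  band, a layer-IV analog) plus noise (sd 0.05). The density profile is
  *shared across areas*, so in multi-area datasets the area is not
  recoverable from the cyto patch alone — which is precisely what makes
  the conditional variant testable: only the condition channel can
  resolve the area's laminar pattern;
* a band-limited synthetic deformation (two sinusoidal modes, wavelengths
  at least a canvas length, seed-controlled phases, amplitude default
  2 px) warps the receptor section into its observed "moving" geometry;
  its numerically exact inverse provides the ground-truth correspondence,
  and landmark pairs are exact by construction;
* all randomness flows from the single spec seed through named
  sub-streams; the same seed reproduces a dataset bit for bit.

What the simulator does **not** emulate: real staining histochemistry,
3-D geometry and sectioning artifacts, tissue damage (beyond mask-based
exclusion tests), registration error, or the uncalibrated intensity scale
of real autoradiographs. Tests passing on synthetic data therefore
demonstrate that the pipeline's geometry, losses, optimization and
metrics behave as specified — not that the trained weights transfer to
real tissue.

## Desk-scale problem sizes

The package's own tests exercise the full pipeline at a reduced scale
chosen to keep the complete suite comfortably runnable on a single CPU:
6 x 12 mm canvases at 125 µm receptor resolution (16 px receptor / 256 px
cyto patches, the same 16x gap as the full-scale 128/2048 contract),
~200 training pairs, batch 10, and 10 training epochs for the single-area
recovery check (6 for the conditioning check, whose signal emerges
earlier). Under those conditions the trained single-area generator beats
the constant
per-patch-mean predictor in z-MAE and recovers the laminar depth profile
with Pearson r > 0.8 (averaged over three training seeds), and the
conditional multi-area model steers a fixed cyto input toward the
template of the conditioned area. The full-scale architecture contract
(2048^2 input, 64-channel backbone map at 128^2, 128^2 output) is checked
by a direct forward pass.

## Known limitations

* Training at the published scale (250 epochs, 128^2 patches, thousands
  of pairs) is possible but slow in this CPU implementation; the package
  is designed for methodological fidelity and testability, not
  throughput.
* The discriminator's layer count is given ambiguously in the source
  description (four in the text, five in the figure caption); the default
  is four with `n_layers = 5` available.
* FID values depend on the embedder; only relative comparisons within
  one embedder are meaningful.
* The fixed-point inversion assumes a contractive field; fields with
  displacement gradients near or above one (not produced by the
  simulator) will fail with a reported residual rather than silently
  returning a bad inverse.
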