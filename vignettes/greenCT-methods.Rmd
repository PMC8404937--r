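---
title: "Learned post-processing for sparse-view CT: models, simulation design and numerical choices"
author: "greenCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned post-processing for sparse-view CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Sparse-view CT lowers radiation dose by acquiring far fewer angular
projections than a conventional scan; limited-angle CT additionally
restricts the source trajectory to a partial arc.  Filtered back-projection
(FBP) applied to such subsampled sinograms produces characteristic global
streaking artefacts and, in the limited-angle case, anisotropic shading.
Learned post-processing (LPP) attacks the problem in image space: a
convolutional network is trained on pairs (y, x) of FBP reconstructions and
their ground truths, and at deployment maps a corrupted reconstruction to a
restored image.

Two forward contracts are implemented.  The *direct* map

    x_hat = F_theta(y)

is used by the shallow three-layer single-scale network (3L-SSNet): three
stride-1 convolution blocks (Conv2D + BatchNorm + ReLU on the hidden
layers, a linear final convolution), no pooling, so the network operates at
one scale with a small receptive field.  The *residual* map

    x_hat = y + R_theta(y)

is used by the residual UNet (ResUNet): the subnetwork only has to learn
the artefact component, which for streak-type corruption is an easier
manifold than the image itself.  R_theta is a symmetric encoder-decoder
with levels l = 0..L, n convolutions per level, channel ladder
c_l = c0 * 2^l, 2x2 max pooling, nearest-neighbour upsampling followed by a
3x3 convolution, *additive* skip connections (cheaper than concatenation),
and a tanh output layer, which bounds the learned residual to [-1, 1] per
pixel.  The reference configuration is L = 4, n = 3, c0 = 64.

## Synthetic study design

The package studies these networks entirely on synthetic data, so every
result is reproducible from a seed.  The phantom module provides:

* a **chest-like family** (training domain): a soft-tissue body ellipse,
  two lung cavities, a spine-like insert and a few random bright internal
  features, plus zero-mean Gaussian texture (sd `textureSigma`, default
  0.02) inside the body.  The texture emulates the fact that real
  reconstructed training slices are never noise-free; it is truncated so
  images stay in [0, 1].
* a **flat-sharp family** (out-of-domain): noise-free piecewise-constant
  flat regions containing small high-contrast sharp objects — image
  statistics deliberately unlike the training family.
* the canonical **Shepp-Logan** table, and an anti-aliased centred disk
  whose parallel projections have the closed form 2*sqrt(R^2 - s^2), used
  as the analytic oracle for projector and FBP tests.

Ellipse intensities are designed so composed images lie in [0, 1]; if a
custom specification overflows that range the image is rescaled affinely
and a message records the fact (never a silent clip).

What the generator does **not** emulate: anatomical detail and organ
topology, beam hardening, scatter, detector physics, and the
reconstruction-induced noise correlation of real full-dose reference
images.  Tests passing on this family therefore demonstrate correctness of
the pipeline and the *direction* of the learned-post-processing effect, not
clinical performance.

## Acquisition protocols and projector numerics

Two presets reproduce the studied protocols: **full-range** (360 views,
1-degree spacing over [0, 360)) and **half-range** (180 views over
[0, 180), limited angle).  In parallel geometry these two carry the same
information (opposite rays coincide), so the paired-data simulations use a
fan beam with a flat virtual detector through the rotation axis
(source-axis and axis-detector distances both default to twice the image
side, detector pitch 1 pixel, detector count ceiling(sqrt(2) * side)
rounded to even).  Parallel geometry remains available and is used by the
analytic unit tests.

Forward projection uses Joseph's method: stepping one pixel along the
ray's major axis with linear interpolation along the minor axis.  It is
exactly linear in the image, preserves total mass across views to < 1%,
and matches disk chord lengths to < 2 pixel-lengths.

Measurement noise is white Gaussian, parameterised by the *relative L2
level*: e = level * (||b||_2 / sqrt(m)) * xi with xi standard normal over
all m sinogram entries, so the expected relative perturbation equals
`level`.  The training level is 1e-2; the unseen-noise scenario doubles it.

FBP filters each detector row with a frequency-domain windowed ramp |f|
(ram-lak default, hann and cosine available, cutoff as a fraction of
Nyquist).  Constructing the ramp directly in the frequency domain makes the
DC gain exactly zero.  Back-projection is pixel-driven with linear
detector interpolation; fan data are cosine pre-weighted and distance
weighted (inverse square).  The angular scaling is delta-theta, halved for
trajectories covering the full circle.  Half-range fan data are
reconstructed with plain weighting and no short-scan compensation: the
resulting limited-angle artefacts are the object of study, not a defect.
On a 128 px anti-aliased disk, 180-view noiseless parallel FBP reaches
relative error 0.044, and error decreases monotonically along the view
ladder 30/60/120/180.

## The convolution engine and training

No deep-learning framework is attached: the networks run on the package's
own single-precision engine (im2col + BLAS sgemm per image, with a direct
cache-friendly path for narrow final projections; batch normalisation over
batch + spatial positions with running statistics at momentum 0.1; max-pool
argmax routing and nearest-neighbour upsampling adjoints).  The backward
pass is validated against central finite differences (agreement improves as
the step shrinks, confirming truncation-limited error).  Single precision
is the standard arithmetic for CNN training; metrics are computed in double
precision.

Training minimises the empirical mean over the dataset of the per-image
summed squared error (the per-image *sum*, not the mean; the learning rate
absorbs the scale).  Optimisers: Adam (beta 0.9/0.999) for the shallow
network, SGD with Nesterov momentum 0.99 for the ResUNet; learning rate
decays polynomially (exponent p = 1 by default, the simplest choice
compatible with fixed endpoints); batch size 8; gradients clipped at
global L2 norm 5.  The reference schedule (`paperTrainConfig()`) runs 50
epochs from 1e-2 down to 1e-5.

The desk-scale presets (`deskTrainConfig()`) run 15 epochs.  The ResUNet
keeps the reference optimiser settings unchanged.  For the shallow
network's direct map the reference endpoints belong to a ~20k-step
schedule; compressed into ~375 desk steps they spend the first epochs
recovering from an aggressive start and stall the last ones at a vanishing
rate while the loss is still falling steeply.  The desk preset therefore
starts at 3e-3 and decays to 1e-4 — chosen once from the training-loss
trajectory at the desk scale and kept; batch size, clipping, optimiser
family and the polynomial decay form are the reference ones.

Two initialisation choices matter at desk scale.  Hidden convolutions use
He-normal initialisation.  In residual mode the final convolution starts at
exactly zero, so the initial network is the identity and training improves
on the FBP input from the first step instead of first unlearning a large
random residual — the standard zero-init trick for residual restoration
networks.  This also realises the residual contract exactly: with a zeroed
head, the forward map returns its input bit-for-bit (at single precision).

### Desk-scale protocol

The desk-scale study trains each network **once** on a 200-pair mixed
dataset (100 chest phantoms at 128 x 128, each simulated under both the
full-range and the half-range protocol at noise 1e-2) for 15 epochs, and
evaluates per protocol on 10 held-out phantoms.  A single model serving
both acquisition protocols is in keeping with the efficiency theme and
halves the training compute relative to per-protocol models; the direction
claim (trained networks beat their FBP inputs on RE and SSIM under both
protocols) is evaluated per protocol regardless.  The ResUNet runs at
reduced width c0 = 16 for the desk suite; the 3L-SSNet at full width.

## Receptive-field calculus

`receptiveField()` implements the layer-wise recursion r_0 = 1,
r_t = r_{t-1} + A_t with non-overlap increment
A_t = (k_t - 1) * prod(s_1..s_{t-1}): the tap spacing of layer t is the
stride accumulated *before* it.  A variant of this recursion circulates in
which the product includes the current layer's stride; for strided or
pooled layers that variant exceeds the receptive field actually measurable
on the network (conv3/pool2/conv3: 9 versus the measured 8).  The package
therefore ships a brute-force oracle, `empiricalRF()`, which instantiates
the stack with all-ones kernels, zero biases and bypassed normalisation and
scans single-pixel impulses across the centre row and column; the analytic
and empirical values agree on every stack tested (randomized conv/pool
suites are part of the acceptance tests).  For stride-1 stacks the two
recursions coincide: the shallow network's receptive field is 15 x 15
either way (0.086% of a 512 px input), which is the headline contrast with
the UNet.

For the ResUNet, the encoder chain to the bottleneck gives a receptive
field of 202 px at the reference configuration (15.6% of a 512 px input).
A published figure of 172 x 172 (11.28%) for this configuration is not
reconstructible from the recursion under either product convention; the
package reports the computed value.

## Cost accounting

`countParameters()` counts k^2 * c_in * c_out kernel weights per
convolution (headline figure), plus biases and batch-norm affine terms in
the trainable total.  `countFlops()` counts 2 operations per
multiply-accumulate, convolution layers only, at the layer's running
spatial size — for any stride-1 pool-free network this collapses to
2 * pixels * weights, a closed form the tests cross-check.  Under this
convention the table-consistent 3L-SSNet has 85,696 weights and 4.49e10
FLOPs at 512 px.

The published textual description of the shallow network (kernels 9/5/3 at
constant 128 channels) is inconsistent with its published cost figures
(85e3 parameters, 44e9 FLOPs): the text implies 421,120 weights.  Kernels
9/3/5 with channels 128 -> 64 -> 1 reproduce the cost figures to within 1%
(parameters) and 3% (FLOPs), so both variants are shipped
(`build3LSSNet("table-consistent")`, the default, and `"as-text"`).  The
corresponding ResUNet figure (34.5e6 parameters) is likewise not
reconstructible because the decoder layout is underdetermined; the
spec-compliant symmetric decoder built here has ~47e6 weights at c0 = 64.

## Metrics

* **RE**: ||x - gt||_2 / ||gt||_2, the unsquared norm ratio (a squared
  variant is available by flag; the unsquared ratio is the conventional
  relative error and matches the scale of published FBP values).
* **PSNR**: both conventions are always reported, because published tables
  print two numbers whose relationship is not reconstructible:
  `psnrPaper` = 20 log10(n * max(gt) / ||x - gt||_2) with n the pixel
  count, and the standard `psnrStd` = 20 log10(max(gt) / RMSE).  They
  differ by exactly 10 log10(n).
* **SSIM**: mean local SSIM, 11 x 11 Gaussian window (sd 1.5), K1 = 0.01,
  K2 = 0.03, valid-interior averaging; numerically identical (1e-7) to the
  scikit-image reference configuration on fixtures.
* **FSIM**: phase congruency from a log-Gabor bank (4 scales x 4
  orientations, smallest wavelength 6, multiplier 2, sigmaOnf 0.55) and
  Scharr gradient magnitude, combined with T1 = 0.85 and T2 = 160 on a
  0-255 range and averaged with the pointwise maximum phase congruency as
  weight.  The phase-congruency map omits the noise-threshold compensation
  of some reference implementations; the identity, boundedness and
  blur-monotonicity properties are unaffected and are what the evaluation
  relies on.
* The metric dynamic range is taken from the ground truth
  (max(gt) - min(gt)); network outputs are evaluated in their own range.

## Out-of-domain protocol

`runOOD()` evaluates a trained model under a scenario that departs from the
training distribution in exactly one axis: **unseen-noise** doubles the
sinogram noise to 2e-2 while keeping the chest family; **unseen-image**
keeps the training noise 1e-2 but switches to the flat-sharp family.  The
report always contains the paired in-domain evaluation, so the robustness
gap is a computed quantity (per-method RE and SSIM deltas); no direction is
asserted about which network is more robust — that is an empirical finding,
not a contract.  The degenerate scenario (unseen-noise at the training
level) must and does match the in-domain evaluation within stochastic
tolerance.

## Problem sizes

The default test-suite sizes are the package's desk-scale choices: 128 px
images, 200 mixed training pairs, 15 epochs, 10 evaluation phantoms per
protocol for the training-efficacy check; 64 px and a 40-pair quick-trained
model for the out-of-domain protocol; 32-96 px for analytic unit tests.
512 px paper-emulation geometry presets are available throughout
(`makeGeometry(..., 512)`, `countFlops(net, 512)`, `paperTrainConfig()`).

## Known limitations

* The projector/FBP pair is self-consistent and oracle-checked, but no
  attempt is made to match any external toolbox's scaling conventions
  bit-for-bit.
* Batch-norm statistics are per-channel over batch + spatial positions;
  with very few optimisation steps the running statistics lag the batch
  ones, which slightly penalises evaluation of briefly trained models.
* The engine is single-threaded by design (deterministic given seeds);
  there is no GPU path.
* Fan-beam short-scan (Parker) weighting is intentionally absent; the
  half-range preset is *meant* to produce limited-angle artefacts.
* FSIM omits noise-threshold compensation (above); absolute FSIM values
  can differ slightly from other implementations while orderings agree.
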