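---
title: "Simulating and decoding cortical VSD responses to retinal neuromorphic microstimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding cortical VSD responses to retinal neuromorphic microstimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Intracortical microstimulation (ICMS) for visual prostheses conventionally
delivers fixed-frequency pulse trains that switch electrodes on or off,
reducing an image to binary edge cues. An alternative is to pattern the
pulse timing after retinal ganglion-cell spike trains, so that image
information is carried in millisecond-scale temporal structure. Whether a
cortical population response to such stimulation still contains recoverable
image information is an empirical question, but answering it requires
datasets — matched images, spike trains and cortical responses — that do not
yet exist at scale.

`vsdecode` implements the complete simulation loop used to address this
question computationally:

1. a **retinomorphic spike encoder** turns a grayscale image into spike
   trains of a 120 x 120 grid of off-transient alpha retinal ganglion cell
   models;
2. a **Wiener system** — the kind of model identifiable from voltage-
   sensitive dye (VSD) recordings of cortical slices — turns each pixel's
   pulse train into a simulated cortical VSD response (fractional
   transmittance change dT/T0 at 1 ms resolution);
3. two **3-D convolutional decoders** reconstruct the image, either
   directly from the binned spike stream (Path 1) or from the simulated
   VSD stream through a VSD-to-spike front end and a spike-to-image back
   end (Path 2);
4. an **evaluation suite** (SSIM distributions, radially averaged power,
   orientational power, phase-difference-vs-frequency profiles) and a
   **fixed-frequency stimulation baseline** with pulse-budget matching
   complete the loop.

# The retinomorphic encoder

A stimulus stream — a full-field gray adaptation field followed by the test
image — is processed per grid unit by

* a *delayed difference of Gaussians*: `g(t) = Gc * I(t) - Gs * I(t - d)`,
  center sigma 1.2 px, surround sigma 3.0 px, surround delay `d` = 5 ms,
  both filters normalized to unit DC gain so a uniform field produces no
  drive. The sign is inverted for off polarity, so luminance *decrements*
  excite.
* a zero-sum *biphasic temporal kernel*, the difference of two alpha
  functions with time constants 10 ms and 40 ms, discretely renormalized so
  its samples sum exactly to zero (sustained input produces no sustained
  drive) and scaled to unit peak;
* an *Izhikevich neuron* (forward Euler at 0.5 ms; regular-spiking
  parameters a = 0.02, b = 0.2, c = -65, d = 8, peak 30 mV) driven by the
  filtered signal times a gain.

Parameter values for the DoG, the biphasic kernel and the neuron are not
published alongside the framework this package implements; they live in the
hardware-oriented companion work. The defaults above are behavior-level
choices: they produce the defining off-transient response (a transient
burst at image onset over ~150 ms, then silence). The gain default (40) was
calibrated once so that a mixture-style synthetic image drives 2-10
spikes/unit in 150 ms on the full grid (measured ~4.4), inside the band the
encoder is meant to occupy; all values are exposed in `encoder_config()`.

Spike events are binned into half-open 5 ms windows; multiple spikes in one
bin saturate to 1, so the resulting spike stream is binary and can serve as
a binary-cross-entropy target. 150 ms of recording yields the 30-frame
spike stream; the adaptation period (200 ms by default) is long enough for
the biphasic filter to settle.

# The Wiener system

The cortical stage is a per-pixel Wiener cascade

    y(t) = f( k * (L_gamma * s)(t) )

with `s` the pulse train rendered as unit impulses on a 1 ms grid,
`L_gamma(t) = 1 / (1 + (t/gamma)^2)` a Lorentzian broadening with
gamma = 0.25 ms (peak 1, not renormalized; its continuous-time FWHM is
2 gamma), `k` a causal linear filter, and `f` a modified-Softplus static
gain

    f(x) = log(1 + exp(beta * z)) / beta,
    z = p1 / (1 + exp(-p2 (x - p3))) + p4 exp(p5 x) + p6,

evaluated with an exact linear asymptote for large `beta * z`. Pixels are
strictly independent; 1000 ms of simulated response per pixel is block-mean
downsampled to the 200-frame VSD stream.

The package's default generative model (`default_wiener_model()`) uses an
alpha-function filter (rise time constant 30 ms, 300 ms support) — a fast
rise and slow decay typical of pulse-evoked VSD responses near a
stimulation site — and a saturating sigmoid gain reaching about 2 % dT/T0,
the order of magnitude of absorption-dye fractional signals. These are the
package's stand-ins for the experimentally derived functions, which cannot
be reproduced without the physiological recordings; they are chosen once
and are not tuned per experiment.

## Identification

Both identification steps operate on (pulse train, measured trace) segment
lists at 1 ms:

* `estimate_linear_filter()` computes the cross-**covariance** between the
  Lorentzian-broadened train `w = L_gamma * s` and the trace at causal lags,
  normalized by `sum((w - mean w)^2)`. Centering is the standard
  white-noise estimator and matters in practice: without it the response
  baseline `f(0)` leaks a constant into every lag of `k`. Physiological
  traces are typically baseline-subtracted (no-stimulation trials), so the
  centered estimator is also what such data implicitly assume. Acausal lags
  are discarded.
* `fit_static_nonlinearity()` fits `(beta, p1..p6)` to the (linear
  prediction, measured) cloud by Levenberg-Marquardt from at least eight
  seeded starts spanning sharp/soft rectification and shallow/steep sigmoid
  regimes. The individual parameters are not identifiable (several
  parameter vectors produce the same curve); the fitted *curve* is the
  contract, and tests assert curve recovery, not parameter recovery.

On synthetic data mimicking the experimental protocol (16 segments of
1.4 s, sparse ~10 Hz trains), re-simulated held-out traces correlate with
truth at r > 0.99. This desk-scale round trip is the package's surrogate
for the physiological fit quality reported for this model class; the
physiological values themselves require the original recordings and are out
of scope.

# The decoders

`build_backend()` (Path 1, and the Path-2 back end) maps a spike stream to
one frame: conv(30 x 3 x 3) x 4, conv(30 x 3 x 3) x 4, avgpool(2 x 1 x 1),
conv(15 x 3 x 3) x 8, avgpool(3 x 1 x 1), conv(5 x 3 x 3) x 16,
avgpool(5 x 1 x 1), conv(1 x 3 x 3) x 1. All convolutions use "same"
spatial padding and carry biases; the temporal pooling chain 2 x 3 x 5
collapses 30 frames to 1. Per-layer trainable parameters: 1084, 4324, 4328,
5776, 145.

`build_frontend()` (Path-2 front end) maps a VSD stream to per-voxel spike
probabilities of the same shape: four conv + batch-norm stages (temporal
kernels 7, 5, 5, 3; channels 16, 32, 16, 32) and a 1 x 1 x 1 output
convolution. The published parameter counts fix the bias convention:
1008 = 7*3*3*16 means convolutions followed by batch norm carry **no**
bias, and 33 = 32 + 1 means the terminal convolution does. Per-layer
counts: 1008, 32, 23040, 64, 23040, 32, 13824, 64, 33. `layer_audit()`
recomputes every count in closed form and doubles as a portable JSON
export.

Design choices the architecture tables leave open, fixed here: hidden
activations are ReLU; both output heads are sigmoids (spike probabilities,
images in [0, 1]); the networks emit logits internally and losses are
computed on logits for numerical stability.

## The temporal bridge

The front end emits as many frames as the VSD stream (200 at full scale);
the back end consumes the spike-stream frame count (30). How the published
architecture bridges this gap is not described. The package crops the front
end's output to its first 30 frames (0-150 ms): all spikes live in that
window — the encoder's off-transient response dies out within it — so the
crop discards only frames whose spike target is identically zero. The crop
is a structural layer of the assembled network and gradients flow through
it during refinement.

## Training protocol

All stages use Adam with batch size 2. Pretraining (learning rate 1e-4):
the front end minimizes per-voxel BCE against spike streams zero-padded to
the VSD frame count, early-stopped on held-out F1 at threshold 0.5; the
back end minimizes 1 - SSIM against the prefiltered target images,
early-stopped on held-out SSIM. The assembled Path-2 network is then
refined for three rounds of (front trainable / back frozen, then back
trainable / front frozen) under the end-to-end 1 - SSIM loss at learning
rate 0.5e-4 — the "1e-4 or 0.5e-4" choice is disambiguated as
coarse-then-fine. Frozen blocks run in inference mode (running batch-norm
statistics) and their parameters are checked bit-identical across their
frozen phase by digest. Early stopping uses patience 10 and minimum
improvement 1e-4 by default, with the best-metric parameters restored.

SSIM follows the reference formulation: 11 x 11 Gaussian window with sigma
1.5, K1 = 0.01, K2 = 0.03, dynamic range 1, averaged over window positions
fully inside the image. The 1 - SSIM training loss uses the analytic SSIM
gradient (validated against finite differences in the test suite). A
single-window "global" mode exposes the closed-form statistic for
hand-checked cases.

# Synthetic images

The photographs used by the original full-scale experiment are stock media
that cannot be redistributed or downloaded at test time, so
`generate_image()` provides seeded procedural stand-ins: `pink_noise`
(broadband texture with a configurable power-spectrum slope, default -2 as
for natural scenes), `blobs` (smooth Gaussian bumps), `shapes` (hard-edged
rectangles and discs), and the default `mixture` overlaying all three —
preserving the two properties the pipeline actually exercises, broadband
spectra and contrast edges. `photoreceptor_prefilter()` applies the
photoreceptor-layer Gaussian blur (sigma 1 px by default; the source
framework does not state a value) with unit DC gain, reflect boundary and
clipping to [0, 1]. Reflect boundaries are used for all spatial filtering
in the package. What the generator does **not** emulate — scene semantics,
occlusions, perspective, photometric nonlinearities — bounds what passing
tests show: they validate the machinery end to end, not perceptual
generalization to photographs.

# Scaled-down study conditions

The full-scale configuration (120 x 120 grid, 400 triplets split 320/80,
30-frame spikes, 200-frame VSD) reproduces the published dimensions and is
the `"paper"` preset. Training it end to end is a GPU-scale undertaking;
the package validates the complete protocol on the `"desk"` preset, chosen
once as: 32 x 32 grid, 50 triplets split 40/10 (8 of the 40 held out for
early stopping), 60 ms spike window (12 frames, pooling chain 2 x 3 x 2),
300 ms simulated responses (60 frames, cropped to 12 at the bridge),
front-end channels 4/8/4/8 instead of 16/32/16/32, back-end channels as
published. Every structural element — two full-temporal convolutions before
pooling, pool-to-one chain, conv/BN bias convention, the two-stage plus
three-round protocol — is preserved; only sizes shrink. On this preset the
full pipeline (dataset, both pretrainings, refinement, evaluation) runs in
minutes on one CPU core; `scripts/acceptance.R` re-runs it from scratch.

Published full-scale SSIM levels depend on the authors' photograph set and
GPU-scale training and are orientation only; the desk-scale contract is
relative: both paths must beat the permuted-pair SSIM baseline by a wide
margin, refinement must not degrade validation SSIM across rounds, and the
phase-difference profile must grow with spatial frequency.

# Fixed-frequency baseline

The comparison strategy mirrors clinical fixed stimulation: 300 Hz for
166 ms (= 50 pulses, first pulse at t = 0), delivered in an all-or-none
fashion at selected pixels. Edges are extracted with the 4-neighbor
Laplacian (reflect boundary, absolute value); pixels are selected top-k by
edge strength so that `k * 50` matches the image's neuromorphic spike count
— top-k selection rather than a scalar threshold because the budget match
is the binding constraint and a fixed threshold cannot guarantee it. Ties
break in row-major order; the budget is matched per image. The selected
pixels all receive the identical train, are simulated through the same
Wiener model, downsampled identically, and decoded by the same Path-2
network, so any difference in the decoded image is attributable to the
stimulation strategy.

# Numerical and engineering notes

* **The 3-D CNN engine is part of the package**: blocked im2col + BLAS
  convolutions (Rcpp/RcppArmadillo) with "same" padding (even temporal
  kernels pad one more sample at the trailing edge), channelwise batch
  norm pooling statistics across the mini-batch, temporal average pooling,
  Adam, and both loss heads with analytic gradients. Every gradient path
  is finite-difference-checked in the tests.
* Spike times are assigned to the start of the Euler step in which the
  membrane crossed threshold; binning is half-open, `[k b, (k+1) b)`.
* Upsampled pulses sit at bin onsets (`t = 5k` ms), consistent with
  half-open binning, so `bin(upsample(S)) = S` exactly.
* VSD downsampling is a block mean (not decimation), preserving the energy
  of the slow dynamics.
* The orientational power distribution counts only frequencies inside the
  Nyquist disc (radial frequency <= 0.5 cycles/pixel): the square spectrum's
  corners sample orientations unevenly and would bias diagonal sectors.
  Phase-difference profiles weight each bin's phases by the original
  image's power, since phases at near-zero power are noise.
* All randomness funnels through one global seed fanned out per stage and
  per item by a deterministic 32-bit hash (`derive_seed()`), so any stage
  can be reproduced in isolation; generated seeds stay below 2^31.
* Datasets persist as native R serialization plus a JSON manifest carrying
  sizes, seed, split membership and configuration digests; regeneration
  from the manifest is bit-identical.

# Limitations

The Wiener stage is strictly per-pixel: no lateral cortical coupling,
recurrence or feedback, so decoding results bound what a linear-nonlinear
cortex would transmit, not what a real network does. The generative model's
filter and gain are plausible stand-ins, not fitted physiology. Training at
the published full scale is supported by the code (the `"paper"` preset
builds the exact architectures) but not demonstrated here on CPU. Synthetic
images are not photographs; SSIM against them measures topological
decodability of the encoding, not perceptual fidelity.
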