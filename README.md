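# vsdecode

Simulation and decoding of cortical voltage-sensitive dye (VSD) responses
to retinal neuromorphic intracortical microstimulation (ICMS).

## What this is for

Cortical visual prostheses conventionally stimulate with fixed-frequency
pulse trains, which reduces an image to binary on/off edge cues at the
electrode sites. An alternative encodes the image in the *timing* of the
pulses, patterned after retinal ganglion-cell spike trains. Whether
cortical population responses to such stimulation still carry recoverable
image information can be studied computationally before the physiology
exists at scale — provided one can simulate the whole loop. `vsdecode`
implements that loop for researchers working on stimulation strategy
design and VSD-based readout:

1. **Retinomorphic encoder** — images to spike trains of off-transient
   alpha retinal ganglion cell models on a 120 x 120 grid: delayed
   difference-of-Gaussians spatial filtering, zero-sum biphasic temporal
   filtering, Izhikevich spike generation (0.5 ms steps), half-open 5 ms
   binning to a binary 30-frame spike stream.
2. **Wiener system** — per pixel, `y(t) = f(k * (L_g * s)(t))`: pulses
   broadened by a Lorentzian `L_g(t) = 1/(1 + (t/g)^2)` (g = 0.25 ms),
   convolved with a causal filter `k`, passed through a modified-Softplus
   gain `f(x) = log(1 + exp(b z))/b` with
   `z = p1 sigmoid(p2 (x - p3)) + p4 exp(p5 x) + p6`. Also the two
   identification steps: `k` by centered cross-covariance against the
   broadened train, `(b, p)` by multi-start least squares.
3. **3-D CNN decoders** — Path 1 decodes images from spikes; Path 2 chains
   a VSD-to-spike front end into the same back end. Architectures with
   published per-layer parameter counts (1008...33 front end,
   1084...145 back end), BCE and 1 - SSIM training with Adam, early
   stopping on F1/SSIM, and three alternating-refinement rounds with
   frozen-block digests. The engine (im2col/BLAS conv3d, batch norm,
   analytic loss gradients) is part of the package.
4. **Evaluation & baseline** — SSIM summaries, radial and orientational
   power spectra, phase-difference-vs-frequency profiles; a fixed 300 Hz /
   166 ms (50-pulse) stimulation baseline with per-image pulse-budget
   matching via top-k Laplacian edge selection.

## Worked example

```r
library(vsdecode)

## a synthetic natural-like image through the photoreceptor prefilter
img <- generate_image(image_style("mixture", seed = 1), 120, 120)
img <- photoreceptor_prefilter(img, 1.0)

## retinal encoding at full scale
cfg <- encoder_config()
spikes <- bin_spikes(encode_stream(img, cfg), bin_ms = 5, record_ms = 150)
spikes
#> <spike_stream 30 frames x 120 x 120, 43824 spikes, bin 5 ms>

## the full triplet: image, spikes, simulated cortical VSD stream
tr <- build_triplet(img, cfg, default_wiener_model())
tr$vsd
#> <vsd_stream 200 frames x 120 x 120, frame 5 ms, range [0.00845, 0.02127]>
```

The spike stream is the binary 30-frame stimulus pattern (43824 spikes is
about 3 spikes per unit in 150 ms — the transient off-response to image
onset). The VSD stream is the per-pixel simulated cortical response in
fractional transmittance change: baseline f(0) = 0.845 % for silent pixels,
up to ~2.1 % where spike bursts drive the saturating gain.

The decoder architectures audit themselves in closed form:

```r
a <- layer_audit(build_backend())
a[a$op == "conv3d", c("layer", "kernel", "out_t", "out_c", "params")]
#>  layer           kernel out_t out_c params
#>      1 (30 x 3 x 3) x 4    30     4   1084
#>      3 (30 x 3 x 3) x 4    30     4   4324
#>      6 (15 x 3 x 3) x 8    15     8   4328
#>      9 (5 x 3 x 3) x 16     5    16   5776
#>     12  (1 x 3 x 3) x 1     1     1    145
```

End-to-end training at desk scale (32 x 32 grid, 50 triplets) runs in
minutes on one CPU core:

```r
cfg <- preset_config("desk", seed = 1)
res <- run_pipeline(cfg, out_dir = "run")   # dataset -> train -> evaluate -> baseline
res$report_path2$ssim$summary                # per-split SSIM mean/sd/n
```

A thin CLI over the same functions ships at `inst/cli/vsdecode.R`
(subcommands `genimg`, `encode`, `simulate`, `identify`, `make-dataset`,
`train`, `decode`, `evaluate`, `baseline`, `run`).

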