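## Shared fixtures, all generated in code at test time.

## small encoder grid for fast unit tests
tiny_encoder <- function(grid = c(16L, 16L), ...) {
  encoder_config(grid = grid, ...)
}

## a small prefiltered natural-like image on the tiny grid
tiny_image <- function(seed = 1L, n = 16L) {
  photoreceptor_prefilter(generate_image(image_style("mixture", seed = seed), n, n))
}

## sparse random pulse-train segments (about `rate_hz`) plus traces from a
## ground-truth model; used by identification tests
make_segments <- function(n_seg, duration_ms = 1400, rate_hz = 10, seed = 1L,
                          model = default_wiener_model()) {
  segs <- lapply(seq_len(n_seg), function(i) {
    s <- derive_seed(seed, "segment", i)
    set.seed(s)
    n <- stats::rpois(1, rate_hz * duration_ms / 1000)
    n <- max(n, 2L)
    pulse_train(sort(sample.int(duration_ms, n) - 1), duration_ms)
  })
  traces <- lapply(segs, simulate_vsd_trace, model = model)
  list(pulses = segs, traces = traces, model = model)
}

## brute-force causal convolution oracle: out[t] = sum_j k[j] x[t-j+1]
conv_causal_oracle <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_len(min(t, length(k))))
      out[t] <- out[t] + k[j] * x[t - j + 1]
  out
}
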