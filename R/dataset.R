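#' Upsample a binned spike stream to per-pixel pulse trains
#'
#' Each set 5 ms frame `k` (1-based frame `k+1`) becomes one pulse at the
#' bin onset `t = k * bin_ms`, on the 1 ms grid of the Wiener model.
#'
#' @param spikes A `spike_stream` (binary array, frames x rows x cols).
#' @param duration_ms Window of the resulting trains (default 1000 ms, the
#'   simulated-response duration).
#' @return List of [pulse_train()]s, one per pixel in column-major (row
#'   fastest) order.
#' @export
upsample_spike_frames <- function(spikes, duration_ms = 1000) {
  arr <- unclass(spikes)
  if (!all(arr %in% c(0, 1))) stop("upsample_spike_frames: stream is not binary")
  bin <- attr(spikes, "bin_ms") %||% 5
  d <- dim(arr)
  flat <- matrix(arr, d[1])           # frames x pixels
  lapply(seq_len(ncol(flat)), function(j) {
    pulse_train((which(flat[, j] > 0) - 1) * bin, duration_ms = duration_ms)
  })
}

## internal: binary pixel-train matrix (time at 1 ms x pixels)
spike_stream_to_impulse_matrix <- function(spikes, duration_ms = 1000, dt_ms = 1) {
  arr <- unclass(spikes)
  bin <- attr(spikes, "bin_ms") %||% 5
  d <- dim(arr)
  n <- as.integer(round(duration_ms / dt_ms))
  flat <- matrix(arr, d[1])
  out <- matrix(0, n, ncol(flat))
  rows <- as.integer(round((seq_len(d[1]) - 1) * bin / dt_ms)) + 1L
  out[rows, ] <- flat
  out
}

#' Downsample a VSD trace from 1 ms to frame resolution
#'
#' Block mean over consecutive `factor`-sample windows (5 ms frames by
#' default), preserving the energy of the slow VSD dynamics.
#'
#' @param trace Numeric vector at 1 ms, or matrix (time x pixels); length
#'   must be divisible by `factor`.
#' @param factor Samples per frame (default 5).
#' @return Vector or matrix of frame means.
#' @export
downsample_vsd <- function(trace, factor = 5) {
  v <- if (is.matrix(trace)) trace else matrix(as.numeric(trace), ncol = 1)
  if (nrow(v) %% factor != 0)
    stop("downsample_vsd: length not divisible by the downsampling factor")
  nf <- nrow(v) %/% factor
  ## mean of each block: reshape (factor, nf * ncol) and column-average
  out <- matrix(colMeans(matrix(v, nrow = factor)), nf, ncol(v))
  if (is.matrix(trace)) out else as.numeric(out)
}

#' Build one (image, spikes, VSD) triplet
#'
#' Deterministic composition: retinal encoding, 5 ms binning, per-pixel
#' upsampling to 1 ms, Wiener-system simulation for `sim_duration_ms`, and
#' block-mean downsampling back to 5 ms frames. Pixels are strictly
#' independent in the cortical stage.
#'
#' @param image A [gray_image()] on the encoder grid (already prefiltered).
#' @param encoder_cfg An [encoder_config()].
#' @param model A [wiener_model()].
#' @param record_ms Spike recording window (default 150 ms -> 30 frames).
#' @param sim_duration_ms Simulated-response duration (default 1000 ms ->
#'   200 frames).
#' @param bin_ms Frame duration (default 5 ms).
#' @return A `triplet` list: `image` ([gray_image()]), `spikes`
#'   (`spike_stream`, `record_ms/bin_ms` frames), `vsd` (`vsd_stream` array
#'   `(n_frames, rows, cols)` with attribute `frame_ms`).
#' @export
build_triplet <- function(image, encoder_cfg, model, record_ms = 150,
                          sim_duration_ms = 1000, bin_ms = 5) {
  ev <- encode_stream(image, encoder_cfg, record_ms = record_ms)
  spikes <- bin_spikes(ev, bin_ms = bin_ms, record_ms = record_ms)
  smat <- spike_stream_to_impulse_matrix(spikes, duration_ms = sim_duration_ms,
                                         dt_ms = model$dt_ms)
  traces <- simulate_vsd_matrix(smat, model)
  frames <- downsample_vsd(traces, factor = as.integer(round(bin_ms / model$dt_ms)))
  vsd <- array(frames, c(nrow(frames), dim(spikes)[2], dim(spikes)[3]))
  vsd <- structure(vsd, class = "vsd_stream", frame_ms = bin_ms)
  structure(list(image = image, spikes = spikes, vsd = vsd), class = "triplet")
}

#' @export
print.vsd_stream <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vsd_stream %d frames x %d x %d, frame %g ms, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], attr(x, "frame_ms"), min(x), max(x)))
  invisible(x)
}

#' Generate a matched dataset of triplets
#'
#' Generates `n` synthetic images (per-index seeds derived from the global
#' seed), applies the photoreceptor prefilter, builds the triplets, and
#' splits them into training and testing sets by a seeded shuffle. The
#' returned manifest records sizes, seed and configuration digests, from
#' which the dataset can be regenerated bit-identically.
#'
#' @param n Number of triplets (the full-scale configuration uses 400).
#' @param split `(n_train, n_test)`; must sum to `n` (full scale: 320/80).
#' @param seed Global seed.
#' @param encoder_cfg An [encoder_config()].
#' @param model A [wiener_model()].
#' @param style Base [image_style()]; its seed field is re-derived per index.
#' @param prefilter_sigma Photoreceptor prefilter sigma in pixels.
#' @param record_ms,sim_duration_ms,bin_ms Timing as in [build_triplet()].
#' @param dir Optional directory: triplets and manifest are written there
#'   (RDS + JSON manifest) in addition to being returned.
#' @param progress Print progress every 10 triplets.
#' @return A `vsd_dataset` list: `train`, `test` (lists of triplets),
#'   `manifest`.
#' @export
make_dataset <- function(n = 400L, split = c(320L, 80L), seed = 1L,
                         encoder_cfg = encoder_config(),
                         model = default_wiener_model(),
                         style = image_style("mixture"),
                         prefilter_sigma = 1.0,
                         record_ms = 150, sim_duration_ms = 1000, bin_ms = 5,
                         dir = NULL, progress = FALSE) {
  n <- as.integer(n); split <- as.integer(split)
  if (length(split) != 2 || sum(split) != n || any(split < 0))
    stop("make_dataset: split must be (n_train, n_test) summing to n")
  grid <- encoder_cfg$grid
  triplets <- vector("list", n)
  for (i in seq_len(n)) {
    st <- style; st$seed <- derive_seed(seed, "image", i)
    img <- generate_image(st, grid[1], grid[2])
    img <- photoreceptor_prefilter(img, prefilter_sigma)
    triplets[[i]] <- build_triplet(img, encoder_cfg, model,
                                   record_ms = record_ms,
                                   sim_duration_ms = sim_duration_ms,
                                   bin_ms = bin_ms)
    if (progress && i %% 10 == 0) message("triplet ", i, "/", n)
  }
  perm <- with_seed(derive_seed(seed, "split"), sample.int(n))
  train_idx <- sort(perm[seq_len(split[1])])
  test_idx <- sort(setdiff(seq_len(n), train_idx))
  manifest <- list(n_total = n, n_train = split[1], n_test = split[2],
                   seed = as.integer(seed),
                   train_idx = train_idx, test_idx = test_idx,
                   encoder_digest = config_digest(unclass(encoder_cfg)),
                   model_digest = config_digest(unclass(model)),
                   style = style$kind, prefilter_sigma = prefilter_sigma,
                   record_ms = record_ms, sim_duration_ms = sim_duration_ms,
                   bin_ms = bin_ms, grid = grid)
  ds <- structure(list(train = triplets[train_idx], test = triplets[test_idx],
                       manifest = manifest), class = "vsd_dataset")
  if (!is.null(dir)) save_dataset(ds, dir)
  ds
}

#' Persist / load a dataset container
#'
#' Triplets are stored with R's native serialization next to a plain-JSON
#' manifest carrying the split and configuration digests.
#'
#' @param ds A `vsd_dataset`.
#' @param dir Directory (created if needed).
#' @return `save_dataset`: `dir` invisibly; `load_dataset`: the dataset.
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ds$train, file.path(dir, "train.rds"))
  saveRDS(ds$test, file.path(dir, "test.rds"))
  jsonlite::write_json(ds$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  structure(list(train = readRDS(file.path(dir, "train.rds")),
                 test = readRDS(file.path(dir, "test.rds")),
                 manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                                simplifyVector = TRUE)),
            class = "vsd_dataset")
}

#' @export
print.vsd_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<vsd_dataset %d triplets (%d train / %d test), grid %d x %d, seed %d>\n",
              m$n_total, m$n_train, m$n_test, m$grid[1], m$grid[2], m$seed))
  invisible(x)
}
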