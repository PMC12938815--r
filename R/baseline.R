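#' Laplacian edge-strength map
#'
#' Absolute response of the 4-neighbor discrete Laplacian (center -4,
#' cross neighbors +1) with reflect boundary handling.
#'
#' @param img A [gray_image()] (or matrix).
#' @return Matrix of edge strengths (same dims).
#' @export
laplacian_edge_map <- function(img) {
  m <- as.matrix(unclass(img))
  p <- reflect_pad(m, 1, 1)
  nr <- nrow(m); nc <- ncol(m)
  core <- p[2:(nr + 1), 2:(nc + 1)]
  lap <- p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
    p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] - 4 * core
  abs(lap)
}

#' Fixed-frequency pulse train
#'
#' Pulses at `k / rate` seconds for `k = 0 .. round(rate * duration) - 1`,
#' anchored at `t = 0`; the clinical reference setting (300 Hz for 166 ms)
#' yields 50 pulses.
#'
#' @param rate_hz Pulse rate (> 0).
#' @param duration_ms Train duration (> 0).
#' @param window_ms Window of the returned [pulse_train()] (default the
#'   train duration; the simulation window is usually longer).
#' @return A [pulse_train()].
#' @export
fixed_rate_train <- function(rate_hz = 300, duration_ms = 166,
                             window_ms = max(duration_ms, 1000)) {
  if (rate_hz <= 0 || duration_ms <= 0)
    stop("fixed_rate_train: rate and duration must be > 0")
  n <- round(rate_hz * duration_ms / 1000)
  times <- (seq_len(n) - 1) / rate_hz * 1000
  times <- times[times < window_ms]
  pulse_train(times, duration_ms = window_ms)
}

#' Select stimulation pixels under a pulse budget
#'
#' Picks the `floor(budget / pulses_per_train)` pixels with the highest
#' edge strength (ties broken by row-major order); every selected pixel
#' receives the identical fixed train, so the plan's total pulse count
#' matches the budget up to train granularity. Top-k selection (rather
#' than a fixed scalar threshold) is what guarantees the budget match.
#'
#' @param edges Edge-strength matrix from [laplacian_edge_map()].
#' @param budget Total pulse budget (>= 0), typically the spike count of
#'   the neuromorphic encoding of the same image.
#' @param pulses_per_train Pulses in the fixed train (default 50).
#' @return A `stimulation_plan`: list `selected` (two-column matrix of
#'   row/col indices), `mask` (logical matrix), `pulses_per_train`,
#'   `total_pulses`.
#' @export
match_pulse_budget <- function(edges, budget, pulses_per_train = 50L) {
  if (budget < 0) stop("match_pulse_budget: budget must be >= 0")
  k <- floor(budget / pulses_per_train)
  if (k == 0) warning("match_pulse_budget: budget below one train; empty plan")
  nr <- nrow(edges); nc <- ncol(edges)
  ## tie-break by row-major scan order
  i <- seq_len(length(edges))
  rowmajor_rank <- (((i - 1L) %% nr)) * nc + ((i - 1L) %/% nr) + 1L
  ord <- order(-as.vector(edges), rowmajor_rank)
  sel <- head(ord, k)
  mask <- matrix(FALSE, nr, ncol(edges))
  mask[sel] <- TRUE
  selected <- cbind(row = ((sel - 1L) %% nr) + 1L,
                    col = ((sel - 1L) %/% nr) + 1L)
  structure(list(selected = selected, mask = mask,
                 pulses_per_train = as.integer(pulses_per_train),
                 total_pulses = as.integer(k * pulses_per_train)),
            class = "stimulation_plan")
}

#' Write a stimulation plan as JSON (+ optional mask PNG)
#'
#' @param plan A `stimulation_plan`.
#' @param path JSON destination.
#' @param mask_png Optional PNG path for the binary mask.
#' @return `path` invisibly.
#' @export
write_stimulation_plan <- function(plan, path, mask_png = NULL) {
  jsonlite::write_json(list(selected = plan$selected,
                            pulses_per_train = plan$pulses_per_train,
                            total_pulses = plan$total_pulses),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(mask_png)) png::writePNG(plan$mask * 1, mask_png)
  invisible(path)
}

#' Fixed-frequency stimulation baseline pipeline
#'
#' The conventional strategy: extract contrast edges (Laplacian), select
#' target pixels so the total pulse count matches the neuromorphic
#' encoding of the same image, stimulate every selected pixel with the
#' identical fixed train, simulate the cortical VSD response per pixel,
#' and decode with the same trained Path-2 decoder.
#'
#' @param img A prefiltered [gray_image()] on the encoder grid.
#' @param encoder_cfg An [encoder_config()] (used to compute the pulse
#'   budget from the image's neuromorphic spike count).
#' @param model A [wiener_model()].
#' @param decoder A trained Path-2 `decoder_net`.
#' @param rate_hz,duration_ms Fixed train parameters (defaults 300 Hz,
#'   166 ms).
#' @param record_ms,sim_duration_ms,bin_ms Timing as in [build_triplet()].
#' @return List `plan` (`stimulation_plan`), `vsd` (`vsd_stream`),
#'   `decoded` ([gray_image()]), `budget` (neuromorphic spike count).
#' @export
baseline_pipeline <- function(img, encoder_cfg, model, decoder,
                              rate_hz = 300, duration_ms = 166,
                              record_ms = 150, sim_duration_ms = 1000,
                              bin_ms = 5) {
  ev <- encode_stream(img, encoder_cfg, record_ms = record_ms)
  spikes <- bin_spikes(ev, bin_ms = bin_ms, record_ms = record_ms)
  budget <- sum(spikes)
  train <- fixed_rate_train(rate_hz, duration_ms, window_ms = sim_duration_ms)
  plan <- match_pulse_budget(laplacian_edge_map(img), budget,
                             pulses_per_train = length(train$times_ms))
  n <- as.integer(round(sim_duration_ms / model$dt_ms))
  s_one <- render_impulses(train, model$dt_ms)
  smat <- matrix(0, n, prod(dim(plan$mask)))
  smat[, as.vector(plan$mask)] <- s_one
  traces <- simulate_vsd_matrix(smat, model)
  frames <- downsample_vsd(traces, factor = as.integer(round(bin_ms / model$dt_ms)))
  vsd <- structure(array(frames, c(nrow(frames), dim(plan$mask))),
                   class = "vsd_stream", frame_ms = bin_ms)
  decoded <- if (is.null(decoder)) NULL else decode(decoder, vsd)
  list(plan = plan, vsd = vsd, decoded = decoded, budget = budget)
}
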