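#' Build the spike-to-image decoder (Path 1 / Path-2 back end)
#'
#' 3-D CNN mapping a binary spike stream `(frames x rows x cols)` to one
#' grayscale frame: two full-temporal-extent convolutions, then alternating
#' temporal average pooling and convolution until a single frame remains,
#' and a final `1 x 3 x 3` convolution. All convolutions carry a bias and
#' use "same" spatial padding; hidden activations are ReLU and the output
#' head is a sigmoid (applied at decode time; the network emits logits).
#' At full scale (`frames = 30`, pools 2/3/5, channels 4/4/8/16/1) the
#' per-layer trainable parameter counts are 1084, 4324, 4328, 5776 and 145.
#'
#' @param frames Input frame count (default 30); must equal `prod(pools)`.
#' @param grid Spatial dims (default `c(120, 120)`).
#' @param channels Channels of the four hidden convolutions.
#' @param pools Temporal pooling divisors (default `c(2, 3, 5)`).
#' @param seed Seed for weight initialization.
#' @return A `decoder_net` with role `"path1_backend"`.
#' @export
build_backend <- function(frames = 30L, grid = c(120L, 120L),
                          channels = c(4L, 4L, 8L, 16L),
                          pools = c(2L, 3L, 5L), seed = 1L) {
  frames <- as.integer(frames)
  if (prod(pools) != frames)
    stop("build_backend: prod(pools) must equal the input frame count")
  f1 <- frames %/% pools[1]
  f2 <- f1 %/% pools[2]
  ch <- as.integer(channels)
  layers <- list(
    layer_conv(frames, 3, 3, 1, ch[1], TRUE, derive_seed(seed, "b1")), layer_relu(),
    layer_conv(frames, 3, 3, ch[1], ch[2], TRUE, derive_seed(seed, "b2")), layer_relu(),
    layer_pool_t(pools[1]),
    layer_conv(f1, 3, 3, ch[2], ch[3], TRUE, derive_seed(seed, "b3")), layer_relu(),
    layer_pool_t(pools[2]),
    layer_conv(f2, 3, 3, ch[3], ch[4], TRUE, derive_seed(seed, "b4")), layer_relu(),
    layer_pool_t(pools[3]),
    layer_conv(1, 3, 3, ch[4], 1, TRUE, derive_seed(seed, "b5"))
  )
  structure(list(layers = layers, blocks = rep("back", length(layers)),
                 role = "path1_backend",
                 input_shape = c(frames, grid, 1L), out_act = "sigmoid"),
            class = "decoder_net")
}

#' Build the VSD-to-spike decoder (Path-2 front end)
#'
#' 3-D CNN mapping a simulated VSD stream to per-voxel spike probabilities
#' of the same shape: four convolution + batch-norm (+ ReLU) stages and a
#' final `1 x 1 x 1` convolution. Convolutions followed by batch norm carry
#' no bias; the final convolution does. At full scale (temporal kernels
#' 7/5/5/3/1, channels 16/32/16/32/1) the per-layer trainable parameter
#' counts are 1008, 32, 23040, 64, 23040, 32, 13824, 64 and 33.
#'
#' @param frames Input frame count (default 200).
#' @param grid Spatial dims.
#' @param channels Channels of the four hidden stages.
#' @param kts Temporal kernel extents of the four hidden convolutions.
#' @param seed Seed for weight initialization.
#' @return A `decoder_net` with role `"path2_frontend"`.
#' @export
build_frontend <- function(frames = 200L, grid = c(120L, 120L),
                           channels = c(16L, 32L, 16L, 32L),
                           kts = c(7L, 5L, 5L, 3L), seed = 1L) {
  ch <- as.integer(channels)
  layers <- list(
    layer_conv(kts[1], 3, 3, 1, ch[1], FALSE, derive_seed(seed, "f1")),
    layer_bn(ch[1]), layer_relu(),
    layer_conv(kts[2], 3, 3, ch[1], ch[2], FALSE, derive_seed(seed, "f2")),
    layer_bn(ch[2]), layer_relu(),
    layer_conv(kts[3], 3, 3, ch[2], ch[3], FALSE, derive_seed(seed, "f3")),
    layer_bn(ch[3]), layer_relu(),
    layer_conv(kts[4], 3, 3, ch[3], ch[4], FALSE, derive_seed(seed, "f4")),
    layer_bn(ch[4]), layer_relu(),
    layer_conv(1, 1, 1, ch[4], 1, TRUE, derive_seed(seed, "f5"))
  )
  structure(list(layers = layers, blocks = rep("front", length(layers)),
                 role = "path2_frontend",
                 input_shape = c(as.integer(frames), grid, 1L),
                 out_act = "sigmoid"),
            class = "decoder_net")
}

#' Assemble the two-stage Path-2 decoder
#'
#' Connects the pretrained front end (VSD -> spike probabilities, all
#' frames) to the back end through a temporal crop keeping the back end's
#' input frames (the early window in which all spikes occur).
#'
#' @param front,back `decoder_net`s from [build_frontend()] and
#'   [build_backend()].
#' @return A `decoder_net` with role `"path2_full"`; layers keep their
#'   block labels (`"front"`, `"back"`) for freezing.
#' @export
assemble_path2 <- function(front, back) {
  if (any(front$input_shape[2:3] != back$input_shape[2:3]))
    stop("assemble_path2: spatial grids differ between blocks")
  keep <- back$input_shape[1]
  if (keep > front$input_shape[1])
    stop("assemble_path2: back end needs more frames than the front end emits")
  ## the front end's logits pass through a sigmoid before entering the back
  ## end, mirroring its standalone spike-probability output
  layers <- c(front$layers, list(list(type = "sigmoid_bridge"),
                                 layer_crop_t(keep)), back$layers)
  blocks <- c(front$blocks, "bridge", "bridge", back$blocks)
  structure(list(layers = layers, blocks = blocks, role = "path2_full",
                 input_shape = front$input_shape, out_act = "sigmoid"),
            class = "decoder_net")
}

#' @export
print.decoder_net <- function(x, ...) {
  a <- layer_audit(x)
  cat(sprintf("<decoder_net role=%s, %d layers, %d trainable parameters>\n",
              x$role, nrow(a), sum(a$params)))
  print(a, row.names = FALSE)
  invisible(x)
}

#' Closed-form layer audit of a decoder network
#'
#' Per-layer operation, kernel, output shape and trainable parameter count,
#' computed in closed form from the layer specifications and checked
#' against the actual parameter array sizes. This is the ledger used to
#' verify the architectures against their published parameter counts.
#'
#' @param net A `decoder_net`.
#' @return data.frame with columns `layer`, `op`, `kernel`, `out_t`,
#'   `out_h`, `out_w`, `out_c`, `params`.
#' @export
layer_audit <- function(net) {
  shp <- net$input_shape  # (T, H, W, C)
  rows <- list()
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    if (ly$type == "conv") {
      d <- dim(ly$w)
      n <- prod(d) + length(ly$b %||% numeric(0))
      stopifnot(length(ly$w) == prod(d))
      shp <- c(shp[1], shp[2], shp[3], d[5])
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, op = "conv3d",
        kernel = sprintf("(%d x %d x %d) x %d", d[1], d[2], d[3], d[5]),
        out_t = shp[1], out_h = shp[2], out_w = shp[3], out_c = shp[4],
        params = n)
    } else if (ly$type == "bn") {
      n <- length(ly$gamma) + length(ly$beta)
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, op = "batch_norm", kernel = "[gamma, beta]",
        out_t = shp[1], out_h = shp[2], out_w = shp[3], out_c = shp[4],
        params = n)
    } else if (ly$type == "pool_t") {
      shp[1] <- shp[1] %/% ly$factor
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, op = "avgpool3d",
        kernel = sprintf("%d x 1 x 1", ly$factor),
        out_t = shp[1], out_h = shp[2], out_w = shp[3], out_c = shp[4],
        params = 0)
    } else if (ly$type == "crop_t") {
      shp[1] <- ly$keep
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, op = "crop_t", kernel = sprintf("keep %d", ly$keep),
        out_t = shp[1], out_h = shp[2], out_w = shp[3], out_c = shp[4],
        params = 0)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        layer = li, op = ly$type, kernel = "",
        out_t = shp[1], out_h = shp[2], out_w = shp[3], out_c = shp[4],
        params = 0)
    }
  }
  do.call(rbind, rows)
}

#' Total trainable parameters of a network
#' @param net A `decoder_net`.
#' @return Integer count.
#' @export
count_params <- function(net) sum(layer_audit(net)$params)

#' Export the layer audit as portable JSON
#'
#' @param net A `decoder_net`.
#' @param path Destination file.
#' @return `path` invisibly.
#' @export
write_layer_audit <- function(net, path) {
  jsonlite::write_json(layer_audit(net), path, dataframe = "rows", digits = NA)
  invisible(path)
}

## digest of a block's parameters (freeze contract checks)
block_digest <- function(net, block) {
  idx <- which(net$blocks == block)
  vals <- unlist(lapply(net$layers[idx], function(ly)
    c(ly$w, ly$b, ly$gamma, ly$beta, ly$run_mean, ly$run_var)))
  sprintf("%08x", as.integer(fnv1a32(paste(format(vals, digits = 17), collapse = ",")) %% 2147483647))
}

#' Decode a stream into a grayscale image
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' applies the sigmoid output head. Accepts a single stream or a list.
#'
#' @param net A trained `decoder_net`.
#' @param stream A `spike_stream` (Path 1) or `vsd_stream` (Path 2), or a
#'   list of them.
#' @return A [gray_image()] (or list of them, order preserved).
#' @export
decode <- function(net, stream) {
  if (is.list(stream) && !inherits(stream, c("spike_stream", "vsd_stream")))
    return(lapply(stream, decode, net = net))
  x <- with_channel(stream)
  if (!all(dim(x) == net$input_shape))
    stop(sprintf("decode: stream shape (%s) does not match net input (%s)",
                 paste(dim(x), collapse = "x"),
                 paste(net$input_shape, collapse = "x")))
  out <- nn_forward(net, list(x), training = FALSE)$out[[1]]
  d <- dim(out)
  gray_image(clip01(matrix(sigmoid(out), d[2], d[3])))
}

## dataset accessors ----------------------------------------------------------

triplet_vsd_input <- function(tr) with_channel(tr$vsd)
triplet_spike_input <- function(tr) with_channel(tr$spikes)
triplet_spike_target <- function(tr, frames) {
  s <- with_channel(tr$spikes)
  d <- dim(s)
  if (d[1] == frames) return(s)
  out <- array(0, c(frames, d[2], d[3], d[4]))
  out[seq_len(d[1]), , , ] <- s   # spikes only exist in the early window
  out
}
triplet_image_target <- function(tr) as.matrix(unclass(tr$image))

#' Pretrain the VSD-to-spike front end
#'
#' Binary cross-entropy on per-voxel spike probability; the target spike
#' stream is zero-padded to the VSD frame count (all spikes lie in the
#' early window). Early stopping monitors F1 at threshold 0.5 on the
#' held-out fold.
#'
#' @param net A `decoder_net` from [build_frontend()].
#' @param train,val Lists of triplets.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List `(net, history, best_metric)`.
#' @export
pretrain_frontend <- function(net, train, val, cfg = train_config(),
                              verbose = FALSE) {
  frames <- net$input_shape[1]
  fit_net(net,
          inputs = lapply(train, triplet_vsd_input),
          targets = lapply(train, triplet_spike_target, frames = frames),
          loss = "bce", lr = cfg$lr, max_epochs = cfg$max_epochs,
          batch_size = cfg$batch_size, patience = cfg$patience,
          min_delta = cfg$min_delta, seed = derive_seed(cfg$seed, "front"),
          val_inputs = lapply(val, triplet_vsd_input),
          val_targets = lapply(val, triplet_spike_target, frames = frames),
          metric = "f1", verbose = verbose)
}

#' Pretrain the spike-to-image back end
#'
#' `1 - SSIM` loss between the decoded frame and the (prefiltered) target
#' image; early stopping monitors validation SSIM.
#'
#' @inheritParams pretrain_frontend
#' @param net A `decoder_net` from [build_backend()].
#' @return List `(net, history, best_metric)`.
#' @export
pretrain_backend <- function(net, train, val, cfg = train_config(),
                             verbose = FALSE) {
  fit_net(net,
          inputs = lapply(train, triplet_spike_input),
          targets = lapply(train, triplet_image_target),
          loss = "ssim", lr = cfg$lr, max_epochs = cfg$max_epochs,
          batch_size = cfg$batch_size, patience = cfg$patience,
          min_delta = cfg$min_delta, seed = derive_seed(cfg$seed, "back"),
          val_inputs = lapply(val, triplet_spike_input),
          val_targets = lapply(val, triplet_image_target),
          metric = "ssim", verbose = verbose)
}

#' Alternating refinement of the assembled Path-2 decoder
#'
#' For each of `cfg$rounds` rounds: re-train the front end with the back
#' end frozen, then the back end with the front end frozen, both under the
#' end-to-end `1 - SSIM` loss at the refinement learning rate. Frozen
#' parameters are bit-identical before and after their frozen phase.
#'
#' @param path2 A `decoder_net` from [assemble_path2()].
#' @param train,val Lists of triplets.
#' @param cfg A [train_config()].
#' @param verbose Print per-phase progress.
#' @return List `(net, round_ssim, history)` where `round_ssim` is the
#'   end-to-end validation SSIM after each round (round 0 = before
#'   refinement).
#' @export
alternating_refinement <- function(path2, train, val, cfg = train_config(),
                                   verbose = FALSE) {
  inputs <- lapply(train, triplet_vsd_input)
  targets <- lapply(train, triplet_image_target)
  vin <- lapply(val, triplet_vsd_input)
  vtg <- lapply(val, triplet_image_target)
  ssim_now <- function(net) eval_metric(net, vin, vtg, "ssim", ssim_settings())
  round_ssim <- ssim_now(path2)
  hist <- list()
  for (r in seq_len(cfg$rounds)) {
    for (phase in c("front", "back")) {
      frozen <- setdiff(c("front", "back"), phase)
      dig0 <- block_digest(path2, frozen)
      res <- fit_net(path2, inputs, targets, loss = "ssim",
                     lr = cfg$lr_refine, max_epochs = cfg$refine_epochs,
                     batch_size = cfg$batch_size, patience = cfg$patience,
                     min_delta = cfg$min_delta,
                     seed = derive_seed(cfg$seed, "refine", r, phase),
                     frozen = c(frozen, "bridge"),
                     val_inputs = vin, val_targets = vtg, metric = "ssim",
                     verbose = verbose)
      path2 <- res$net
      stopifnot(identical(block_digest(path2, frozen), dig0))
      hist[[paste0("round", r, "_", phase)]] <- res$history
      if (verbose) message(sprintf("round %d %s: val SSIM %.4f", r, phase,
                                   res$best_metric))
    }
    round_ssim <- c(round_ssim, ssim_now(path2))
  }
  list(net = path2, round_ssim = round_ssim, history = hist)
}

#' Save / load a decoder checkpoint
#'
#' Parameters in R's native serialization plus the portable JSON layer
#' audit alongside for cross-language verification.
#'
#' @param net A `decoder_net`.
#' @param path Checkpoint path (`.rds`); the audit is written to
#'   `paste0(path, ".audit.json")`.
#' @return `save_decoder`: `path` invisibly; `load_decoder`: the network.
#' @export
save_decoder <- function(net, path) {
  saveRDS(net, path)
  write_layer_audit(net, paste0(path, ".audit.json"))
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) readRDS(path)
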