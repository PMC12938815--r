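#' Run-configuration presets
#'
#' `"paper"` is the full-scale configuration: 120 x 120 grid, 150 ms spike
#' window (30 frames at 5 ms), 1000 ms simulated responses (200 frames),
#' 400 triplets split 320/80, front-end channels 16/32/16/32 and back-end
#' temporal pooling 2/3/5. `"desk"` is the scaled-down profile for
#' single-CPU work: 32 x 32 grid, 60 ms spike window (12 frames, pooling
#' 2/3/2), 300 ms responses (60 frames), 50 triplets split 40/10,
#' front-end channels 4/8/4/8. Both are complete, structurally identical
#' configurations; only sizes differ.
#'
#' @param preset `"paper"` or `"desk"`.
#' @param seed Global seed fanned out to every stage.
#' @return A `run_config` list with elements `preset`, `seed`, `grid`,
#'   `record_ms`, `sim_duration_ms`, `bin_ms`, `n`, `split`, `encoder`,
#'   `model`, `train`, `frontend`, `backend`, `prefilter_sigma`, `style`.
#' @export
preset_config <- function(preset = c("desk", "paper"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    grid <- c(120L, 120L)
    cfg <- list(
      preset = "paper", seed = as.integer(seed), grid = grid,
      record_ms = 150, sim_duration_ms = 1000, bin_ms = 5,
      n = 400L, split = c(320L, 80L),
      encoder = encoder_config(grid = grid),
      model = default_wiener_model(),
      train = train_config(seed = derive_seed(seed, "train")),
      frontend = list(channels = c(16L, 32L, 16L, 32L), kts = c(7L, 5L, 5L, 3L)),
      backend = list(channels = c(4L, 4L, 8L, 16L), pools = c(2L, 3L, 5L)),
      prefilter_sigma = 1.0, style = "mixture")
  } else {
    grid <- c(32L, 32L)
    cfg <- list(
      preset = "desk", seed = as.integer(seed), grid = grid,
      record_ms = 60, sim_duration_ms = 300, bin_ms = 5,
      n = 50L, split = c(40L, 10L),
      encoder = encoder_config(grid = grid),
      model = default_wiener_model(),
      train = train_config(max_epochs = 12L, patience = 4L,
                           refine_epochs = 2L,
                           seed = derive_seed(seed, "train")),
      frontend = list(channels = c(4L, 8L, 4L, 8L), kts = c(7L, 5L, 5L, 3L)),
      backend = list(channels = c(4L, 4L, 8L, 16L), pools = c(2L, 3L, 2L)),
      prefilter_sigma = 1.0, style = "mixture")
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path JSON file.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   configuration (reconstructed through [preset_config()] with stored
#'   overrides).
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$encoder <- unclass(out$encoder)
  out$model <- unclass(out$model)
  out$train <- unclass(out$train)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- preset_config(x$preset, seed = x$seed)
  for (nm in c("grid", "record_ms", "sim_duration_ms", "bin_ms", "n", "split",
               "prefilter_sigma", "style"))
    if (!is.null(x[[nm]])) cfg[[nm]] <- x[[nm]]
  if (!is.null(x$encoder)) cfg$encoder <- do.call(encoder_config, x$encoder)
  if (!is.null(x$model)) cfg$model <- wiener_model(k = x$model$k,
    gamma_ms = x$model$gamma_ms, beta = x$model$beta, p = x$model$p)
  if (!is.null(x$train)) cfg$train <- do.call(train_config, x$train)
  cfg
}

## build both decoder nets for a run configuration
config_nets <- function(config) {
  frames_spk <- as.integer(round(config$record_ms / config$bin_ms))
  frames_vsd <- as.integer(round(config$sim_duration_ms / config$bin_ms))
  list(
    backend = build_backend(frames = frames_spk, grid = config$grid,
                            channels = config$backend$channels,
                            pools = config$backend$pools,
                            seed = derive_seed(config$seed, "backend_init")),
    frontend = build_frontend(frames = frames_vsd, grid = config$grid,
                              channels = config$frontend$channels,
                              kts = config$frontend$kts,
                              seed = derive_seed(config$seed, "frontend_init")))
}

#' Run the full simulation-and-decoding pipeline
#'
#' Executes the stages in dependency order: dataset generation (images ->
#' spikes -> simulated VSD), Path-1 training (back end on spikes), Path-2
#' training (front-end and back-end pretraining, assembly, alternating
#' refinement), evaluation (SSIM + Fourier profiles per path), and the
#' fixed-frequency baseline on the test images. Artifacts are written
#' under `out_dir`, each stamped with the configuration digest and seed;
#' a stage whose artifact already carries the current digest is skipped
#' unless `force`.
#'
#' @param config A `run_config` from [preset_config()].
#' @param stages Subset of `c("dataset", "train", "evaluate", "baseline")`
#'   (default all).
#' @param out_dir Output directory.
#' @param force Re-run stages whose artifacts are up to date.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the artifacts produced (dataset, nets,
#'   reports, baseline results).
#' @export
run_pipeline <- function(config, stages = c("dataset", "train", "evaluate",
                                            "baseline"),
                         out_dir = "vsdecode_run", force = FALSE,
                         verbose = TRUE) {
  all_stages <- c("dataset", "train", "evaluate", "baseline")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0)
    stop("run_pipeline: unknown stage(s) ", paste(bad, collapse = ", "),
         "; valid stages are ", paste(all_stages, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(list(unclass(config)))
  say <- function(...) if (verbose) message(...)
  prov <- function(name) file.path(out_dir, paste0(name, ".provenance.json"))
  fresh <- function(name) {
    f <- prov(name)
    !force && file.exists(f) &&
      identical(jsonlite::read_json(f)$digest, digest)
  }
  stamp <- function(name) jsonlite::write_json(
    list(digest = digest, seed = config$seed, stage = name,
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    prov(name), auto_unbox = TRUE)
  res <- list()

  ds_dir <- file.path(out_dir, "dataset")
  if ("dataset" %in% stages) {
    if (fresh("dataset")) {
      say("dataset: cached, skipping")
      res$dataset <- load_dataset(ds_dir)
    } else {
      say("dataset: generating ", config$n, " triplets")
      res$dataset <- make_dataset(
        n = config$n, split = config$split,
        seed = derive_seed(config$seed, "dataset"),
        encoder_cfg = config$encoder, model = config$model,
        style = image_style(config$style),
        prefilter_sigma = config$prefilter_sigma,
        record_ms = config$record_ms,
        sim_duration_ms = config$sim_duration_ms,
        bin_ms = config$bin_ms, dir = ds_dir)
      stamp("dataset")
    }
  }

  if (any(c("train", "evaluate", "baseline") %in% stages)) {
    if (is.null(res$dataset)) {
      if (!file.exists(file.path(ds_dir, "manifest.json")))
        stop("run_pipeline: missing upstream artifact for stage 'train' ",
             "(run the 'dataset' stage first)")
      res$dataset <- load_dataset(ds_dir)
    }
    ds <- res$dataset
    nval <- max(2L, length(ds$train) %/% 5L)
    val <- ds$train[seq_len(nval)]
    tra <- ds$train[-seq_len(nval)]
  }

  p1_path <- file.path(out_dir, "path1.rds")
  p2_path <- file.path(out_dir, "path2.rds")
  if ("train" %in% stages) {
    if (fresh("train")) {
      say("train: cached, skipping")
      res$path1 <- load_decoder(p1_path); res$path2 <- load_decoder(p2_path)
    } else {
      nets <- config_nets(config)
      say("train: Path-1 back end (1 - SSIM loss)")
      bk <- pretrain_backend(nets$backend, tra, val, config$train,
                             verbose = verbose)
      res$path1 <- bk$net
      say("train: Path-2 front end (BCE loss)")
      fr <- pretrain_frontend(nets$frontend, tra, val, config$train,
                              verbose = verbose)
      say("train: alternating refinement")
      p2 <- assemble_path2(fr$net, bk$net)
      rf <- alternating_refinement(p2, tra, val, config$train,
                                   verbose = verbose)
      res$path2 <- rf$net
      res$refinement <- rf$round_ssim
      save_decoder(res$path1, p1_path)
      save_decoder(res$path2, p2_path)
      jsonlite::write_json(rf$round_ssim, file.path(out_dir, "refinement.json"),
                           digits = NA)
      stamp("train")
    }
  }

  if ("evaluate" %in% stages) {
    if (is.null(res$path1)) {
      if (!file.exists(p1_path))
        stop("run_pipeline: missing upstream artifact for stage 'evaluate' ",
             "(run the 'train' stage first)")
      res$path1 <- load_decoder(p1_path); res$path2 <- load_decoder(p2_path)
    }
    say("evaluate: decoding and scoring both paths")
    all_tr <- c(ds$train, ds$test)
    splitlab <- rep(c("train", "test"), c(length(ds$train), length(ds$test)))
    originals <- lapply(all_tr, function(t) t$image)
    dec1 <- lapply(all_tr, function(t) decode(res$path1, t$spikes))
    dec2 <- lapply(all_tr, function(t) decode(res$path2, t$vsd))
    res$report_path1 <- eval_report(dec1, originals, splitlab)
    res$report_path2 <- eval_report(dec2, originals, splitlab)
    write_eval_report(res$report_path1, file.path(out_dir, "eval_path1.json"))
    write_eval_report(res$report_path2, file.path(out_dir, "eval_path2.json"))
    stamp("evaluate")
  }

  if ("baseline" %in% stages) {
    if (is.null(res$path2)) {
      if (!file.exists(p2_path))
        stop("run_pipeline: missing upstream artifact for stage 'baseline' ",
             "(run the 'train' stage first)")
      res$path2 <- load_decoder(p2_path)
    }
    say("baseline: fixed-rate stimulation on test images")
    res$baseline <- lapply(ds$test, function(t)
      baseline_pipeline(t$image, config$encoder, config$model, res$path2,
                        record_ms = config$record_ms,
                        sim_duration_ms = config$sim_duration_ms,
                        bin_ms = config$bin_ms))
    stamp("baseline")
  }
  invisible(res)
}
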