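test_that("full-scale back end reproduces the published parameter ledger", {
  net <- build_backend()
  a <- layer_audit(net)
  convs <- a[a$op == "conv3d", ]
  expect_equal(convs$params, c(1084, 4324, 4328, 5776, 145))
  ## output shapes down the stack: spatial size preserved, time pooled
  expect_true(all(a$out_h == 120 & a$out_w == 120))
  expect_equal(a$out_t[a$op == "avgpool3d"], c(15, 5, 1))
  expect_equal(convs$out_c, c(4, 4, 8, 16, 1))
  expect_equal(count_params(net), 1084 + 4324 + 4328 + 5776 + 145)
})

test_that("full-scale front end reproduces the published parameter ledger", {
  net <- build_frontend()
  a <- layer_audit(net)
  tracked <- a[a$op %in% c("conv3d", "batch_norm"), ]
  expect_equal(tracked$params, c(1008, 32, 23040, 64, 23040, 32, 13824, 64, 33))
  expect_true(all(a$out_t == 200 & a$out_h == 120 & a$out_w == 120))
  expect_equal(tracked$out_c[tracked$op == "conv3d"], c(16, 32, 16, 32, 1))
  ## bias convention: convs followed by batch norm carry no bias
  expect_null(net$layers[[1]]$b)
  expect_length(net$layers[[13]]$b, 1)
})

test_that("assembly composes blocks additively and crops the early window", {
  front <- build_frontend(frames = 20, grid = c(10L, 10L),
                          channels = c(2L, 3L, 2L, 3L))
  back <- build_backend(frames = 4, grid = c(10L, 10L),
                        channels = c(2L, 2L, 3L, 4L), pools = c(2L, 2L, 1L))
  p2 <- assemble_path2(front, back)
  expect_equal(count_params(p2), count_params(front) + count_params(back))
  a <- layer_audit(p2)
  expect_equal(unlist(tail(a, 1)[c("out_t", "out_h", "out_w", "out_c")],
                      use.names = FALSE), c(1, 10, 10, 1))
  expect_equal(a$out_t[a$op == "crop_t"], 4)
  expect_error(assemble_path2(back, front), "frames")
})

test_that("decoding is deterministic, shape-checked and order-preserving", {
  net <- build_backend(frames = 4, grid = c(8L, 8L),
                       channels = c(2L, 2L, 2L, 2L), pools = c(2L, 2L, 1L),
                       seed = 3)
  mk <- function(seed) {
    set.seed(seed)
    structure(array(rbinom(4 * 64, 1, 0.2), c(4, 8, 8)),
              class = "spike_stream", bin_ms = 5)
  }
  s1 <- mk(1); s2 <- mk(2)
  d1 <- decode(net, s1)
  expect_s3_class(d1, "gray_image")
  expect_equal(dim(d1), c(8L, 8L))
  expect_identical(unclass(decode(net, s1)), unclass(d1))
  batch <- decode(net, list(s1, s2, s1))
  expect_identical(unclass(batch[[1]]), unclass(d1))
  expect_identical(unclass(batch[[3]]), unclass(d1))
  expect_false(identical(unclass(batch[[2]]), unclass(d1)))
  bad <- structure(array(0, c(5, 8, 8)), class = "spike_stream", bin_ms = 5)
  expect_error(decode(net, bad), "shape")
})

## one tiny dataset shared by the training smoke tests
smoke_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_encoder(grid = c(12L, 12L))
      cache <<- make_dataset(n = 8, split = c(6, 2), seed = 17,
                             encoder_cfg = cfg,
                             model = default_wiener_model(),
                             record_ms = 20, sim_duration_ms = 100)
    }
    cache
  }
})

test_that("front-end pretraining reduces the BCE from its initial value", {
  ds <- smoke_data()
  net <- build_frontend(frames = 20, grid = c(12L, 12L),
                        channels = c(2L, 4L, 2L, 4L), seed = 2)
  res <- pretrain_frontend(net, ds$train, ds$test,
                           train_config(max_epochs = 3, patience = 5,
                                        lr = 1e-3))
  h <- res$history$train_loss
  expect_lt(h[length(h)], h[1])
  expect_true(all(is.finite(h)))
})

test_that("back-end pretraining beats the untrained net on validation SSIM", {
  ds <- smoke_data()
  net <- build_backend(frames = 4, grid = c(12L, 12L),
                       channels = c(2L, 2L, 4L, 4L), pools = c(2L, 2L, 1L),
                       seed = 2)
  ns <- asNamespace("vsdecode")
  before <- ns$eval_metric(net,
                           lapply(ds$test, ns$triplet_spike_input),
                           lapply(ds$test, ns$triplet_image_target),
                           "ssim", ssim_settings())
  res <- pretrain_backend(net, ds$train, ds$test,
                          train_config(max_epochs = 6, patience = 6, lr = 1e-3))
  expect_gt(res$best_metric, before)
})

test_that("alternating refinement freezes blocks bit-exactly and runs 3 rounds", {
  ds <- smoke_data()
  front <- build_frontend(frames = 20, grid = c(12L, 12L),
                          channels = c(2L, 2L, 2L, 2L), seed = 4)
  back <- build_backend(frames = 4, grid = c(12L, 12L),
                        channels = c(2L, 2L, 2L, 2L), pools = c(2L, 2L, 1L),
                        seed = 5)
  p2 <- assemble_path2(front, back)
  cfg <- train_config(rounds = 3, refine_epochs = 1, max_epochs = 2)
  res <- alternating_refinement(p2, ds$train, ds$test, cfg)
  ## freeze contract is asserted inside via parameter digests; here the
  ## round count: one SSIM entry before refinement plus one per round
  expect_length(res$round_ssim, 4)
  expect_s3_class(res$net, "decoder_net")
  expect_error(train_config(rounds = 0), "rounds")
})

test_that("checkpoints round-trip with a portable layer audit", {
  net <- build_backend(frames = 4, grid = c(8L, 8L),
                       channels = c(2L, 2L, 2L, 2L), pools = c(2L, 2L, 1L))
  f <- tempfile(fileext = ".rds")
  save_decoder(net, f)
  back <- load_decoder(f)
  expect_identical(back$layers, net$layers)
  audit <- jsonlite::read_json(paste0(f, ".audit.json"), simplifyVector = TRUE)
  expect_equal(audit$params, layer_audit(net)$params)
  unlink(c(f, paste0(f, ".audit.json")))
})
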