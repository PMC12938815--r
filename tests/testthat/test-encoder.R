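test_that("biphasic kernel is zero-sum with unit peak and causal convolution matches brute force", {
  cfg <- tiny_encoder()
  k <- biphasic_kernel(cfg)
  expect_lt(abs(sum(k)), 1e-9)
  expect_equal(max(abs(k)), 1)

  ## zero in, zero out
  expect_true(all(biphasic_filter(numeric(80), cfg) == 0))

  ## unit step decays back toward zero (kernel integral is zero)
  cfg2 <- tiny_encoder(kernel_support_ms = 100)
  step <- rep(1, 600)  # 300 ms at 0.5 ms, well past the kernel support
  out <- biphasic_filter(step, cfg2)
  expect_lt(abs(out[length(out)]), 1e-9)
  expect_gt(max(abs(out)), 0.1)

  ## arbitrary signal vs direct O(n^2) convolution
  set.seed(4)
  x <- rnorm(50)
  got <- biphasic_filter(x, cfg)
  expect_lt(max(abs(got - conv_causal_oracle(x, k))), 1e-9)
})

test_that("DoG generator signal vanishes for constant streams and matches kernel arithmetic", {
  ## 27 x 27 grid with a centered impulse keeps both Gaussian supports
  ## (radius <= 12) strictly clear of the reflecting boundary
  cfg <- tiny_encoder(grid = c(27L, 27L), surround_delay_ms = 2)
  dsteps <- round(2 / cfg$dt_ms)
  const <- array(0.7, c(12, 27, 27))
  g <- dog_generator_signal(const, cfg)
  ## after the surround delay both filtrates see the same field
  expect_lt(max(abs(g[(dsteps + 1):12, , ])), 1e-9)

  ## impulse frame: response = -(Gc - delayed Gs) at the impulse pixel
  ## (off polarity inverts the sign)
  imp <- matrix(0, 27, 27); imp[14, 14] <- 1
  frames <- array(0, c(10, 27, 27))
  frames[5, , ] <- imp
  g2 <- dog_generator_signal(frames, cfg)
  blur1 <- function(m, s) {  # direct kernel evaluation oracle
    r <- ceiling(4 * s); k1 <- exp(-((-r:r)^2) / (2 * s^2)); k1 <- k1 / sum(k1)
    K <- outer(k1, k1)
    out <- matrix(0, 27, 27)
    for (i in 1:27) for (j in 1:27) {
      di <- i - 14 + r + 1; dj <- j - 14 + r + 1
      if (di >= 1 && di <= 2 * r + 1 && dj >= 1 && dj <= 2 * r + 1)
        out[i, j] <- K[di, dj]
    }
    out
  }
  expect_lt(max(abs(g2[5, , ] - (-blur1(imp, cfg$center_sigma_px)))), 1e-9)
  expect_lt(max(abs(g2[5 + dsteps, , ] - blur1(imp, cfg$surround_sigma_px))), 1e-9)

  ## off polarity: a step to black excites (positive generator signal)
  stepdark <- array(0.5, c(10, 27, 27))
  stepdark[5:10, , ] <- 0
  g3 <- dog_generator_signal(stepdark, cfg)
  expect_gt(max(g3[5, , ]), 0.1)

  expect_error(dog_generator_signal(array(0, c(3, 4, 4)), cfg), "grid")
})

test_that("Izhikevich dynamics: rest is silent, reset applies, step size barely matters", {
  cfg <- tiny_encoder(grid = c(1L, 1L))
  ## subthreshold rest for 500 ms
  st <- list(v = -65, u = 0.2 * -65)
  n_sp <- 0
  for (i in seq_len(1000)) {
    r <- izhikevich_step(st, 0, 0.5, cfg)
    st <- r$state; n_sp <- n_sp + r$spiked
  }
  expect_equal(n_sp, 0)
  ## the RS fixed point sits near -70 mV (0.04 v^2 + 4.8 v + 140 = 0)
  expect_lt(abs(st$v - (-70)), 2)

  ## suprathreshold state spikes and resets to c exactly
  r <- izhikevich_step(list(v = 31, u = 0.2 * -65), 0, 0.5, cfg)
  expect_true(r$spiked)
  expect_equal(r$state$v, cfg$izh_c)

  ## spike count at dt = 0.5 matches a dt = 0.01 reference within one spike
  run <- function(dt) {
    st <- list(v = -65, u = 0.2 * -65); cnt <- 0
    for (i in seq_len(round(1000 / dt))) {
      r <- izhikevich_step(st, 10, dt, cfg)
      st <- r$state; cnt <- cnt + r$spiked
    }
    cnt
  }
  expect_lte(abs(run(0.5) - run(0.01)), 1)

  expect_error(izhikevich_step(list(v = -65, u = -13), 0, 2, cfg), "dt_ms")
})

test_that("encoding the adaptation field itself drives almost no unit", {
  cfg <- tiny_encoder()
  ev <- encode_stream(gray_image(matrix(cfg$gray_level, 16, 16)), cfg,
                      record_ms = 60)
  expect_lte(length(unique(paste(ev$unit_row, ev$unit_col))), 0.01 * 256)
})

test_that("encoding a natural-like image is deterministic and on the unit grid", {
  cfg <- tiny_encoder()
  img <- tiny_image(2)
  ev1 <- encode_stream(img, cfg, record_ms = 60)
  ev2 <- encode_stream(img, cfg, record_ms = 60)
  expect_identical(ev1, ev2)
  expect_gt(nrow(ev1), 0)
  expect_true(all(ev1$unit_row >= 1 & ev1$unit_row <= 16))
  expect_true(all(ev1$time_ms >= 0 & ev1$time_ms < 60))
  ## per-unit times strictly increasing (sorted output, no duplicates)
  sp <- split(ev1$time_ms, paste(ev1$unit_row, ev1$unit_col))
  expect_true(all(vapply(sp, function(t) all(diff(t) > 0), TRUE)))
})

test_that("raising the gain never silences a firing unit", {
  cfg1 <- tiny_encoder(gain = 40)
  cfg2 <- tiny_encoder(gain = 80)
  per_unit <- function(ev) {
    tab <- table(factor(paste(ev$unit_row, ev$unit_col),
                        levels = paste(rep(1:16, 16), rep(1:16, each = 16))))
    as.numeric(tab)
  }
  for (s in 1:5) {
    img <- tiny_image(s)
    n1 <- per_unit(encode_stream(img, cfg1, record_ms = 60))
    n2 <- per_unit(encode_stream(img, cfg2, record_ms = 60))
    expect_true(all(n2 >= n1), label = paste("image seed", s))
  }
})

test_that("binning uses half-open 5 ms windows and saturates to binary", {
  grid <- c(4L, 4L)
  ev <- structure(
    data.frame(unit_row = c(1L, 1L, 2L, 2L, 3L),
               unit_col = c(1L, 1L, 2L, 2L, 3L),
               time_ms = c(0.5, 1.0, 4.9, 5.0, 12.5)),
    class = c("spike_events", "data.frame"), grid = grid, record_ms = 15)
  s <- bin_spikes(ev, bin_ms = 5, record_ms = 15)
  expect_equal(dim(s), c(3L, 4L, 4L))
  expect_equal(s[1, 1, 1], 1)          # two events saturate to one
  expect_equal(sum(s[, 1, 1]), 1)
  expect_equal(s[1, 2, 2], 1)          # 4.9 ms -> frame 1
  expect_equal(s[2, 2, 2], 1)          # 5.0 ms -> frame 2 (half-open)
  expect_equal(s[3, 3, 3], 1)
  expect_true(all(unclass(s) %in% c(0, 1)))
  expect_error(bin_spikes(ev, bin_ms = 4, record_ms = 15), "multiple")

  ## 150 ms at 5 ms gives 30 frames
  ev0 <- structure(data.frame(unit_row = integer(0), unit_col = integer(0),
                              time_ms = numeric(0)),
                   class = c("spike_events", "data.frame"),
                   grid = grid, record_ms = 150)
  expect_equal(dim(bin_spikes(ev0, 5, 150))[1], 30L)
})

test_that("binning conserves spike presence per unit", {
  cfg <- tiny_encoder()
  ev <- encode_stream(tiny_image(3), cfg, record_ms = 60)
  s <- bin_spikes(ev, 5, 60)
  has_event <- matrix(FALSE, 16, 16)
  has_event[cbind(ev$unit_row, ev$unit_col)] <- TRUE
  has_frame <- apply(unclass(s), c(2, 3), max) > 0
  expect_identical(has_frame, has_event)
})
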