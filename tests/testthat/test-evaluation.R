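test_that("SSIM is 1 on identity, symmetric, and negative for inverted patterns", {
  set.seed(3)
  x <- gray_image(matrix(runif(400), 20, 20))
  y <- gray_image(matrix(runif(400), 20, 20))
  expect_equal(ssim(x, x), 1.0)
  expect_lt(abs(ssim(x, y) - ssim(y, x)), 1e-9)
  ## binary checkerboard vs its inverse: strongly anticorrelated structure
  cb <- gray_image((outer(1:16, 1:16, `+`) %% 2))
  expect_lt(ssim(cb, gray_image(1 - unclass(cb))), 0)
  expect_error(ssim(x, gray_image(matrix(0.2, 4, 4))), "dimensions")
})

test_that("single-window SSIM matches the closed-form statistic on toy images", {
  a <- matrix(c(0.2, 0.4, 0.6, 0.8, 1.0, 0.1, 0.3, 0.5, 0.7), 3)
  b <- matrix(c(0.3, 0.4, 0.5, 0.9, 0.8, 0.2, 0.2, 0.6, 0.6), 3)
  st <- ssim_settings(window = "global")
  C1 <- 0.01^2; C2 <- 0.03^2
  mu1 <- mean(a); mu2 <- mean(b)
  v1 <- mean(a^2) - mu1^2; v2 <- mean(b^2) - mu2^2
  cv <- mean(a * b) - mu1 * mu2
  expected <- ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
    ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
  expect_equal(ssim(gray_image(a), gray_image(b), st), expected)
})

test_that("SSIM summaries aggregate per split with sample sd", {
  imgs <- lapply(1:4, function(i) generate_image(image_style("blobs", seed = i),
                                                 16, 16))
  ## identical pairs: mean 1, sd 0, sizes propagated
  ss <- ssim_summary(imgs, imgs, c("train", "train", "train", "test"))
  expect_equal(ss$summary$mean, c(1, 1))
  expect_equal(ss$summary$sd[ss$summary$split == "train"], 0)
  expect_equal(ss$summary$n[order(ss$summary$split)], c(1L, 3L))
  ## aggregation equals direct recomputation
  ss2 <- ssim_summary(imgs[1:2], imgs[c(2, 1)], c("a", "a"))
  direct <- c(ssim(imgs[[1]], imgs[[2]]), ssim(imgs[[2]], imgs[[1]]))
  expect_equal(ss2$summary$mean, mean(direct))
  expect_equal(ss2$summary$sd, sd(direct))
  expect_error(ssim_summary(imgs, imgs[1:2], c("a", "a")), "paired")
})

test_that("F1 matches a brute-force contingency count", {
  truth <- array(rbinom(160, 1, 0.3), c(10, 4, 4))
  expect_equal(f1_score(truth, truth), 1.0)
  expect_equal(f1_score(array(0, dim(truth)), truth), 0.0)
  set.seed(12)
  pred <- array(runif(160), c(10, 4, 4))
  got <- f1_score(pred, truth, threshold = 0.5)
  pb <- as.vector(pred) >= 0.5; tb <- as.vector(truth) == 1
  tp <- sum(pb & tb); fp <- sum(pb & !tb); fn <- sum(!pb & tb)
  expect_equal(got, 2 * tp / (2 * tp + fp + fn))
})

test_that("the Fourier pipeline removes DC, concentrates gratings and obeys Parseval", {
  ## constant image: all-zero power after mean removal
  sp0 <- fourier_spectrum(gray_image(matrix(0.4, 32, 32)))
  expect_lt(max(sp0$power), 1e-18)

  ## horizontal cosine at 0.125 cycles/pixel: power in the two conjugate bins
  n <- 32
  img <- gray_image(0.5 + 0.4 * cos(2 * pi * 0.125 * outer(rep(1, n), 0:(n - 1))))
  sp <- fourier_spectrum(img)
  ord <- order(sp$power, decreasing = TRUE)
  top2 <- arrayInd(ord[1:2], dim(sp$power))
  expect_equal(sort(abs(sp$fx[top2[, 2]])), c(0.125, 0.125))
  expect_equal(abs(sp$fy[top2[, 1]]), c(0, 0))
  expect_gt(sum(sp$power[ord[1:2]]) / sum(sp$power), 1 - 1e-9)

  ## Parseval: total power equals N^2 * biased variance
  m <- matrix(runif(n * n), n)
  spm <- fourier_spectrum(gray_image(m))
  v <- mean((m - mean(m))^2)
  expect_lt(abs(sum(spm$power) - n^2 * n^2 * v) / (n^4 * v), 1e-6)

  ## conjugate symmetry of the phase for real input
  ph <- spm$phase
  c0 <- n %/% 2 + 1
  for (k in 1:5) {
    expect_lt(abs(ph[c0 + k, c0 + 2] + ph[c0 - k, c0 - 2]) %% (2 * pi), 1e-6)
  }
})

test_that("radial profile peaks at a grating frequency and is flat for white noise", {
  n <- 32
  img <- gray_image(0.5 + 0.4 * cos(2 * pi * 0.25 * outer(rep(1, n), 0:(n - 1))))
  pr <- radial_power_profile(fourier_spectrum(img))
  expect_lt(abs(pr$freq[which.max(pr$power)] - 0.25), 1 / n)

  expect_true(all(radial_power_profile(
    list(power = matrix(0, n, n),
         freq = fourier_spectrum(gray_image(matrix(runif(n * n), n)))$freq)
  )$power == 0))

  ## ensemble of white-noise images: profile flat within +-20 % above 0.05 c/px
  prof <- 0
  for (s in 1:100) {
    set.seed(s)
    prof <- prof + radial_power_profile(
      fourier_spectrum(gray_image(matrix(runif(n * n), n))))$power
  }
  pr1 <- radial_power_profile(fourier_spectrum(gray_image(matrix(runif(n * n), n))))
  sel <- pr1$freq >= 0.05
  rel <- (prof / 100)[sel]
  expect_lt(max(abs(rel - mean(rel)) / mean(rel)), 0.2)
})

test_that("orientation histogram finds grating orientation and conserves power", {
  n <- 32
  ## vertical stripes (luminance varies along x): energy on the fx axis,
  ## i.e. the 90-degree-orthogonal orientation bin in frequency space
  img <- gray_image(0.5 + 0.4 * cos(2 * pi * 0.25 * outer(rep(1, n), 0:(n - 1))))
  sp <- fourier_spectrum(img)
  od <- orientational_power_distribution(sp, 36)
  expect_equal(od$angle_deg[which.max(od$power)], 2.5)  # fy = 0 sector

  mask <- !(outer(sp$fy == 0, sp$fx == 0, `&`)) & sp$freq <= 0.5 + 1e-12
  expect_lt(abs(sum(od$power) - sum(sp$power[mask])) /
            max(sum(sp$power[mask]), 1e-300), 1e-9)

  ## isotropic noise ensemble: no orientation dominates strongly
  acc <- 0
  for (s in 1:100) {
    set.seed(s + 500)
    acc <- acc + orientational_power_distribution(
      fourier_spectrum(gray_image(matrix(runif(64 * 64), 64))), 12)$power
  }
  expect_lt(max(acc) / min(acc), 1.5)
})

test_that("phase differences vanish on identity and follow the shift theorem", {
  img <- generate_image(image_style("pink_noise", seed = 8), 32, 32)
  pd <- phase_difference_profile(img, img)
  expect_true(all(pd$dphase < 1e-9))

  ## 1-pixel circular shift along columns: phase ramps as 2 pi f_x
  m <- unclass(img)
  shifted <- gray_image(m[, c(32, 1:31)])
  so <- fourier_spectrum(img); sd_ <- fourier_spectrum(shifted)
  ns <- asNamespace("vsdecode")
  dphi <- abs(ns$wrap_phase(so$phase - sd_$phase))
  c0 <- 32 %/% 2 + 1
  for (k in c(2, 5, 9, 13)) {
    f <- so$fx[c0 + k]
    expected <- abs(ns$wrap_phase(2 * pi * f))
    expect_lt(abs(dphi[c0, c0 + k] - expected) / expected, 0.05)
  }
})

test_that("evaluation reports aggregate profiles and export cleanly", {
  orig <- lapply(1:3, function(i) generate_image(image_style("mixture", seed = i),
                                                 16, 16))
  dec <- lapply(orig, function(im)
    photoreceptor_prefilter(im, 1.0))
  rep_ <- eval_report(dec, orig, rep("test", 3))
  expect_s3_class(rep_, "eval_report")
  expect_true(all(rep_$ssim$per_image$ssim <= 1))
  expect_equal(nrow(rep_$phase_difference),
               nrow(phase_difference_profile(orig[[1]], dec[[1]])))
  f <- tempfile(fileext = ".json")
  write_eval_report(rep_, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.json$", "_phase.csv", f)))
  p <- plot_ssim_violin(rep_)
  expect_s3_class(p, "ggplot")
  unlink(c(f, sub("\\.json$", "_radial.csv", f),
           sub("\\.json$", "_orientation.csv", f),
           sub("\\.json$", "_phase.csv", f)))
})
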