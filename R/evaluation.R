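#' SSIM settings
#'
#' Windowed structural-similarity configuration: 11 x 11 Gaussian window
#' with sigma 1.5, stability constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`
#' with `K1 = 0.01`, `K2 = 0.03` and dynamic range `L = 1` (images in
#' `[0, 1]`). `window = "global"` uses a single uniform window over the
#' whole image (the closed-form single-window statistic, useful for
#' hand-checked toy cases).
#'
#' @param window `"gaussian"` or `"global"`.
#' @param win_size Window side (odd, default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param K1,K2 Stability constants.
#' @param L Dynamic range (default 1).
#' @return An `ssim_settings` list.
#' @export
ssim_settings <- function(window = "gaussian", win_size = 11L, sigma = 1.5,
                          K1 = 0.01, K2 = 0.03, L = 1.0) {
  structure(list(window = window, win_size = as.integer(win_size),
                 sigma = sigma, K1 = K1, K2 = K2, L = L),
            class = "ssim_settings")
}

## truncated normalized 2-D Gaussian window
ssim_window <- function(s) {
  r <- (s$win_size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * s$sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

## FFT 2-D full convolution (output size n + k - 1)
fft_conv2_full <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  px <- matrix(0, nr, nc); px[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / (nr * nc)
}

## valid part of the 2-D convolution (window fully inside the image)
conv2_valid <- function(x, k) {
  full <- fft_conv2_full(x, k)
  full[nrow(k):nrow(x), ncol(k):ncol(x), drop = FALSE]
}

## SSIM between two matrices; optionally the gradient wrt `a`.
ssim_with_grad <- function(a, b, s = ssim_settings(), grad = TRUE) {
  C1 <- (s$K1 * s$L)^2; C2 <- (s$K2 * s$L)^2
  if (identical(s$window, "global")) {
    mu1 <- mean(a); mu2 <- mean(b)
    v1 <- mean(a^2) - mu1^2; v2 <- mean(b^2) - mu2^2
    cv <- mean(a * b) - mu1 * mu2
    val <- ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
      ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
    return(list(value = val, map = matrix(val, 1, 1), grad = NULL))
  }
  G <- ssim_window(s)
  mu1 <- conv2_valid(a, G); mu2 <- conv2_valid(b, G)
  m11 <- conv2_valid(a * a, G); m22 <- conv2_valid(b * b, G)
  m12 <- conv2_valid(a * b, G)
  s1 <- m11 - mu1^2; s2 <- m22 - mu2^2; s12 <- m12 - mu1 * mu2
  A1 <- 2 * mu1 * mu2 + C1; A2 <- 2 * s12 + C2
  B1 <- mu1^2 + mu2^2 + C1; B2 <- s1 + s2 + C2
  S <- (A1 * A2) / (B1 * B2)
  out <- list(value = mean(S), map = S, grad = NULL)
  if (grad) {
    N <- length(S)
    dS_dm1 <- (2 * mu2 * (A2 - A1)) / (B1 * B2) -
      2 * mu1 * S * (1 / B1 - 1 / B2)
    dS_dm2 <- -S / B2          # wrt G*(a^2)
    dS_dm3 <- 2 * A1 / (B1 * B2)  # wrt G*(a b)
    g1 <- fft_conv2_full(dS_dm1, G)
    g2 <- fft_conv2_full(dS_dm2, G)
    g3 <- fft_conv2_full(dS_dm3, G)
    out$grad <- (g1 + 2 * a * g2 + b * g3) / N
  }
  out
}

#' Structural similarity index between two images
#'
#' Windowed SSIM (luminance, contrast and structure terms with the
#' configured stability constants), averaged over window positions where
#' the window lies fully inside the image.
#'
#' @param a,b [gray_image()]s (or matrices) of equal dimensions.
#' @param settings An [ssim_settings()].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, settings = ssim_settings()) {
  a <- as.matrix(unclass(a)); b <- as.matrix(unclass(b))
  if (!all(dim(a) == dim(b))) stop("ssim: image dimensions differ")
  ssim_with_grad(a, b, settings, grad = FALSE)$value
}

#' Per-split SSIM summary of decoded images
#'
#' @param decoded,originals Paired lists of images.
#' @param split Character/factor vector of split labels (e.g. `"train"`,
#'   `"test"`), one per pair.
#' @param settings An [ssim_settings()].
#' @return List with `per_image` (data.frame `split`, `ssim`) and `summary`
#'   (data.frame `split`, `mean`, `sd`, `n`; sample standard deviation).
#' @export
ssim_summary <- function(decoded, originals, split, settings = ssim_settings()) {
  if (length(decoded) != length(originals) || length(decoded) != length(split))
    stop("ssim_summary: decoded, originals and split must be paired")
  vals <- vapply(seq_along(decoded),
                 function(i) ssim(decoded[[i]], originals[[i]], settings), 0.0)
  per <- data.frame(split = as.character(split), ssim = vals)
  agg <- do.call(rbind, lapply(split(per$ssim, per$split), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  agg <- data.frame(split = rownames(agg), agg, row.names = NULL)
  list(per_image = per, summary = agg)
}

#' F1 score of binarized spike predictions
#'
#' Predictions are thresholded; `F1 = 2 TP / (2 TP + FP + FN)`, defined as
#' 0 when the denominator vanishes (no positives anywhere).
#'
#' @param pred_probs Array of probabilities, same shape as `truth`.
#' @param truth Binary array.
#' @param threshold Binarization threshold (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(pred_probs, truth, threshold = 0.5) {
  p <- unclass(pred_probs); t <- unclass(truth)
  if (!all(dim(p) == dim(t))) stop("f1_score: shapes differ")
  pb <- p >= threshold
  tp <- sum(pb & t > 0)
  fp <- sum(pb & t <= 0)
  fn <- sum(!pb & t > 0)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

#' Centered 2-D Fourier power and phase of an image
#'
#' The image mean is removed before the transform so the DC term does not
#' dominate the power profiles. Output maps are centered (zero frequency in
#' the middle) with frequency axes in cycles/pixel.
#'
#' @param img A square [gray_image()] (or matrix).
#' @return List `power` (squared magnitude), `phase` (radians in
#'   `(-pi, pi]`), `fx`, `fy` (cycles/pixel for columns/rows), `freq`
#'   (radial frequency map).
#' @export
fourier_spectrum <- function(img) {
  m <- as.matrix(unclass(img))
  if (nrow(m) != ncol(m)) stop("fourier_spectrum: image must be square")
  n <- nrow(m)
  F <- stats::fft(m - mean(m))
  shift <- function(x) {
    h <- n %/% 2
    idx <- c((h + 1):n, 1:h)
    x[idx, idx]
  }
  Fc <- shift(F)
  f1 <- (seq_len(n) - 1 - n %/% 2) / n
  list(power = Mod(Fc)^2, phase = Arg(Fc), fx = f1, fy = f1,
       freq = sqrt(outer(f1^2, f1^2, `+`)))
}

#' Radially averaged power profile
#'
#' Mean power in annular bins of width `1/N` cycles/pixel from 0 to the
#' Nyquist frequency 0.5.
#'
#' @param spec Output of [fourier_spectrum()] (or a centered power matrix
#'   plus `freq` map in a list).
#' @return data.frame `freq` (bin centers, cycles/pixel), `power`.
#' @export
radial_power_profile <- function(spec) {
  n <- nrow(spec$power)
  width <- 1 / n
  bins <- floor(spec$freq / width)
  keep <- spec$freq <= 0.5 + 1e-12
  idx <- bins[keep]
  pw <- tapply(spec$power[keep], idx, mean)
  centers <- (as.numeric(names(pw)) + 0.5) * width
  data.frame(freq = centers, power = as.numeric(pw))
}

#' Orientational power distribution
#'
#' Power summed in angular sectors of `[0, 180)` degrees (the real-image
#' spectrum is conjugate-symmetric, so the plane folds onto a half-turn).
#' Only frequencies within the Nyquist disc (radial frequency <= 0.5
#' cycles/pixel) are counted -- the square's corners sample orientations
#' unevenly -- and the DC bin is excluded.
#'
#' @param spec Output of [fourier_spectrum()].
#' @param n_angle_bins Number of sectors (default 36, i.e. 5 degrees).
#' @return data.frame `angle_deg` (bin centers), `power`.
#' @export
orientational_power_distribution <- function(spec, n_angle_bins = 36L) {
  n <- nrow(spec$power)
  ang <- atan2(outer(spec$fy, rep(1, n)), outer(rep(1, n), spec$fx))
  deg <- (ang * 180 / pi) %% 180
  mask <- !(outer(spec$fy == 0, spec$fx == 0, `&`)) & spec$freq <= 0.5 + 1e-12
  width <- 180 / n_angle_bins
  bin <- pmin(floor(deg / width), n_angle_bins - 1L)
  pw <- tapply(spec$power[mask], bin[mask], sum)
  out <- data.frame(angle_deg = (seq_len(n_angle_bins) - 0.5) * width,
                    power = 0)
  out$power[as.integer(names(pw)) + 1L] <- as.numeric(pw)
  out
}

## wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Phase difference between original and decoded images vs frequency
#'
#' Per radial frequency bin, the mean absolute wrapped phase difference,
#' weighted by the original image's spectral power (phases at near-zero
#' power are noise).
#'
#' @param orig,decoded Equal-size square images.
#' @return data.frame `freq` (bin centers, cycles/pixel), `dphase`
#'   (radians in `[0, pi]`).
#' @export
phase_difference_profile <- function(orig, decoded) {
  so <- fourier_spectrum(orig)
  sd_ <- fourier_spectrum(decoded)
  dphi <- abs(wrap_phase(so$phase - sd_$phase))
  n <- nrow(so$power)
  width <- 1 / n
  keep <- so$freq <= 0.5 + 1e-12 & so$freq > 0
  bins <- floor(so$freq / width)[keep]
  w <- so$power[keep]; d <- dphi[keep]
  num <- tapply(w * d, bins, sum)
  den <- tapply(w, bins, sum)
  centers <- (as.numeric(names(num)) + 0.5) * width
  data.frame(freq = centers,
             dphase = as.numeric(num) / pmax(as.numeric(den), 1e-300))
}

#' Full evaluation report for decoded images
#'
#' SSIM distributions per split plus the Fourier-domain profiles (radial
#' power, orientational power, phase difference), each computed per image
#' and averaged across images.
#'
#' @param decoded,originals Paired image lists.
#' @param split Split label per pair.
#' @param settings An [ssim_settings()].
#' @return An `eval_report` list: `ssim` (see [ssim_summary()]),
#'   `radial_power_orig`, `radial_power_decoded`,
#'   `orientation_orig`, `orientation_decoded`, `phase_difference`.
#' @export
eval_report <- function(decoded, originals, split, settings = ssim_settings()) {
  ss <- ssim_summary(decoded, originals, split, settings)
  avg_profiles <- function(imgs, fun) {
    profs <- lapply(imgs, function(im) fun(fourier_spectrum(im)))
    out <- profs[[1]]
    out[[2]] <- rowMeans(vapply(profs, function(p) p[[2]], numeric(nrow(out))))
    out
  }
  phase <- lapply(seq_along(decoded), function(i)
    phase_difference_profile(originals[[i]], decoded[[i]]))
  pd <- phase[[1]]
  pd$dphase <- rowMeans(vapply(phase, function(p) p$dphase, numeric(nrow(pd))))
  structure(list(
    ssim = ss,
    radial_power_orig = avg_profiles(originals, radial_power_profile),
    radial_power_decoded = avg_profiles(decoded, radial_power_profile),
    orientation_orig = avg_profiles(originals, orientational_power_distribution),
    orientation_decoded = avg_profiles(decoded, orientational_power_distribution),
    phase_difference = pd), class = "eval_report")
}

#' Export an evaluation report as JSON (+ CSV profiles)
#'
#' @param report An `eval_report`.
#' @param path JSON destination; CSV profiles are written alongside with
#'   suffixes `_radial.csv`, `_orientation.csv`, `_phase.csv`.
#' @return `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  base <- sub("\\.json$", "", path)
  utils::write.csv(report$radial_power_decoded,
                   paste0(base, "_radial.csv"), row.names = FALSE)
  utils::write.csv(report$orientation_decoded,
                   paste0(base, "_orientation.csv"), row.names = FALSE)
  utils::write.csv(report$phase_difference,
                   paste0(base, "_phase.csv"), row.names = FALSE)
  invisible(path)
}

#' Violin plot of SSIM distributions per split
#'
#' @param ss Result of [ssim_summary()] (or an `eval_report`).
#' @return A ggplot object.
#' @export
plot_ssim_violin <- function(ss) {
  if (inherits(ss, "eval_report")) ss <- ss$ssim
  ggplot2::ggplot(ss$per_image,
                  ggplot2::aes(x = split, y = ssim)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "SSIM") +
    ggplot2::theme_minimal()
}

#' Radially averaged power profiles of original vs decoded images
#'
#' @param report An `eval_report`.
#' @return A ggplot object (log10 power vs cycles/pixel).
#' @export
plot_radial_power <- function(report) {
  d <- rbind(cbind(report$radial_power_orig, which = "original"),
             cbind(report$radial_power_decoded, which = "decoded"))
  ggplot2::ggplot(d, ggplot2::aes(x = freq, y = power, colour = which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (cycles/pixel)", y = "power") +
    ggplot2::theme_minimal()
}

#' Phase-difference profile plot
#'
#' @param report An `eval_report`.
#' @return A ggplot object.
#' @export
plot_phase_difference <- function(report) {
  ggplot2::ggplot(report$phase_difference,
                  ggplot2::aes(x = freq, y = dphase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (cycles/pixel)",
                  y = "|phase difference| (rad)") +
    ggplot2::theme_minimal()
}
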