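#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of luminance values in `[0, 1]`
#' (rows x cols). It is the visual stimulus fed to the retinomorphic
#' encoder and the target of the decoders.
#'
#' @param pixels Numeric matrix with finite values in `[0, 1]`.
#' @return A `gray_image` object (a classed matrix).
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("gray_image: non-finite pixel values")
  if (any(pixels < 0 | pixels > 1)) stop("gray_image: values must lie in [0, 1]")
  structure(pixels, class = c("gray_image", class(pixels)))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Style descriptor for the synthetic image generator
#'
#' Procedural stand-in for natural photographs: broadband `1/f`-type
#' textures, smooth blobs, hard-edged shapes, or a mixture of all three
#' (the default training material). Deterministic given `seed`.
#'
#' @param kind One of `"constant"`, `"pink_noise"`, `"blobs"`, `"shapes"`,
#'   `"mixture"`.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   `(style, dims)`.
#' @param spectral_slope Log-log slope of the radially averaged power
#'   spectrum for the `pink_noise` texture (natural scenes are near -2).
#' @param level Gray level for `kind = "constant"`.
#' @param n_blobs,n_shapes Element counts for the respective styles.
#' @return An `image_style` list.
#' @export
image_style <- function(kind = "mixture", seed = 1L, spectral_slope = -2,
                        level = 0.5, n_blobs = 6L, n_shapes = 4L) {
  kinds <- c("constant", "pink_noise", "blobs", "shapes", "mixture")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("image_style: unknown kind; must be one of ",
         paste(kinds, collapse = ", "))
  structure(list(kind = kind, seed = as.integer(seed),
                 spectral_slope = spectral_slope, level = level,
                 n_blobs = as.integer(n_blobs), n_shapes = as.integer(n_shapes)),
            class = "image_style")
}

## broadband texture with power-spectrum slope `alpha` (power ~ f^alpha)
gen_pink_noise <- function(h, w, alpha) {
  wn <- matrix(stats::rnorm(h * w), h, w)
  fx <- ifelse(seq_len(w) - 1 <= w / 2, seq_len(w) - 1, seq_len(w) - 1 - w) / w
  fy <- ifelse(seq_len(h) - 1 <= h / 2, seq_len(h) - 1, seq_len(h) - 1 - h) / h
  f <- sqrt(outer(fy^2, fx^2, `+`))
  amp <- f^(alpha / 2)
  amp[1, 1] <- 0  # zero DC; level set by rescale
  Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / (h * w)
}

gen_blobs <- function(h, w, n) {
  img <- matrix(0, h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    sy <- stats::runif(1, 0.04, 0.2) * h; sx <- stats::runif(1, 0.04, 0.2) * w
    a <- stats::runif(1, -1, 1)
    img <- img + a * outer(exp(-(ys - cy)^2 / (2 * sy^2)),
                           exp(-(xs - cx)^2 / (2 * sx^2)))
  }
  img
}

gen_shapes <- function(h, w, n) {
  img <- matrix(stats::runif(1, 0.3, 0.7), h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  for (i in seq_len(n)) {
    lev <- stats::runif(1)
    if (stats::runif(1) < 0.5) {  # rectangle
      r0 <- sort(sample.int(h, 2)); c0 <- sort(sample.int(w, 2))
      img[r0[1]:r0[2], c0[1]:c0[2]] <- lev
    } else {                      # disc
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      rad <- stats::runif(1, 0.05, 0.25) * min(h, w)
      mask <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= rad^2
      img[mask] <- lev
    }
  }
  img
}

rescale01 <- function(m) {
  rng <- range(m)
  if (diff(rng) < .Machine$double.eps) return(matrix(clip01(rng[1]), nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

#' Generate a synthetic natural-like grayscale image
#'
#' Deterministic given `(style, height, width)`: the style's seed is combined
#' with the dimensions so repeated calls are bit-identical. All styles except
#' `constant` are rescaled to span `[0, 1]`.
#'
#' @param style An [image_style()].
#' @param height,width Image dimensions in pixels (at least 8).
#' @return A [gray_image()].
#' @export
generate_image <- function(style, height = 120L, width = 120L) {
  if (!inherits(style, "image_style")) style <- do.call(image_style, as.list(style))
  if (height < 8 || width < 8) stop("generate_image: dimensions must be >= 8")
  h <- as.integer(height); w <- as.integer(width)
  px <- with_seed(derive_seed(style$seed, "genimg", style$kind, h, w), {
    switch(style$kind,
      constant   = matrix(clip01(style$level), h, w),
      pink_noise = rescale01(gen_pink_noise(h, w, style$spectral_slope)),
      blobs      = rescale01(gen_blobs(h, w, style$n_blobs)),
      shapes     = rescale01(gen_shapes(h, w, style$n_shapes)),
      mixture    = {
        base <- rescale01(gen_pink_noise(h, w, style$spectral_slope))
        bl <- gen_blobs(h, w, style$n_blobs)
        sh <- gen_shapes(h, w, style$n_shapes)
        rescale01(0.5 * base + 0.3 * rescale01(bl) + 0.2 * sh)
      })
  })
  gray_image(px)
}

#' Photoreceptor-layer spatial prefilter
#'
#' Gaussian low-pass emulating the optical blur of the photoreceptor cell
#' layer, applied to stimuli before retinal encoding. Unit DC gain, reflect
#' boundary; the output is clipped to `[0, 1]`.
#'
#' @param img A [gray_image()].
#' @param sigma_px Gaussian standard deviation in pixels (> 0, default 1).
#' @return Filtered [gray_image()].
#' @export
photoreceptor_prefilter <- function(img, sigma_px = 1.0) {
  if (sigma_px <= 0) stop("photoreceptor_prefilter: sigma_px must be > 0")
  gray_image(clip01(gaussian_blur(unclass(img), sigma_px)))
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8- or 16-bit files are rescaled to `[0, 1]`; RGB(A) input is converted to
#' luminance by channel averaging.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("read_gray_image: unsupported extension '", ext, "'"))
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  gray_image(clip01(a))
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img A [gray_image()].
#' @param path Destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- clip01(unclass(img))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path),
    stop("write_gray_image: unsupported extension '", ext, "'"))
  invisible(path)
}

#' Bilinear resampling onto the encoder grid
#'
#' Used to bring externally supplied photographs to the configured grid
#' (default 120 x 120) before prefiltering and encoding.
#'
#' @param img A [gray_image()].
#' @param height,width Target dimensions.
#' @return A [gray_image()] of size `height x width`.
#' @export
resample_image <- function(img, height = 120L, width = 120L) {
  m <- unclass(img)
  sr <- nrow(m); sc <- ncol(m)
  ry <- (seq_len(height) - 0.5) / height * sr + 0.5
  rx <- (seq_len(width) - 0.5) / width * sc + 0.5
  y0 <- clip01(floor(ry), 1, sr); y1 <- clip01(y0 + 1, 1, sr)
  x0 <- clip01(floor(rx), 1, sc); x1 <- clip01(x0 + 1, 1, sc)
  wy <- ry - y0; wx <- rx - x0
  out <- (1 - wy) * ((m[y0, x0, drop = FALSE] * rep(1 - wx, each = height)) +
                     (m[y0, x1, drop = FALSE] * rep(wx, each = height))) +
         wy * ((m[y1, x0, drop = FALSE] * rep(1 - wx, each = height)) +
               (m[y1, x1, drop = FALSE] * rep(wx, each = height)))
  gray_image(clip01(out))
}
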