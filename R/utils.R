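#' @useDynLib vsdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft nextn rnorm runif sd cor coef optim
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 32-bit string/scalar hash used to fan a global seed out to
## per-stage and per-index seeds, and to digest configurations. FNV-1a on the
## UTF-8 bytes, folded into [0, 2^31 - 1].
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    ## XOR with a byte only touches the low 8 bits; keep everything in doubles
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime 16777619, split into
    ## 16-bit halves so every intermediate stays exactly representable
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' A single run seed fans out to per-stage and per-item seeds so each stage
#' can be re-run independently yet reproducibly. The result is always a
#' non-negative integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param ... Labels (stage name, item index, ...) distinguishing the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  as.integer(fnv1a32(paste(c(seed, ...), collapse = "/")) %% 2147483647)
}

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Digest of an arbitrary configuration list: canonical JSON, then FNV hash
## rendered in hex. Used to stamp artifacts and dataset manifests.
config_digest <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  sprintf("%08x", as.integer(fnv1a32(as.character(js)) %% 2147483647))
}

## --- small numerics shared across modules -----------------------------------

## Normalized 1-D discrete Gaussian, radius ceil(4*sigma) (DC gain exactly 1).
gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Reflect-pad a matrix by (rpad, cpad) on each side (edge mirror, no repeat
## of the border pixel beyond the image: classic "reflect" indexing).
reflect_pad <- function(m, rpad, cpad) {
  ridx <- reflect_index(seq(1 - rpad, nrow(m) + rpad), nrow(m))
  cidx <- reflect_index(seq(1 - cpad, ncol(m) + cpad), ncol(m))
  m[ridx, cidx, drop = FALSE]
}

## mirror indexing i in Z onto 1..n (reflection without border repeat)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1) %% (2 * (n - 1))
  as.integer(ifelse(p < n, p + 1, 2 * n - 1 - p))
}

## Separable Gaussian blur with reflect boundary and unit DC gain.
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  p <- reflect_pad(m, r, r)
  ## rows then columns, valid part only
  p <- apply(p, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  p <- t(apply(p, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  p[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

## Causal discrete convolution of each column of `x` (time down rows) with
## kernel `k` (k[1] acts at lag 0), FFT-based. Returns same number of rows.
causal_conv_cols <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x); m <- length(k)
  L <- stats::nextn(n + m - 1L, 2)
  kf <- stats::fft(c(k, numeric(L - m)))
  xf <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  out <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

## clip to [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
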