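#' Retinomorphic encoder configuration
#'
#' Parameters of the off-transient alpha retinal-ganglion-cell emulation:
#' a delayed difference of two Gaussian spatial filters (center minus
#' delayed surround, both with unit DC gain), a zero-sum biphasic temporal
#' kernel (difference of two alpha functions), and Izhikevich spike
#' generation on a unit grid.
#'
#' @param grid `(rows, cols)` of the encoder unit grid (default 120 x 120).
#' @param dt_ms Simulation step in ms (default 0.5; must be <= 1 for the
#'   forward-Euler neuron update to be stable).
#' @param center_sigma_px,surround_sigma_px DoG sigmas in pixels; the
#'   surround must be wider than the center.
#' @param surround_delay_ms Delay of the surround signal relative to the
#'   center, in ms.
#' @param tau_fast_ms,tau_slow_ms Time constants of the two alpha functions
#'   forming the biphasic temporal kernel.
#' @param kernel_support_ms Length of the sampled biphasic kernel.
#' @param gain Drive gain mapping the filtered generator signal to the
#'   Izhikevich input current.
#' @param polarity Only `"off"` (luminance decrements excite) is provided.
#' @param izh_a,izh_b,izh_c,izh_d Izhikevich parameters (regular-spiking
#'   defaults 0.02, 0.2, -65, 8).
#' @param v_peak Spike detection threshold in mV (30 mV convention).
#' @param gray_level Full-field adaptation gray level.
#' @param gray_ms Adaptation duration before the image switch.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(grid = c(120L, 120L), dt_ms = 0.5,
                           center_sigma_px = 1.2, surround_sigma_px = 3.0,
                           surround_delay_ms = 5, tau_fast_ms = 10,
                           tau_slow_ms = 40, kernel_support_ms = 250,
                           gain = 40, polarity = "off",
                           izh_a = 0.02, izh_b = 0.2, izh_c = -65, izh_d = 8,
                           v_peak = 30, gray_level = 0.5, gray_ms = 200) {
  if (dt_ms <= 0) stop("encoder_config: dt_ms must be > 0")
  if (surround_sigma_px <= center_sigma_px)
    stop("encoder_config: surround sigma must exceed center sigma")
  if (!identical(polarity, "off")) stop("encoder_config: only 'off' polarity is implemented")
  cfg <- list(grid = as.integer(grid), dt_ms = dt_ms,
              center_sigma_px = center_sigma_px,
              surround_sigma_px = surround_sigma_px,
              surround_delay_ms = surround_delay_ms,
              tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
              kernel_support_ms = kernel_support_ms, gain = gain,
              polarity = polarity, izh_a = izh_a, izh_b = izh_b,
              izh_c = izh_c, izh_d = izh_d, v_peak = v_peak,
              gray_level = gray_level, gray_ms = gray_ms)
  class(cfg) <- "encoder_config"
  cfg
}

#' Biphasic temporal kernel of the encoder
#'
#' Difference of two alpha functions `(t/tau) exp(1 - t/tau)` with fast and
#' slow time constants, scaled so the discrete samples sum exactly to zero
#' (a sustained input produces no sustained drive) and the peak is 1.
#'
#' @param cfg An [encoder_config()].
#' @return Numeric vector of kernel samples at `cfg$dt_ms`.
#' @export
biphasic_kernel <- function(cfg) {
  t <- seq(0, cfg$kernel_support_ms, by = cfg$dt_ms)
  alpha <- function(tau) (t / tau) * exp(1 - t / tau)
  kf <- alpha(cfg$tau_fast_ms)
  ks <- alpha(cfg$tau_slow_ms)
  k <- kf - (sum(kf) / sum(ks)) * ks   # exact discrete zero sum
  k / max(abs(k))
}

## coerce a frame stream to array (n_t, rows, cols)
as_frame_array <- function(frames) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    arr <- array(0, c(length(frames), d[1], d[2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    arr
  } else if (length(dim(frames)) == 3L) frames
  else array(frames, c(1L, dim(frames)))
}

#' DoG generator signal of a frame stream
#'
#' Per-unit generator signal `g(t) = Gc * I(t) - Gs * I(t - delay)`, the
#' center and delayed-surround Gaussian filtrates (both unit DC gain),
#' sign-inverted for off polarity so luminance decrements excite. Frames
#' before the stream start are taken equal to the first frame.
#'
#' @param frames List of matrices, or array `(n_t, rows, cols)`, sampled at
#'   `cfg$dt_ms`.
#' @param cfg An [encoder_config()].
#' @return Array `(n_t, rows, cols)` of generator signals.
#' @export
dog_generator_signal <- function(frames, cfg) {
  arr <- as_frame_array(frames)
  if (!all(dim(arr)[2:3] == cfg$grid))
    stop("dog_generator_signal: frame dims do not match encoder grid")
  nt <- dim(arr)[1]
  dsteps <- as.integer(round(cfg$surround_delay_ms / cfg$dt_ms))
  ## blur each distinct frame once (streams are typically piecewise constant)
  cblur <- vector("list", nt); sblur <- vector("list", nt)
  prev <- -1L
  for (i in seq_len(nt)) {
    if (prev > 0 && identical(arr[i, , ], arr[prev, , ])) {
      cblur[[i]] <- cblur[[prev]]; sblur[[i]] <- sblur[[prev]]
    } else {
      cblur[[i]] <- gaussian_blur(arr[i, , ], cfg$center_sigma_px)
      sblur[[i]] <- gaussian_blur(arr[i, , ], cfg$surround_sigma_px)
      prev <- i
    }
  }
  out <- array(0, dim(arr))
  sgn <- if (cfg$polarity == "off") -1 else 1
  for (i in seq_len(nt)) {
    j <- max(1L, i - dsteps)
    out[i, , ] <- sgn * (cblur[[i]] - sblur[[j]])
  }
  out
}

#' Causal biphasic temporal filtering
#'
#' Convolves each unit's signal with the zero-sum biphasic kernel
#' (causally: the output at `t` depends on inputs at `<= t`).
#'
#' @param signal Numeric vector, matrix (time in rows, units in columns), or
#'   array `(n_t, rows, cols)`, sampled at `cfg$dt_ms`.
#' @param cfg An [encoder_config()].
#' @return Filtered signal, same shape as the input.
#' @export
biphasic_filter <- function(signal, cfg) {
  k <- biphasic_kernel(cfg)
  d <- dim(signal)
  if (is.null(d)) {
    as.numeric(causal_conv_cols(matrix(signal, ncol = 1), k))
  } else if (length(d) == 2L) {
    causal_conv_cols(signal, k)
  } else {
    out <- causal_conv_cols(matrix(signal, d[1]), k)
    array(out, d)
  }
}

#' One forward-Euler Izhikevich update
#'
#' `v' = v + dt (0.04 v^2 + 5 v + 140 - u + I)`, `u' = u + dt a (b v - u)`;
#' if the updated `v` reaches `v_peak` a spike is flagged and the reset
#' `v <- c`, `u <- u + d` is applied. Vectorized over units.
#'
#' @param state List with numeric `v` and `u` (membrane and recovery).
#' @param input_current Drive current (scalar or per-unit vector).
#' @param dt_ms Step in ms (<= 1 for stability).
#' @param cfg An [encoder_config()].
#' @return List `(state = list(v, u), spiked = logical)`.
#' @export
izhikevich_step <- function(state, input_current, dt_ms, cfg) {
  if (dt_ms > 1) stop("izhikevich_step: dt_ms must be <= 1 ms")
  v <- state$v; u <- state$u
  vn <- v + dt_ms * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  un <- u + dt_ms * cfg$izh_a * (cfg$izh_b * v - u)
  if (!all(is.finite(vn)) || !all(is.finite(un)))
    stop("izhikevich_step: non-finite state (diverging drive; reduce gain or dt)")
  spiked <- vn >= cfg$v_peak
  vn[spiked] <- cfg$izh_c
  un[spiked] <- un[spiked] + cfg$izh_d
  list(state = list(v = vn, u = un), spiked = spiked)
}

#' Encode an image into retinal spike events
#'
#' Presents a full-field gray adaptation field followed by the image, runs
#' the DoG -> biphasic -> gain -> Izhikevich pipeline on every grid unit at
#' `cfg$dt_ms`, and collects spikes for `record_ms` after the switch. The
#' stimulus stream is piecewise constant, which the implementation exploits:
#' the generator signal takes one value during the surround delay and one
#' afterwards, so only three spatial filtrates are ever computed.
#'
#' @param image A [gray_image()] on the encoder grid.
#' @param cfg An [encoder_config()].
#' @param gray_ms Adaptation duration before the switch (default from `cfg`).
#' @param record_ms Recording window after the switch (default 150 ms).
#' @return A `spike_events` data.frame with columns `unit_row`, `unit_col`,
#'   `time_ms` (time relative to the image switch, in `[0, record_ms)`),
#'   with the grid and window stored as attributes.
#' @export
encode_stream <- function(image, cfg, gray_ms = cfg$gray_ms, record_ms = 150) {
  m <- unclass(image)
  if (!all(dim(m) == cfg$grid)) stop("encode_stream: image does not match encoder grid")
  dt <- cfg$dt_ms
  n_units <- prod(cfg$grid)
  n_gray <- as.integer(round(gray_ms / dt))
  n_rec <- as.integer(round(record_ms / dt))
  n_tot <- n_gray + n_rec
  dsteps <- as.integer(round(cfg$surround_delay_ms / dt))
  sgn <- if (cfg$polarity == "off") -1 else 1

  cimg <- gaussian_blur(m, cfg$center_sigma_px)
  simg <- gaussian_blur(m, cfg$surround_sigma_px)
  ## generator signal phases (gray field filters to the gray level exactly)
  g1 <- sgn * as.vector(cimg - cfg$gray_level)  # switch .. switch+delay
  g2 <- sgn * as.vector(cimg - simg)            # after the surround delay

  sig <- matrix(0, n_tot, n_units)
  if (dsteps > 0 && n_gray + 1 <= n_tot) {
    i1 <- seq(n_gray + 1, min(n_gray + dsteps, n_tot))
    sig[i1, ] <- rep(g1, each = length(i1))
  }
  if (n_gray + dsteps + 1 <= n_tot) {
    i2 <- (n_gray + dsteps + 1):n_tot
    sig[i2, ] <- rep(g2, each = length(i2))
  }
  drive <- cfg$gain * causal_conv_cols(sig, biphasic_kernel(cfg))

  v <- rep(-65, n_units); u <- cfg$izh_b * v
  state <- list(v = v, u = u)
  hit_unit <- integer(0); hit_time <- numeric(0)
  for (i in seq_len(n_tot)) {
    st <- izhikevich_step(state, drive[i, ], dt, cfg)
    state <- st$state
    if (i > n_gray && any(st$spiked)) {
      t_rel <- (i - n_gray) * dt - dt  # spike assigned to the step start
      idx <- which(st$spiked)
      hit_unit <- c(hit_unit, idx)
      hit_time <- c(hit_time, rep(t_rel, length(idx)))
    }
  }
  keep <- hit_time >= 0 & hit_time < record_ms
  ev <- data.frame(unit_row = ((hit_unit[keep] - 1L) %% cfg$grid[1]) + 1L,
                   unit_col = ((hit_unit[keep] - 1L) %/% cfg$grid[1]) + 1L,
                   time_ms = hit_time[keep])
  ev <- ev[order(ev$unit_col, ev$unit_row, ev$time_ms), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("spike_events", "data.frame"),
            grid = cfg$grid, record_ms = record_ms)
}

#' Bin spike events into a binary spike-image stream
#'
#' Half-open 5 ms bins `[k b, (k+1) b)`; several spikes of a unit within one
#' bin saturate to 1, so the stream is binary and usable as a
#' binary-cross-entropy target.
#'
#' @param events A `spike_events` data.frame from [encode_stream()].
#' @param bin_ms Bin width in ms (must divide `record_ms` exactly).
#' @param record_ms Recording window; defaults to the events attribute.
#' @return A `spike_stream`: binary array `(n_frames, rows, cols)` with
#'   attribute `bin_ms`.
#' @export
bin_spikes <- function(events, bin_ms = 5, record_ms = attr(events, "record_ms")) {
  grid <- attr(events, "grid")
  if (is.null(grid)) stop("bin_spikes: events carry no grid attribute")
  nf <- record_ms / bin_ms
  if (abs(nf - round(nf)) > 1e-9)
    stop("bin_spikes: record_ms must be an exact multiple of bin_ms")
  nf <- as.integer(round(nf))
  arr <- array(0, c(nf, grid[1], grid[2]))
  if (nrow(events) > 0) {
    f <- floor(events$time_ms / bin_ms) + 1L
    ok <- f >= 1L & f <= nf
    arr[cbind(f[ok], events$unit_row[ok], events$unit_col[ok])] <- 1
  }
  structure(arr, class = "spike_stream", bin_ms = bin_ms)
}

#' @export
print.spike_stream <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<spike_stream %d frames x %d x %d, %d spikes, bin %g ms>\n",
              d[1], d[2], d[3], sum(x), attr(x, "bin_ms")))
  invisible(x)
}
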