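#' Pulse train
#'
#' Sorted pulse onset times (ms) within a recording window, the input
#' `s(t)` of the Wiener system (rendered as unit impulses on the 1 ms
#' identification grid; physical current amplitude is metadata only).
#'
#' @param times_ms Strictly increasing onset times in `[0, duration_ms)`.
#' @param duration_ms Window length in ms (default 1000).
#' @return A `pulse_train` object.
#' @export
pulse_train <- function(times_ms = numeric(0), duration_ms = 1000) {
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) > 1 && any(diff(times_ms) <= 0))
    stop("pulse_train: times must be strictly increasing")
  if (length(times_ms) > 0 && (min(times_ms) < 0 || max(times_ms) >= duration_ms))
    stop("pulse_train: times must lie in [0, duration_ms)")
  structure(list(times_ms = times_ms, duration_ms = duration_ms),
            class = "pulse_train")
}

#' Sampled Lorentzian broadening kernel
#'
#' `L(t) = 1 / (1 + (t / gamma)^2)` sampled symmetrically on
#' `[-support_ms, support_ms]`; peak value 1, not renormalized. Accounts for
#' the temporal broadening of each stimulation impulse; the continuous-time
#' full width at half maximum is `2 gamma`.
#'
#' @param gamma_ms Width parameter in ms (> 0; default 0.25).
#' @param dt_ms Sampling step (default 1).
#' @param support_ms Half support; must be at least `6 gamma`.
#' @return Numeric vector with attribute `t_ms` of sample times.
#' @export
lorentzian_kernel <- function(gamma_ms = 0.25, dt_ms = 1, support_ms = 6) {
  if (gamma_ms <= 0) stop("lorentzian_kernel: gamma must be > 0")
  if (support_ms < 6 * gamma_ms) stop("lorentzian_kernel: support must be >= 6*gamma")
  t <- seq(-support_ms, support_ms, by = dt_ms)
  structure(1 / (1 + (t / gamma_ms)^2), t_ms = t)
}

#' Wiener-system model of the cortical VSD response
#'
#' Cascade `y(t) = f( k * (L_gamma * s) (t) )`: unit impulses at the pulse
#' times, broadened by a Lorentzian of width `gamma`, convolved with a
#' causal linear filter `k`, and passed through the static modified-Softplus
#' gain `f`. Output units are fractional transmittance change (dT/T0).
#'
#' @param k Sampled linear filter at `dt_ms` (lag 0 first).
#' @param gamma_ms Lorentzian width (default 0.25 ms).
#' @param beta Softplus sharpness (> 0).
#' @param p Numeric length-6 vector `(p1..p6)` of the static gain.
#' @param dt_ms Grid step; the identification grid is 1 ms.
#' @return A `wiener_model` object.
#' @export
wiener_model <- function(k, gamma_ms = 0.25, beta = 100,
                         p = c(0.02, 1.5, 1.2, 0, 0, 0), dt_ms = 1) {
  if (gamma_ms <= 0) stop("wiener_model: gamma must be > 0")
  if (beta <= 0) stop("wiener_model: beta must be > 0")
  if (length(p) != 6) stop("wiener_model: p must have 6 elements")
  if (length(k) == 0 || !all(is.finite(k))) stop("wiener_model: invalid filter k")
  structure(list(k = as.numeric(k), gamma_ms = gamma_ms, beta = beta,
                 p = as.numeric(p), dt_ms = dt_ms),
            class = "wiener_model")
}

#' Default Wiener model used for surrogate-data generation
#'
#' Linear filter: alpha function `(t/tau) exp(1 - t/tau)` (`tau` 30 ms,
#' 300 ms support, peak 1), a plausible monosynaptic-rise/slow-decay VSD
#' impulse response. Static gain: saturating sigmoid reaching about 2 %
#' dT/T0, with a sharp softplus floor near zero.
#'
#' @param tau_ms Filter rise time constant.
#' @param support_ms Filter support length.
#' @return A [wiener_model()].
#' @export
default_wiener_model <- function(tau_ms = 30, support_ms = 300) {
  t <- seq(0, support_ms - 1)
  k <- (t / tau_ms) * exp(1 - t / tau_ms)
  wiener_model(k = k, gamma_ms = 0.25, beta = 100, p = c(0.02, 1.5, 1.2, 0, 0, 0))
}

## unit impulses on the model grid
render_impulses <- function(pulses, dt_ms = 1) {
  n <- as.integer(round(pulses$duration_ms / dt_ms))
  s <- numeric(n)
  if (length(pulses$times_ms) > 0) {
    idx <- as.integer(floor(pulses$times_ms / dt_ms)) + 1L
    for (i in idx) s[i] <- s[i] + 1
  }
  s
}

## centered (non-causal) convolution of columns with a symmetric kernel
centered_conv_cols <- function(x, kern) {
  x <- as.matrix(x)
  half <- (length(kern) - 1L) %/% 2L
  out <- causal_conv_cols(rbind(x, matrix(0, half, ncol(x))), kern)
  out[(half + 1):(half + nrow(x)), , drop = FALSE]
}

#' Linear stage of the Wiener system
#'
#' Renders the pulse train as unit impulses at `dt_ms`, broadens them with
#' the Lorentzian, and convolves causally with the filter `k`, cropped to
#' the train's window.
#'
#' @param pulses A [pulse_train()].
#' @param model A [wiener_model()].
#' @return Numeric vector `x(t)`, one sample per `dt_ms`.
#' @export
linear_stage <- function(pulses, model) {
  if (length(model$k) == 0) stop("linear_stage: model has no filter")
  s <- render_impulses(pulses, model$dt_ms)
  L <- lorentzian_kernel(model$gamma_ms, model$dt_ms,
                         support_ms = max(6 * model$gamma_ms, 5 * model$dt_ms))
  w <- centered_conv_cols(matrix(s, ncol = 1), L)
  as.numeric(causal_conv_cols(w, model$k))
}

#' Modified-Softplus static gain
#'
#' `f(x) = Softplus_beta(z)` with
#' `z = p1 / (1 + exp(-p2 (x - p3))) + p4 exp(p5 x) + p6` and
#' `Softplus_beta(z) = log(1 + exp(beta z)) / beta`, evaluated in a
#' numerically stable form (exact linear asymptote for large `beta z`).
#'
#' @param x Numeric input (the linear prediction).
#' @param beta Sharpness (> 0).
#' @param p Length-6 parameter vector.
#' @return `f(x)`, same shape as `x`.
#' @export
modified_softplus <- function(x, beta, p) {
  if (beta <= 0) stop("modified_softplus: beta must be > 0")
  z <- p[1] / (1 + exp(-p[2] * (x - p[3]))) + p[4] * exp(p[5] * x) + p[6]
  bz <- beta * z
  out <- ifelse(bz > 30, z + log1p(exp(-bz)) / beta, log1p(exp(bz)) / beta)
  out
}

#' Simulate a VSD trace for one pulse train
#'
#' Applies the static gain sample-wise to the linear stage. With no pulses
#' the trace is constant at `f(0)` (the model baseline).
#'
#' @param pulses A [pulse_train()].
#' @param model A [wiener_model()].
#' @return A `vsd_trace` numeric vector (dT/T0 at `dt_ms` resolution,
#'   length `duration_ms / dt_ms`).
#' @export
simulate_vsd_trace <- function(pulses, model) {
  x <- linear_stage(pulses, model)
  structure(modified_softplus(x, model$beta, model$p),
            class = "vsd_trace", dt_ms = model$dt_ms)
}

## Vectorized simulation: columns of `smat` (time x pixels) are impulse
## trains on the model grid; returns matrix of traces. Single FFT pass.
simulate_vsd_matrix <- function(smat, model) {
  L <- lorentzian_kernel(model$gamma_ms, model$dt_ms,
                         support_ms = max(6 * model$gamma_ms, 5 * model$dt_ms))
  w <- centered_conv_cols(smat, L)
  x <- causal_conv_cols(w, model$k)
  modified_softplus(x, model$beta, model$p)
}

#' Estimate the linear filter by cross-correlation
#'
#' White-noise-style identification: `k(tau)` is the cross-covariance of
#' the Lorentzian-broadened pulse train `w = L_gamma * s` with the measured
#' trace at causal lags (both signals centered, the standard white-noise
#' estimator; centering removes the response baseline `f(0)` that would
#' otherwise leak a constant into the filter), normalized by
#' `sum((w - mean(w))^2)` so an identity system is recovered at unit scale.
#' Segments may be supplied as lists; statistics are pooled across
#' segments.
#'
#' @param pulses A [pulse_train()] or list of them (one per segment).
#' @param measured A numeric trace or list of traces matching `pulses`.
#' @param gamma_ms Lorentzian width used for broadening.
#' @param support_ms Filter support (lags `0 .. support_ms - dt`).
#' @param dt_ms Grid step (default 1 ms).
#' @return Numeric vector `k` of length `support_ms / dt_ms`.
#' @export
estimate_linear_filter <- function(pulses, measured, gamma_ms = 0.25,
                                   support_ms = 300, dt_ms = 1) {
  if (inherits(pulses, "pulse_train")) pulses <- list(pulses)
  if (!is.list(measured)) measured <- list(measured)
  stopifnot(length(pulses) == length(measured))
  if (sum(vapply(pulses, function(p) length(p$times_ms), 0L)) == 0)
    stop("estimate_linear_filter: no pulses in any segment")
  nlag <- as.integer(round(support_ms / dt_ms))
  L <- lorentzian_kernel(gamma_ms, dt_ms, support_ms = max(6 * gamma_ms, 5 * dt_ms))
  num <- numeric(nlag); den <- 0
  for (i in seq_along(pulses)) {
    s <- render_impulses(pulses[[i]], dt_ms)
    y <- as.numeric(measured[[i]])
    if (length(y) != length(s))
      stop("estimate_linear_filter: trace and train lengths differ in segment ", i)
    w <- as.numeric(centered_conv_cols(matrix(s, ncol = 1), L))
    w <- w - mean(w)
    y <- y - mean(y)
    den <- den + sum(w^2)
    n <- length(w)
    for (lag in 0:(nlag - 1L)) {
      if (lag < n)
        num[lag + 1L] <- num[lag + 1L] +
          sum(w[seq_len(n - lag)] * y[seq_len(n - lag) + lag])
    }
  }
  num / den
}

#' Fit the static nonlinearity by multi-start least squares
#'
#' Minimizes `sum((y - f(x))^2)` over `(beta, p1..p6)` of the modified
#' Softplus with Levenberg-Marquardt from multiple seeded starts (covering
#' sharp/soft rectification and shallow/steep sigmoid regimes), returning
#' the best fit. Parameters themselves can be non-identifiable; the fitted
#' curve is the contract.
#'
#' @param x Linear predictions (>= 200 paired samples).
#' @param y Measured values.
#' @param n_starts Number of starts (>= 8).
#' @param seed Seed for the start jitter.
#' @return List `(beta, p, rss, fitted)` where `fitted` is `f` as a
#'   function of `x`.
#' @export
fit_static_nonlinearity <- function(x, y, n_starts = 12, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 200) stop("fit_static_nonlinearity: need >= 200 paired samples")
  n_starts <- max(8L, as.integer(n_starts))
  ry <- diff(range(y)); rx <- diff(range(x))
  if (ry < .Machine$double.eps) {           # constant response
    return(list(beta = 50, p = c(0, 1, 0, 0, 0, mean(y)), rss = 0,
                fitted = function(z) rep(mean(y), length(z))))
  }
  if (rx < .Machine$double.eps) stop("fit_static_nonlinearity: degenerate x")

  resid_fn <- function(par) {
    f <- modified_softplus(x, exp(par[1]), par[2:7])
    f - y
  }
  base_starts <- list(
    c(log(50), ry, 4 / rx, mean(x), 0, 0, min(y)),
    c(log(10), 2 * ry, 1 / rx, mean(x), 0, 0, min(y)),
    ## near-identity: sigmoid linear regime with slope ry/rx, sharp softplus
    c(log(300), 4 * ry, 1 / rx, mean(x), 0, 0, mean(y) - 2 * ry),
    c(log(50), ry * rx, 0.1 / rx, mean(x), 0, 0, min(y)),
    c(log(5),  ry, 2 / rx, stats::median(x), ry / 10, 0.5 / rx, min(y))
  )
  best <- NULL
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      b <- base_starts[[((i - 1) %% length(base_starts)) + 1]]
      if (i > length(base_starts)) b <- b * stats::runif(7, 0.5, 1.5) +
          c(0, 0, 0, stats::rnorm(1, 0, rx / 4), 0, 0, stats::rnorm(1, 0, ry / 4))
      b
    })
  })
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("fit_static_nonlinearity: no start converged (identification error)")
  beta <- exp(best$par[1]); p <- best$par[2:7]
  list(beta = beta, p = p, rss = best$rss,
       fitted = function(z) modified_softplus(z, beta, p))
}

#' Pearson correlation between measured and simulated traces
#'
#' @param measured,simulated Equal-length numeric traces (n >= 3).
#' @return Pearson r; `NA` with a warning if either trace has zero variance.
#' @export
pearson_fit <- function(measured, simulated) {
  measured <- as.numeric(measured); simulated <- as.numeric(simulated)
  if (length(measured) != length(simulated) || length(measured) < 3)
    stop("pearson_fit: traces must have equal length >= 3")
  if (stats::sd(measured) == 0 || stats::sd(simulated) == 0) {
    warning("pearson_fit: zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(measured, simulated)
}

#' Identify a Wiener model from pulse/response segments
#'
#' Two-step identification: linear filter by normalized cross-correlation,
#' then the static nonlinearity by least squares on (linear prediction,
#' measured) pairs pooled over segments.
#'
#' @param pulses List of [pulse_train()] segments.
#' @param measured List of measured traces (1 ms grid).
#' @param gamma_ms Lorentzian width (default 0.25 ms).
#' @param support_ms Filter support (default 300 ms).
#' @param seed Seed for the nonlinearity fit starts.
#' @return A fitted [wiener_model()].
#' @export
identify_wiener <- function(pulses, measured, gamma_ms = 0.25,
                            support_ms = 300, seed = 1L) {
  k <- estimate_linear_filter(pulses, measured, gamma_ms, support_ms)
  mdl0 <- wiener_model(k = k, gamma_ms = gamma_ms, beta = 100,
                       p = c(0, 1, 0, 0, 0, 0))
  xs <- unlist(lapply(seq_along(pulses),
                      function(i) linear_stage(pulses[[i]], mdl0)))
  ys <- unlist(lapply(measured, as.numeric))
  nl <- fit_static_nonlinearity(xs, ys, seed = seed)
  wiener_model(k = k, gamma_ms = gamma_ms, beta = nl$beta, p = nl$p)
}

#' Serialize / restore a Wiener model as JSON
#'
#' @param model A [wiener_model()].
#' @param path Destination / source file.
#' @return `write_wiener_model`: `path` invisibly; `read_wiener_model`: the
#'   model.
#' @export
write_wiener_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wiener_model
#' @export
read_wiener_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wiener_model(k = x$k, gamma_ms = x$gamma_ms, beta = x$beta, p = x$p,
               dt_ms = x$dt_ms %||% 1)
}
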