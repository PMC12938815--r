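test_that("Lorentzian kernel evaluates its closed form", {
  L <- lorentzian_kernel(0.25, dt_ms = 0.05, support_ms = 2)
  t <- attr(L, "t_ms")
  expect_equal(L[t == 0], 1)
  ## half maximum at +-gamma: continuous-time FWHM = 2 gamma = 0.5 ms
  expect_equal(L[abs(abs(t) - 0.25) < 1e-9], c(0.5, 0.5))
  expect_equal(unname(L[abs(t - 0.5) < 1e-9]), 1 / 5)
  expect_error(lorentzian_kernel(-1), "gamma")
  expect_error(lorentzian_kernel(0.25, support_ms = 1), "support")
})

test_that("linear stage is a causal convolution obeying superposition", {
  mdl <- default_wiener_model()
  expect_true(all(linear_stage(pulse_train(numeric(0), 400), mdl) == 0))

  ## brute-force double-sum oracle for a single pulse
  p1 <- pulse_train(50, 400)
  x <- linear_stage(p1, mdl)
  expect_length(x, 400)
  L <- lorentzian_kernel(mdl$gamma_ms, 1, support_ms = 5)
  half <- (length(L) - 1) / 2
  s <- numeric(400); s[51] <- 1
  w <- numeric(400)
  for (t in 1:400) for (j in seq_along(L)) {
    src <- t - (j - 1 - half)
    if (src >= 1 && src <= 400) w[t] <- w[t] + L[j] * s[src]
  }
  xo <- conv_causal_oracle(w, mdl$k)
  expect_lt(max(abs(x - xo)), 1e-9)

  ## superposition
  p2 <- pulse_train(130, 400)
  p12 <- pulse_train(c(50, 130), 400)
  expect_lt(max(abs(linear_stage(p12, mdl) -
                    (linear_stage(p1, mdl) + linear_stage(p2, mdl)))), 1e-9)
})

test_that("modified Softplus matches its formula and limiting cases", {
  ## zero inner argument: f = log(2) / beta for all x
  expect_equal(modified_softplus(c(-5, 0, 7), 1, c(0, 1, 0, 0, 0, 0)),
               rep(log(2), 3))
  ## saturated sigmoid, near-linear softplus
  expect_lt(abs(modified_softplus(5, 20, c(1, 1000, 0, 0, 0, 0)) - 1), 1e-3)
  ## random draws vs direct high-precision evaluation of the formula
  set.seed(9)
  for (i in 1:20) {
    p <- c(runif(1, 0, 2), runif(1, 0.1, 3), rnorm(1), runif(1, 0, 0.5),
           runif(1, -1, 1), rnorm(1, 0, 0.3))
    beta <- runif(1, 0.5, 30)
    x <- rnorm(5)
    z <- p[1] / (1 + exp(-p[2] * (x - p[3]))) + p[4] * exp(p[5] * x) + p[6]
    direct <- log1p(exp(beta * z)) / beta
    ok <- beta * z < 300          # direct form valid below overflow
    got <- modified_softplus(x, beta, p)
    expect_lt(max(abs(got[ok] - direct[ok]) / pmax(abs(direct[ok]), 1e-12)),
              1e-10)
  }
  expect_error(modified_softplus(1, -2, rep(0, 6)), "beta")
})

test_that("simulated traces are the Softplus of the linear stage at 1 ms", {
  mdl <- default_wiener_model()
  ## baseline: no pulses -> constant f(0)
  y0 <- simulate_vsd_trace(pulse_train(numeric(0), 300), mdl)
  expect_length(y0, 300)
  expect_true(all(abs(y0 - modified_softplus(0, mdl$beta, mdl$p)) < 1e-12))

  ## 1000 ms window -> 1000 samples; composition of oracles
  p <- pulse_train(c(10, 12, 40, 300), 1000)
  y <- simulate_vsd_trace(p, mdl)
  expect_length(y, 1000)
  expect_lt(max(abs(y - modified_softplus(linear_stage(p, mdl),
                                          mdl$beta, mdl$p))), 1e-9)
})

test_that("simulation is translation-equivariant inside the window", {
  mdl <- default_wiener_model()
  y1 <- simulate_vsd_trace(pulse_train(c(20, 55), 900), mdl)
  y2 <- simulate_vsd_trace(pulse_train(c(120, 155), 900), mdl)
  expect_lt(max(abs(y1[30:500] - y2[130:600])), 1e-9)
})

test_that("filter estimation is linear in the trace and recovers a known filter", {
  mdl <- default_wiener_model()
  seg <- make_segments(4, seed = 21)
  ## zero measurement -> zero filter
  k0 <- estimate_linear_filter(seg$pulses, lapply(seg$traces, function(x) x * 0),
                               support_ms = 80)
  expect_true(all(k0 == 0))
  ## scaling the measurement scales the filter
  k1 <- estimate_linear_filter(seg$pulses, seg$traces, support_ms = 80)
  k3 <- estimate_linear_filter(seg$pulses, lapply(seg$traces, function(x) 3 * x),
                               support_ms = 80)
  expect_lt(max(abs(k3 - 3 * k1)), 1e-9)
  expect_error(estimate_linear_filter(list(pulse_train(numeric(0), 100)),
                                      list(numeric(100))), "no pulses")

  ## identity nonlinearity (y = linear stage), sparse random pulses:
  ## the filter is recovered with r >= 0.99
  segs <- lapply(1:16, function(i) {
    set.seed(derive_seed(33, "lin", i))
    pulse_train(sort(sample.int(1400, 14) - 1), 1400)
  })
  traces <- lapply(segs, function(p) linear_stage(p, mdl))
  khat <- estimate_linear_filter(segs, traces, support_ms = 300)
  expect_gte(stats::cor(khat, mdl$k), 0.99)
})

test_that("nonlinearity fitting recovers the response curve", {
  set.seed(14)
  x <- runif(2000, 0, 3)
  true_beta <- 100; true_p <- c(0.02, 1.5, 1.2, 0, 0, 0)
  y_true <- modified_softplus(x, true_beta, true_p)
  y <- y_true + rnorm(2000, 0, 0.01 * diff(range(y_true)))
  fit <- fit_static_nonlinearity(x, y, seed = 5)
  rmse <- sqrt(mean((fit$fitted(x) - y_true)^2))
  expect_lte(rmse, 0.02 * diff(range(y_true)))

  ## exactly linear data is reproduced almost perfectly
  xl <- seq(0, 1, length.out = 500)
  fit2 <- fit_static_nonlinearity(xl, xl, seed = 5)
  expect_lte(sqrt(mean((fit2$fitted(xl) - xl)^2)), 1e-3)

  ## constant response
  fit3 <- fit_static_nonlinearity(xl, rep(0.4, 500), seed = 5)
  expect_lt(max(abs(fit3$fitted(xl) - 0.4)), 1e-9)
  expect_equal(fit3$rss, 0)

  expect_error(fit_static_nonlinearity(1:10, 1:10), "200")
})

test_that("Pearson fit statistic matches the covariance formula", {
  expect_equal(pearson_fit(1:10, 1:10), 1.0)
  expect_equal(pearson_fit(1:10, -(1:10)), -1.0)
  a <- c(2.1, 0.5, 3.3, 1.8, 2.2, 0.1, 4.0, 2.7, 1.1, 3.6)
  b <- c(1.0, 0.2, 2.9, 2.2, 2.0, 0.4, 3.1, 2.5, 1.4, 2.8)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_fit(a, b), manual)
  expect_warning(r <- pearson_fit(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_fit(1:2, 1:2), "length")
})

test_that("adding a pulse never lowers the response of a monotone system", {
  mdl <- default_wiener_model()   # p1, p2 >= 0 and k >= 0: monotone
  y1 <- simulate_vsd_trace(pulse_train(c(100, 200), 800), mdl)
  y2 <- simulate_vsd_trace(pulse_train(c(100, 150, 200), 800), mdl)
  expect_true(all(y2 - y1 >= -1e-12))
})
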