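test_that("first-order low-pass step response matches the closed form", {
  wc <- 2 * pi * 5
  lp <- rational_tf(poles = -wc, gain = wc)
  y <- tf_simulate(lp, rep(1, 101), fs = 100, oversample = 8)
  expect_lt(max(abs(y$value - (1 - exp(-wc * y$time)))), 1e-6)
})

test_that("simulation error shrinks as the input sampling refines", {
  # the discretization is exact for piecewise-linear inputs, so the residual
  # error is the first-order-hold representation of a curved input; it must
  # fall quadratically as the input rate doubles
  wc <- 2 * pi * 4
  lp <- rational_tf(poles = -wc, gain = wc)
  h <- abs(freq_resp(lp, 6))
  ph <- Arg(freq_resp(lp, 6))
  ref <- function(tt) 0.5 - 0.5 * h * cos(2 * pi * 6 * tt + ph)
  errs <- vapply(c(100, 200, 400, 800), function(fs_in) {
    t_in <- (0:(2 * fs_in)) / fs_in
    y <- tf_simulate(lp, sin(2 * pi * 3 * t_in)^2, fs = fs_in, oversample = 1)
    sel <- y$time > 1.5   # steady state
    max(abs(y$value[sel] - ref(y$time[sel])))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], errs[1] / 20)
})

test_that("the simulator is linear and time-invariant", {
  set.seed(21)
  tf <- design_approx_filter(adwt_design_params("db1", 100))
  x1 <- rnorm(200); x2 <- rnorm(200)
  x1[1] <- 0  # time invariance below holds for inputs starting at rest
  y1 <- tf_simulate(tf, x1, fs = 100, oversample = 4)$value
  y2 <- tf_simulate(tf, x2, fs = 100, oversample = 4)$value
  y12 <- tf_simulate(tf, 2 * x1 - 3 * x2, fs = 100, oversample = 4)$value
  expect_equal(y12, 2 * y1 - 3 * y2, tolerance = 1e-12)
  # shifting the input by whole input samples shifts the output
  xs <- c(numeric(5), x1[1:195])
  ys <- tf_simulate(tf, xs, fs = 100, oversample = 4)$value
  n <- length(y1)
  expect_equal(ys[(5 * 4 + 1):n], y1[1:(n - 20)], tolerance = 1e-8)
})

test_that("steady-state sine amplitude matches the frequency response", {
  wc <- 2 * pi * 2
  lp <- rational_tf(poles = -wc, gain = wc)
  f0 <- 1
  t_in <- (0:1999) / 100
  y <- tf_simulate(lp, sin(2 * pi * f0 * t_in), fs = 100, oversample = 8)
  sel <- y$time > 10 / wc * 2 * pi  # well past ten time constants
  amp <- max(abs(y$value[sel]))
  expect_equal(amp, abs(freq_resp(lp, f0)), tolerance = 1e-3)
})

test_that("an unstable filter warns but still simulates", {
  expect_warning(y <- tf_simulate(rational_tf(poles = +1, gain = 1),
                                  rep(1, 20), fs = 10, oversample = 1),
                 "unstable")
  expect_true(all(is.finite(y$value)))
})

test_that("analytic group delay matches closed forms at the band limits", {
  wc <- 500
  hp <- rational_tf(zeros = 0, poles = -wc, gain = 1)
  gd <- analog_group_delay(hp, c(1e-4, 1e6))
  expect_equal(gd$delay_s[1], 1 / wc, tolerance = 1e-6)
  expect_equal(gd$delay_s[2], 0, tolerance = 1e-9)
})

test_that("analytic group delay agrees with numerical phase differentiation", {
  tab <- table2_filters(360)
  f <- log_freq_grid(1, 140, 60)
  for (tf in list(tab$A1, tab$A4, tab$D4)) {
    gd <- analog_group_delay(tf, f)
    h <- 1e-4
    numeric_gd <- -vapply(f, function(ff) {
      d <- Arg(freq_resp(tf, ff + h)) - Arg(freq_resp(tf, ff - h))
      d <- d - 2 * pi * round(d / (2 * pi))
      d / (2 * pi * 2 * h)
    }, numeric(1))
    expect_lt(max(abs(gd$delay_s - numeric_gd)), 1e-6)
  }
})

test_that("group delay of a cascade is the sum of branch delays", {
  tab <- table2_filters(360)
  f <- log_freq_grid(5, 100, 30)
  casc <- rational_tf(c(tab$A1$zeros, tab$D1$zeros),
                      c(tab$A1$poles, tab$D1$poles),
                      tab$A1$gain * tab$D1$gain)
  expect_equal(analog_group_delay(casc, f)$delay_s,
               analog_group_delay(tab$A1, f)$delay_s +
                 analog_group_delay(tab$D1, f)$delay_s, tolerance = 1e-12)
})

test_that("exact notch frequencies are excluded and flagged", {
  a1 <- design_approx_filter(adwt_design_params("db1", 360))
  fn <- 180
  gd <- analog_group_delay(a1, c(90, fn, 200))
  expect_true(is.na(gd$delay_s[2]))
  expect_equal(attr(gd, "excluded"), fn)
  expect_true(all(is.finite(gd$delay_s[-2])))
})

test_that("FIR group delay is flat for symmetric 2-tap filters", {
  fp <- daubechies_filters("db1", 360)
  f <- c(10, 60, 120, 170)
  for (h in list(fp$lowpass, fp$highpass)) {
    gd <- fir_group_delay(h, 360, f)
    expect_equal(gd$delay_s, rep(0.5 / 360, 4), tolerance = 1e-12)
  }
  expect_equal(fir_group_delay(fp$lowpass, 360, 60)$delay_s * 1000, 1.389,
               tolerance = 1e-3)
  expect_error(fir_group_delay(fp$lowpass, 360, 180), "Nyquist")
})

test_that("FIR group delay matches the numerical phase-derivative oracle", {
  fp <- daubechies_filters("db4", 360)
  f <- seq(5, 170, by = 15)
  gd <- fir_group_delay(fp$lowpass, 360, f)
  cdiff <- function(ff, h) {
    d <- Arg(fir_dtft(fp$lowpass, ff + h, 360)) -
      Arg(fir_dtft(fp$lowpass, ff - h, 360))
    (d - 2 * pi * round(d / (2 * pi))) / (2 * pi * 2 * h)
  }
  # Richardson-extrapolated central difference: truncation error ~ h^4
  numeric_gd <- -vapply(f, function(ff) {
    (4 * cdiff(ff, 5e-4) - cdiff(ff, 1e-3)) / 3
  }, numeric(1))
  expect_lt(max(abs(gd$delay_s - numeric_gd)), 1e-9)
})

test_that("bulk-delay equalization absorbs constant offsets exactly", {
  f <- log_freq_grid(10, 150, 100)
  base <- data.frame(freq_hz = f, delay_s = 1e-3 + 1e-4 * sin(f / 20))
  shifted <- base
  shifted$delay_s <- base$delay_s + 5e-3
  eq <- equalize_and_error(shifted, base, c(10, 150))
  expect_equal(eq$fixed_delay, 5e-3, tolerance = 1e-9)
  expect_lt(eq$peak, 1e-6)
  # adding a constant to either curve leaves the residual unchanged
  eq2 <- equalize_and_error(base, base, c(10, 150))
  expect_equal(eq2$peak, 0, tolerance = 1e-12)
  expect_error(equalize_and_error(base, base, c(200, 300)), "empty")
})

test_that("residual group-delay errors reproduce the published levels", {
  rep1 <- group_delay_report("db1", 360)
  expect_lt(max(rep1$peak_pct_cycle), 4)
  rep4 <- group_delay_report("db4", 360)
  expect_equal(max(rep4$peak_pct_cycle), 15, tolerance = 2 / 15)
})
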