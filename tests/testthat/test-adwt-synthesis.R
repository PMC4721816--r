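params1 <- adwt_design_params("db1", 360)
params4 <- adwt_design_params("db4", 360)

test_that("first-order notch reproduces the published A1 coefficients", {
  co <- tf_coeffs(design_approx_filter(params1))
  # monic denominator s^2 + (wn/Q) s + wn^2 with wn = 2*pi*180, Q = 1/sqrt(2)
  expect_equal(co$den[1], 1)
  expect_equal(co$den[2], 1599, tolerance = 5e-3)
  expect_equal(co$den[3], 1.279e6, tolerance = 5e-3)
  expect_equal(co$num[1], 1.414, tolerance = 5e-3)
  expect_equal(co$num[2], 0)
  expect_equal(co$num[3], 1.809e6, tolerance = 5e-3)
})

test_that("fourth-order notch reproduces the published A4 coefficients", {
  co <- tf_coeffs(design_approx_filter(params4))
  scale <- 21609 / co$den[1]          # match the published leading coefficient
  den <- co$den * scale
  num <- co$num * scale
  expect_equal(den[2], 4.441e7, tolerance = 5e-3)
  expect_equal(den[3], 9.495e10, tolerance = 5e-3)
  expect_equal(den[4], 5.067e13, tolerance = 5e-3)
  expect_equal(den[5], 2.813e16, tolerance = 5e-3)
  expect_equal(num[1], 3.056e4, tolerance = 5e-3)
  expect_equal(num[3], 6.973e10, tolerance = 5e-3)
  expect_equal(num[5], 3.978e16, tolerance = 5e-3)
  expect_equal(num[c(2, 4)], c(0, 0))
})

test_that("details high-pass matches the published D1 pole and limits", {
  d1 <- design_details_filter(params1)
  expect_length(d1$poles, 1)
  expect_equal(Re(d1$poles), -4524 / 4, tolerance = 1e-4)  # 4 significant figures
  expect_equal(abs(freq_resp(d1, 1e-9)), 0, tolerance = 1e-9)
  expect_equal(abs(freq_resp(d1, 1e12)), 1, tolerance = 1e-6)
  d4 <- design_details_filter(params4)
  co <- tf_coeffs(d4)
  wc <- 2 * pi * 360 / 2.34
  expect_equal(co$den[2], 2.6131 * wc, tolerance = 1e-4)  # Butterworth s^3 term
  expect_equal(abs(freq_resp(d4, 360 / 2.34)), 1 / sqrt(2), tolerance = 1e-9)
})

test_that("approximation DC gain matches the FIR lowpass coefficient sum", {
  for (p in list(params1, params4)) {
    a <- design_approx_filter(p, gain_mode = "fir")
    expect_equal(abs(freq_resp(a, 1e-9)), sqrt(2), tolerance = 1e-9)
    expect_equal(abs(freq_resp(a, 1e12)), sqrt(2), tolerance = 1e-6)
  }
})

test_that("the notch has exact transmission zeros at the notch frequency", {
  for (p in list(params1, params4)) {
    a <- design_approx_filter(p)
    fn <- p$base_fs / p$approx_fn_ratio
    expect_lt(abs(freq_resp(a, fn)), 1e-12)
    expect_true(all(abs(Re(a$zeros)) < 1e-9 * abs(a$zeros)))
  }
})

test_that("table2 filters return the literal printed transfer functions", {
  tab <- table2_filters(360)
  co <- tf_coeffs(tab$A1)
  expect_equal(co$num / co$den[1], c(1.414, 0, 1.809e6), tolerance = 1e-6)
  expect_equal(co$den / co$den[1], c(1, 1599, 1.279e6), tolerance = 1e-6)
  d1 <- tf_coeffs(tab$D1)
  expect_equal(d1$num / d1$den[1], c(-9 / 4, 0), tolerance = 1e-6)
  expect_equal(d1$den / d1$den[1], c(1, 4524 / 4), tolerance = 1e-6)
  d4 <- tf_coeffs(tab$D4)
  expect_equal(d4$den[length(d4$den)] / d4$den[1], 1 / 1.825e-11,
               tolerance = 1e-4)
  # published gains: sqrt(2) DC on A, 2.25 / 2.0 high-frequency on D
  expect_equal(abs(freq_resp(tab$A4, 1e-9)), 3.978e16 / 2.813e16,
               tolerance = 1e-6)
  expect_equal(abs(freq_resp(tab$D1, 1e12)), 2.25, tolerance = 1e-6)
  expect_equal(abs(freq_resp(tab$D4, 1e12)), 2.0, tolerance = 1e-6)
})

test_that("table2 filters frequency-scale to other sampling rates", {
  a1_720 <- table2_filters(720)$A1
  # notch frequency doubles to 2262 rad/s
  expect_equal(sort(Im(a1_720$zeros)), c(-2262, 2262), tolerance = 1e-3)
  f <- c(10, 50, 100, 200)
  expect_equal(abs(freq_resp(a1_720, 2 * f)),
               abs(freq_resp(table2_filters(360)$A1, f)), tolerance = 1e-9)
})

test_that("level scaling halves every corner frequency and preserves limit gains", {
  d1 <- design_details_filter(params1)
  expect_equal(scale_level(d1, 1), d1)
  d1_l2 <- scale_level(d1, 2)
  expect_equal(Re(d1_l2$poles), -1131 / 2, tolerance = 1e-3)
  a1 <- design_approx_filter(params1)
  for (lev in c(2, 4)) {
    al <- scale_level(a1, lev)
    f <- c(5, 20, 80)
    expect_equal(abs(freq_resp(al, f)), abs(freq_resp(a1, f * 2^(lev - 1))),
                 tolerance = 1e-12)
    expect_equal(abs(freq_resp(al, 1e-9)), abs(freq_resp(a1, 1e-9)),
                 tolerance = 1e-9)
  }
  # associativity: level i of level j equals level i + j - 1
  expect_equal(tf_coeffs(scale_level(scale_level(a1, 2), 3)),
               tf_coeffs(scale_level(a1, 4)), tolerance = 1e-12)
})

test_that("filter banks scale the level-1 design down the levels", {
  bank <- build_filter_bank(params1, 4)
  expect_length(bank$A, 4)
  expect_length(bank$D, 4)
  expect_equal(Re(bank$D[[4]]$poles), -1131 / 8, tolerance = 1e-3)
  fn <- vapply(bank$A, function(a) max(Im(a$zeros)), numeric(1))
  expect_equal(fn / fn[1], c(1, 1 / 2, 1 / 4, 1 / 8))
  bank4 <- build_filter_bank(params4, 1, mode = "designed", gain_mode = "fir")
  expect_equal(tf_coeffs(bank4$A[[1]]),
               tf_coeffs(design_approx_filter(params4, gain_mode = "fir")))
  expect_error(build_filter_bank(params1, 2, gain_mode = "printed"), "table2")
})

test_that("designed approximation magnitude tracks the FIR response in-band", {
  # implementation assertion: within 1.5 dB below half the notch frequency
  for (wav in c("db1", "db4")) {
    p <- adwt_design_params(wav, 360)
    fir <- daubechies_filters(wav, 360)
    fn <- 360 / p$approx_fn_ratio
    f <- log_freq_grid(3.6, 0.5 * fn, 200)
    ha <- abs(freq_resp(design_approx_filter(p, "fir"), f))
    hf <- abs(fir_dtft(fir$lowpass, f, 360))
    expect_lt(max(abs(20 * log10(ha / hf))), 1.5)
  }
})

test_that("published details gains place the analog response on the FIR curve", {
  # db1: within 1.5 dB up to 0.35 fs (the published 2.25 gain supplies the
  # low-frequency pi/2 correction a Nyquist-matched first-order filter lacks)
  tab <- table2_filters(360)
  fir1 <- daubechies_filters("db1", 360)
  f <- log_freq_grid(3.6, 0.35 * 360, 200)
  expect_lt(max(abs(20 * log10(abs(freq_resp(tab$D1, f)) /
                               abs(fir_dtft(fir1$highpass, f, 360))))), 1.5)
  # FIR-matched mode instead anchors the Nyquist magnitude at sqrt(2)
  b <- build_filter_bank(params1, 1, mode = "table2", gain_mode = "fir")
  expect_equal(abs(freq_resp(b$D[[1]], 1e12)), sqrt(2), tolerance = 1e-6)
})

test_that("design parameter validation", {
  expect_error(adwt_design_params("db2", 360), "supply them explicitly")
  p2 <- adwt_design_params("db2", 360, details_order = 2,
                           details_fc_ratio = 2.2, approx_fn_ratio = 2.1,
                           approx_q = 0.7)
  expect_s3_class(design_approx_filter(p2), "rational_tf")
  expect_error(adwt_design_params("db1", -5), "base_fs")
})
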