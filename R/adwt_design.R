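#' ADWT synthesis parameters
#'
#' Parameters of the analog filters that approximate a Daubechies
#' decomposition pair: a Butterworth high-pass of order `details_order` with
#' cut-off `fc = base_fs / details_fc_ratio` for the details branch, and a
#' Butterworth band-stop (notch) with notch frequency
#' `fn = base_fs / approx_fn_ratio` and quality factor `approx_q` for the
#' approximation branch. Defaults: db1 uses order 1, fc = fs/2, fn = fs/2,
#' Q = 1/sqrt(2); db4 uses order 4, fc = fs/2.34, fn = fs/2.12, Q = 0.735.
#' (The Q = 1/sqrt(2) default for db1 is what the first-order notch
#' denominator s-coefficient omega_n * sqrt(2) requires.)
#'
#' @param wavelet wavelet name, order or [wavelet_spec()].
#' @param base_fs base sampling frequency in Hz.
#' @param details_order,details_fc_ratio,approx_fn_ratio,approx_q overrides of
#'   the per-wavelet defaults (required for orders other than 1 and 4).
#' @return object of class `adwt_design_params`.
#' @export
adwt_design_params <- function(wavelet, base_fs,
                               details_order = NULL, details_fc_ratio = NULL,
                               approx_fn_ratio = NULL, approx_q = NULL) {
  spec <- wavelet_spec(wavelet)
  defaults <- switch(spec$name,
    db1 = list(order = 1L, fc = 2, fn = 2, q = 1 / sqrt(2)),
    db4 = list(order = 4L, fc = 2.34, fn = 2.12, q = 0.735),
    NULL)
  if (is.null(defaults) && (is.null(details_order) || is.null(details_fc_ratio) ||
                            is.null(approx_fn_ratio) || is.null(approx_q)))
    stop("no built-in design parameters for ", spec$name,
         "; supply them explicitly")
  p <- list(wavelet = spec, base_fs = base_fs,
            details_order = details_order %||% defaults$order,
            details_fc_ratio = details_fc_ratio %||% defaults$fc,
            approx_fn_ratio = approx_fn_ratio %||% defaults$fn,
            approx_q = approx_q %||% defaults$q)
  stopifnot(p$base_fs > 0, p$details_order >= 1,
            p$details_fc_ratio > 0, p$approx_fn_ratio > 0, p$approx_q > 0)
  structure(p, class = "adwt_design_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalized Butterworth pole set of order n (|p| = 1, left half-plane)
butterworth_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

#' Details (high-pass) ADWT filter
#'
#' Butterworth high-pass of the requested order with -3 dB cut-off
#' `2 * pi * base_fs / details_fc_ratio` rad/s: n zeros at the origin and the
#' Butterworth pole set scaled to the cut-off. Gain modes: `"normalized"`
#' gives unit high-frequency (passband) gain magnitude; `"fir"` gives
#' magnitude sqrt(2), matching the FIR details filter at Nyquist.
#'
#' @param params an [adwt_design_params()].
#' @param gain_mode `"normalized"` or `"fir"`.
#' @return a [rational_tf()]; `|H(0)| = 0` exactly.
#' @export
design_details_filter <- function(params, gain_mode = c("normalized", "fir")) {
  gain_mode <- match.arg(gain_mode)
  stopifnot(inherits(params, "adwt_design_params"))
  n <- params$details_order
  wc <- 2 * pi * params$base_fs / params$details_fc_ratio
  # negative sign matches the FIR details filters, whose Nyquist response
  # sum((-1)^n h[n]) = -sqrt(2) is negative (the published D rows carry it)
  g <- switch(gain_mode, normalized = -1, fir = -sqrt(2))
  rational_tf(zeros = rep(0 + 0i, n), poles = wc * butterworth_poles(n),
              gain = g)
}

#' Approximation (band-stop notch) ADWT filter
#'
#' The approximation branch is the lower half of a Butterworth notch: the
#' band-stop filter obtained by applying the low-pass-to-band-stop frequency
#' transformation to the Butterworth low-pass prototype of order
#' `ceiling(details_order / 2)` (so the analog order is twice that: 2 for
#' db1, 4 for db4), with notch frequency `omega_n = 2 pi base_fs /
#' approx_fn_ratio` and stop bandwidth `omega_n / Q`. The numerator is
#' proportional to `(s^2 + omega_n^2)^m` — exact transmission zeros on the
#' imaginary axis. Gain modes: `"fir"` (default) gives DC gain sqrt(2),
#' matching the FIR lowpass coefficient sum; `"normalized"` gives unity.
#'
#' @param params an [adwt_design_params()].
#' @param gain_mode `"fir"` or `"normalized"`.
#' @return a [rational_tf()] of even order with `|H(j omega_n)| = 0`.
#' @export
design_approx_filter <- function(params, gain_mode = c("fir", "normalized")) {
  gain_mode <- match.arg(gain_mode)
  stopifnot(inherits(params, "adwt_design_params"))
  m <- as.integer(ceiling(params$details_order / 2))
  wn <- 2 * pi * params$base_fs / params$approx_fn_ratio
  bw <- wn / params$approx_q
  proto <- butterworth_poles(m)
  # band-stop image of each prototype pole p: roots of s^2 - (bw/p) s + wn^2
  poles <- unlist(lapply(proto, function(p) {
    b <- -bw / p
    disc <- sqrt(as.complex(b^2 - 4 * wn^2))
    c((-b + disc) / 2, (-b - disc) / 2)
  }))
  zeros <- rep(c(1i * wn, -1i * wn), m)
  g <- switch(gain_mode, fir = sqrt(2), normalized = 1)
  rational_tf(zeros = zeros, poles = poles, gain = g)
}

# literal printed transfer-function coefficients for base fs 360 Hz
.table2_360 <- list(
  A1 = list(num = c(1.414, 0, 1.809e6), den = c(1, 1599, 1.279e6)),
  D1 = list(num = c(-9, 0), den = c(4, 4524)),
  A4 = list(num = c(3.056e4, 0, 6.973e10, 0, 3.978e16),
            den = c(21609, 4.441e7, 9.495e10, 5.067e13, 2.813e16)),
  D4 = list(num = c(-3.65e-11, 0, 0, 0, 0),
            den = c(1.825e-11, 2.498e-8, 1.709e-5, 0.005846, 1))
)

#' The published level-1 transfer functions
#'
#' Returns the four literal level-1 analog filters (A1, D1 for db1; A4, D4
#' for db4) exactly as published for a 360 Hz base sampling frequency. For
#' any other rate the functions are frequency-scaled (`s -> s * 360 /
#' base_fs`), which moves every corner frequency by `base_fs / 360` and
#' preserves the printed gains (sqrt(2) at DC for the A filters, 2.25 and 2.0
#' high-frequency gain for D1 and D4).
#'
#' @param base_fs base sampling frequency in Hz.
#' @return named list of [rational_tf()]: `A1`, `D1`, `A4`, `D4`.
#' @export
table2_filters <- function(base_fs = 360) {
  stopifnot(base_fs > 0)
  ratio <- base_fs / 360
  lapply(.table2_360, function(f) {
    tf <- tf_from_coeffs(f$num, f$den)
    # H(s * 360/fs): corner frequencies multiply by fs/360
    rational_tf(tf$zeros * ratio, tf$poles * ratio,
                tf$gain * ratio^(length(tf$zeros) - length(tf$poles)))
  })
}

#' Per-level frequency scaling of an analog filter
#'
#' Level i of the analog bank uses the level-1 design with every corner
#' frequency divided by 2^(i-1): `H_i(s) = H_1(2^(i-1) s)`. Gains at s = 0
#' and s = Inf are unchanged. (The cut-off halves per level, replacing the
#' DWT's decimation stage.)
#'
#' @param tf a [rational_tf()] (a level-1 design).
#' @param level analysis level (>= 1); level 1 is the identity.
#' @return the level-`level` [rational_tf()].
#' @export
scale_level <- function(tf, level) {
  stopifnot(inherits(tf, "rational_tf"), level >= 1)
  cfac <- 2^(level - 1)
  rational_tf(tf$zeros / cfac, tf$poles / cfac,
              tf$gain * cfac^(length(tf$zeros) - length(tf$poles)))
}

#' Analog DWT filter bank
#'
#' Builds the per-level approximation and details filters: the level-1 pair
#' (designed from `params`, or the literal published functions in `"table2"`
#' mode) scaled by [scale_level()] for each deeper level.
#'
#' @param params an [adwt_design_params()].
#' @param levels number of analysis levels.
#' @param mode `"designed"` (synthesize from the parameters) or `"table2"`
#'   (literal published level-1 functions for this wavelet).
#' @param gain_mode gain convention. `"normalized"`: unity passband gain
#'   (the convention of the magnitude-response plots). `"fir"`: FIR-matched
#'   gains — sqrt(2) DC for the approximation branch and magnitude sqrt(2)
#'   at high frequency for the details branch, so band powers are on the
#'   DWT coefficient scale. `"printed"` (table2 mode only): keep the
#'   published gains as-is (2.25 and 2.0 on the details filters); these
#'   sit above sqrt(2) and in practice also absorb the high-frequency droop
#'   of first-order-hold input reconstruction, giving the closest
#'   coefficient tracking.
#' @return object of class `adwt_bank`: lists `A` and `D` of
#'   [rational_tf()] per level, plus `design`, `mode`, `levels`.
#' @export
build_filter_bank <- function(params, levels, mode = c("designed", "table2"),
                              gain_mode = c("normalized", "fir", "printed")) {
  mode <- match.arg(mode)
  gain_mode <- match.arg(gain_mode)
  stopifnot(inherits(params, "adwt_design_params"), levels >= 1)
  if (mode == "designed") {
    if (gain_mode == "printed")
      stop("gain_mode 'printed' requires mode 'table2'")
    a1 <- design_approx_filter(params, gain_mode = gain_mode)
    d1 <- design_details_filter(params, gain_mode = gain_mode)
  } else {
    tab <- table2_filters(params$base_fs)
    pick <- switch(params$wavelet$name,
                   db1 = list(A = tab$A1, D = tab$D1),
                   db4 = list(A = tab$A4, D = tab$D4),
                   stop("table2 mode covers db1 and db4 only"))
    a1 <- pick$A; d1 <- pick$D
    if (gain_mode == "normalized") {
      a1 <- rational_tf(a1$zeros, a1$poles, a1$gain / abs(freq_resp(a1, 0)))
      d1 <- rational_tf(d1$zeros, d1$poles, sign(d1$gain))
    } else if (gain_mode == "fir") {
      d1 <- rational_tf(d1$zeros, d1$poles, sign(d1$gain) * sqrt(2))
    }
  }
  structure(list(levels = as.integer(levels),
                 A = lapply(seq_len(levels), function(i) scale_level(a1, i)),
                 D = lapply(seq_len(levels), function(i) scale_level(d1, i)),
                 design = params, mode = mode, gain_mode = gain_mode),
            class = "adwt_bank")
}

#' @export
print.adwt_bank <- function(x, ...) {
  cat(sprintf("adwt_bank: %s, %d levels, fs = %g Hz (%s mode, %s gain)\n",
              x$design$wavelet$name, x$levels, x$design$base_fs,
              x$mode, x$gain_mode))
  fn1 <- 2 * pi * x$design$base_fs / x$design$approx_fn_ratio
  for (i in seq_len(x$levels))
    cat(sprintf("  level %d: notch %.4g rad/s, details cut-off %.4g rad/s\n",
                i, fn1 / 2^(i - 1),
                2 * pi * x$design$base_fs / x$design$details_fc_ratio / 2^(i - 1)))
  invisible(x)
}
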