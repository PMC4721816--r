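#' Simulate a continuous-time filter on a sampled input
#'
#' Computes the zero-initial-state response of `tf` to the input signal,
#' reconstructed by first-order hold (linear interpolation between samples).
#' The input is first linearly interpolated onto a grid `oversample` times
#' finer; the state-space model (controllable canonical form, built in
#' frequency-normalized units for conditioning) is then discretized exactly
#' under the first-order-hold assumption via the Van Loan block-matrix
#' exponential, and the resulting discrete recursion is run at C speed as a
#' digital IIR filter. For piecewise-linear inputs the sampled output is
#' exact to machine/`expm` precision.
#'
#' @param tf a [rational_tf()].
#' @param x input samples (numeric vector or [sampled_signal()]).
#' @param fs input sampling frequency in Hz (ignored for `sampled_signal`).
#' @param oversample integer >= 1; output grid is `fs * oversample`.
#' @return a [sampled_signal()] on the oversampled grid.
#' @export
tf_simulate <- function(tf, x, fs = NULL, oversample = 8) {
  stopifnot(inherits(tf, "rational_tf"))
  if (inherits(x, "sampled_signal")) {
    fs <- x$fs
    x <- c(x$value)
  }
  if (is.null(fs)) stop("fs required when x is a bare vector")
  oversample <- as.integer(oversample)
  stopifnot(fs > 0, oversample >= 1L)
  if (any(Re(tf$poles) > 0))
    warning("unstable filter (pole with positive real part); simulating anyway")
  if (oversample > 1L) {
    n <- length(x)
    tfine <- seq(0, (n - 1) / fs, by = 1 / (fs * oversample))
    x <- stats::approx(seq(0, (n - 1) / fs, by = 1 / fs), x, xout = tfine)$y
  }
  fso <- fs * oversample
  dz <- discretize_foh(tf, 1 / fso)
  y <- as.numeric(signal::filter(dz$num, dz$den, x))
  # correction for the nonzero shifted-state initial condition when u[1] != 0
  if (x[1] != 0) {
    imp <- c(1, numeric(length(x) - 1))
    y <- y + x[1] * as.numeric(signal::filter(dz$ic_num, dz$den, imp))
  }
  sampled_signal(y, fso)
}

# Exact first-order-hold discretization of a rational_tf.
# Returns the z^-1-form digital filter (num, den) equivalent to the shifted
# state recursion, plus ic_num: the numerator of the response to the initial
# shifted state created by a nonzero first input sample.
discretize_foh <- function(tf, dt) {
  # frequency normalization keeps the companion matrix well conditioned
  w0 <- max(abs(c(tf$poles, tf$zeros)), 1 / dt)
  num <- tf$gain * real_poly(tf$zeros / w0) *
    w0^(length(tf$zeros) - length(tf$poles))
  den <- real_poly(tf$poles / w0)
  n <- length(den) - 1L
  if (n == 0L) {  # static gain
    g <- num[length(num)] / den[length(den)]
    return(list(num = g, den = 1, ic_num = 0))
  }
  a <- den[-1]                       # monic: s^n + a1 s^{n-1} + ... + an
  b <- c(numeric(n + 1 - length(num)), num)
  bn <- b[1]
  # controllable canonical form
  A <- rbind(cbind(matrix(0, n - 1, 1), diag(1, n - 1, n - 1)),
             -rev(a))
  if (n == 1L) A <- matrix(-a, 1, 1)
  B <- matrix(c(numeric(n - 1), 1), n, 1)
  C <- matrix(rev(b[-1]) - bn * rev(a), 1, n)
  D <- bn
  dtn <- dt * w0
  M <- matrix(0, n + 2, n + 2)
  M[1:n, 1:n] <- A
  M[1:n, n + 1] <- B
  M[n + 1, n + 2] <- 1
  E <- as.matrix(Matrix::expm(M * dtn))
  Phi <- E[1:n, 1:n, drop = FALSE]
  G1 <- E[1:n, n + 1, drop = FALSE]            # int e^{A(dt-s)} B ds
  G2 <- E[1:n, n + 2, drop = FALSE] / dtn      # int e^{A(dt-s)} B s/dt ds
  # shifted state z_k = x_k - G2 u_k gives a standard (zero-feedthrough-state)
  # recursion z_{k+1} = Phi z_k + Bz u_k, y_k = C z_k + Dz u_k
  Bz <- Phi %*% G2 + G1 - G2
  Dz <- drop(C %*% G2) + D
  denz <- char_poly(Phi)                       # (1, a1, ..., an) in z^-1 form
  h <- numeric(n + 1)                          # Markov parameters
  h[1] <- Dz
  v <- Bz
  for (k in seq_len(n)) {
    h[k + 1] <- drop(C %*% v)
    v <- Phi %*% v
  }
  numz <- convolve_full(denz, h)[1:(n + 1)]
  # initial condition z_1 = -G2 (per unit u[1]); response C Phi^{k-1} z_1
  w <- numeric(n)
  vic <- -G2
  for (k in seq_len(n)) {
    w[k] <- drop(C %*% vic)
    vic <- Phi %*% vic
  }
  icnum <- convolve_full(denz, w)[seq_len(n)]
  list(num = numz, den = denz, ic_num = icnum)
}

# monic characteristic polynomial via the Faddeev-LeVerrier recursion
char_poly <- function(A) {
  n <- nrow(A)
  cf <- numeric(n + 1)
  cf[1] <- 1
  M <- diag(1, n)
  for (k in seq_len(n)) {
    AM <- A %*% M
    cf[k + 1] <- -sum(diag(AM)) / k
    M <- AM + cf[k + 1] * diag(1, n)
  }
  cf
}

#' Analytic group delay of an analog filter
#'
#' Group delay tau(omega) = -d(phase)/d(omega), computed in closed form from
#' the factored transfer function as a sum over poles and zeros (no numerical
#' differencing). Frequencies that coincide with an imaginary-axis
#' transmission zero (the notch frequency) have undefined phase; they are
#' returned as NA and listed in the `excluded` attribute.
#'
#' @param tf a [rational_tf()].
#' @param freq_hz evaluation frequencies in Hz (> 0, strictly increasing).
#' @return a `group_delay_curve`: data.frame with `freq_hz` and `delay_s`.
#' @export
analog_group_delay <- function(tf, freq_hz) {
  stopifnot(inherits(tf, "rational_tf"), all(freq_hz > 0),
            !is.unsorted(freq_hz, strictly = TRUE))
  w <- 2 * pi * freq_hz
  tau <- numeric(length(w))
  excluded <- logical(length(w))
  for (z in tf$zeros) {
    d2 <- (0 - Re(z))^2 + (w - Im(z))^2
    hit <- d2 <= (1e-12 * max(abs(z), 1))^2
    excluded <- excluded | hit
    tau <- tau + ifelse(hit, 0, Re(z) / d2)
  }
  for (p in tf$poles) {
    d2 <- (0 - Re(p))^2 + (w - Im(p))^2
    tau <- tau - Re(p) / d2
  }
  tau[excluded] <- NA_real_
  structure(data.frame(freq_hz = freq_hz, delay_s = tau),
            excluded = freq_hz[excluded],
            class = c("group_delay_curve", "data.frame"))
}

#' Group delay of an FIR filter
#'
#' Discrete-time group delay in seconds, from the exact derivative formula
#' tau(omega) = Re(H1 / H0) / fs samples-in-seconds, where H0 is the filter's
#' DTFT and H1 the DTFT of `n * h[n]`.
#'
#' @param coeffs FIR taps (index 1 = z^0).
#' @param base_fs sampling frequency in Hz.
#' @param freq_hz evaluation frequencies in Hz, each < `base_fs / 2`.
#' @return a `group_delay_curve`.
#' @export
fir_group_delay <- function(coeffs, base_fs, freq_hz) {
  stopifnot(length(coeffs) >= 2, base_fs > 0)
  if (any(freq_hz >= base_fs / 2))
    stop("frequencies at or above Nyquist are out of range")
  n <- seq_along(coeffs) - 1
  tau <- vapply(freq_hz, function(f) {
    e <- exp(-1i * 2 * pi * f / base_fs * n)
    Re(sum(n * coeffs * e) / sum(coeffs * e))
  }, numeric(1)) / base_fs
  structure(data.frame(freq_hz = freq_hz, delay_s = tau),
            class = c("group_delay_curve", "data.frame"))
}

#' Logarithmic frequency grid
#'
#' @param from,to band edges in Hz (inclusive).
#' @param n number of points.
#' @return numeric vector of frequencies.
#' @export
log_freq_grid <- function(from, to, n = 512) {
  stopifnot(from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n))
}

#' Default group-delay evaluation band
#'
#' Details branch: `[0.05, 0.95] * fs/2` intersected with the analog filter's
#' -3 dB passband (lower edge raised to the high-pass cut-off); when the
#' cut-off reaches the upper edge (the db1 case, fc = fs/2) the full
#' `[0.05, 0.95] * fs/2` band is used. Approximation branch:
#' `[0.01 * fs, 0.8 * fn]`, which stays clear of both DC and the notch
#' singularity.
#'
#' @param params an [adwt_design_params()].
#' @param branch `"details"` or `"approximation"`.
#' @return numeric length-2 band in Hz.
#' @export
default_gd_band <- function(params, branch = c("details", "approximation")) {
  branch <- match.arg(branch)
  fs <- params$base_fs
  if (branch == "details") {
    lo <- 0.05 * fs / 2
    hi <- 0.95 * fs / 2
    fc <- fs / params$details_fc_ratio
    if (fc < hi) lo <- max(lo, fc)
    c(lo, hi)
  } else {
    fn <- fs / params$approx_fn_ratio
    c(0.01 * fs, 0.8 * fn)
  }
}

#' Fixed-delay equalization and residual group-delay error
#'
#' Finds the single bulk delay `d` minimizing the peak of
#' `|tau_analog(f) - tau_digital(f) - d| * f * 100` over the band — the
#' residual group-delay error expressed as a percentage of a cycle at each
#' frequency. The objective is a maximum of convex functions of `d` and is
#' minimized by Brent search over the range of the raw delay difference.
#'
#' @param analog,digital `group_delay_curve` objects on a common frequency
#'   grid covering `band`.
#' @param band numeric length-2 band in Hz.
#' @return list with `fixed_delay` (s), `error` (data.frame `freq_hz`,
#'   `error_pct_cycle`), and `peak` (% of a cycle).
#' @export
equalize_and_error <- function(analog, digital, band) {
  stopifnot(length(band) == 2, band[2] > band[1])
  if (!isTRUE(all.equal(analog$freq_hz, digital$freq_hz)))
    stop("curves must share a frequency grid")
  sel <- analog$freq_hz >= band[1] & analog$freq_hz <= band[2] &
    is.finite(analog$delay_s) & is.finite(digital$delay_s)
  if (!any(sel)) stop("empty evaluation band")
  f <- analog$freq_hz[sel]
  diff <- analog$delay_s[sel] - digital$delay_s[sel]
  obj <- function(d) max(abs(diff - d) * f * 100)
  rng <- range(diff)
  if (rng[1] == rng[2]) {
    d <- rng[1]
  } else {
    d <- stats::optimize(obj, interval = rng, tol = 1e-14)$minimum
  }
  err <- (diff - d) * f * 100
  list(fixed_delay = d,
       error = data.frame(freq_hz = f, error_pct_cycle = err),
       peak = max(abs(err)))
}

#' Group-delay error summary for a wavelet at its default bands
#'
#' Runs the full comparison for one wavelet: designs the analog pair, takes
#' the FIR pair, computes both group-delay curves on a 512-point logarithmic
#' grid per branch, equalizes with the minimax bulk delay, and reports the
#' per-branch peak residual error in percent of a cycle.
#'
#' @param wavelet wavelet name or order (db1 or db4).
#' @param base_fs base sampling frequency in Hz.
#' @param n_grid grid points per branch.
#' @return data.frame with one row per branch: `branch`, `fixed_delay_s`,
#'   `peak_pct_cycle`.
#' @export
group_delay_report <- function(wavelet, base_fs = 360, n_grid = 512) {
  params <- adwt_design_params(wavelet, base_fs)
  fir <- daubechies_filters(params$wavelet, base_fs)
  rows <- lapply(c("details", "approximation"), function(br) {
    band <- default_gd_band(params, br)
    f <- log_freq_grid(band[1], band[2], n_grid)
    tf <- switch(br, details = design_details_filter(params),
                 approximation = design_approx_filter(params))
    h <- switch(br, details = fir$highpass, approximation = fir$lowpass)
    eq <- equalize_and_error(analog_group_delay(tf, f),
                             fir_group_delay(h, base_fs, f), band)
    data.frame(branch = br, fixed_delay_s = eq$fixed_delay,
               peak_pct_cycle = eq$peak)
  })
  do.call(rbind, rows)
}
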