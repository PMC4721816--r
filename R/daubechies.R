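#' Daubechies wavelet specification
#'
#' @param wavelet either a name such as `"db4"` or a positive integer order
#'   (number of vanishing moments; the FIR filters have 2 * order taps).
#' @return list with `name` and `order`, class `wavelet_spec`.
#' @export
wavelet_spec <- function(wavelet) {
  if (inherits(wavelet, "wavelet_spec")) return(wavelet)
  if (is.character(wavelet)) {
    m <- regmatches(wavelet, regexec("^[dD][bB]([0-9]+)$", wavelet))[[1]]
    if (length(m) < 2L) stop("unrecognised wavelet name: ", wavelet)
    order <- as.integer(m[2])
  } else {
    order <- as.integer(wavelet)
  }
  if (is.na(order) || order < 1L) stop("wavelet order must be a positive integer")
  structure(list(name = paste0("db", order), order = order),
            class = "wavelet_spec")
}

#' Daubechies decomposition filter pair
#'
#' Constructs the orthogonal Daubechies decomposition (analysis) FIR pair by
#' spectral factorization of the maximally flat half-band autocorrelation,
#' with minimum-phase root selection. The lowpass (approximation) filter sums
#' to sqrt(2); the highpass (details) filter is its quadrature-mirror
#' alternating-sign reversal and sums to zero.
#'
#' @param wavelet a [wavelet_spec()], name, or order.
#' @param base_fs sampling frequency in Hz attached to the pair (bookkeeping
#'   for band edges and group-delay analysis).
#' @return object of class `fir_pair`: `lowpass`, `highpass` (index 1 is the
#'   z^0 tap), `wavelet`, `base_fs`.
#' @export
daubechies_filters <- function(wavelet, base_fs = 1) {
  spec <- wavelet_spec(wavelet)
  N <- spec$order
  if (N == 1L) {
    h <- c(1, 1) / sqrt(2)  # Haar scaling filter
  } else {
    # P(y) = sum_{k<N} C(N-1+k, k) y^k, y = (2 - z - 1/z)/4.
    # Roots of z^{N-1} P(y(z)) come in (r, 1/r) pairs; keep |r| < 1.
    pk <- choose(N - 1 + 0:(N - 1), 0:(N - 1))
    # y^k expressed in z: ((2 - z - z^-1)/4)^k * z^{N-1}, ascending powers of z
    acc <- numeric(2 * N - 1)
    base <- c(-1, 2, -1) / 4         # z^{-1}, z^0, z^{1} of y
    term <- 1                        # y^0
    for (k in 0:(N - 1)) {
      # term holds coefficients of y^k in powers z^{-k}..z^{k}
      padded <- numeric(2 * N - 1)
      off <- N - k                   # position of z^{-k} within z^{-(N-1)}..z^{N-1}
      padded[off:(off + length(term) - 1)] <- term
      acc <- acc + pk[k + 1] * padded
      if (k < N - 1) term <- convolve_full(term, base)
    }
    r <- polyroot(acc)
    r <- r[Mod(r) < 1]               # minimum-phase half of each pair
    stopifnot(length(r) == N - 1)
    q <- real_poly(r)
    h <- convolve_full(choose(N, 0:N), rev(q))
    h <- h * sqrt(2) / sum(h)
  }
  # h is already the decomposition (analysis) lowpass: the time-reversed
  # minimum-phase scaling filter, energy concentrated at the filter tail
  lowpass <- h
  L <- length(lowpass)
  highpass <- (-1)^(1:L) * lowpass[L:1]
  structure(list(lowpass = lowpass, highpass = highpass,
                 wavelet = spec, base_fs = base_fs),
            class = "fir_pair")
}

# full linear convolution of two coefficient vectors
convolve_full <- function(a, b) {
  if (!length(a) || !length(b)) return(numeric(0))
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' @export
print.fir_pair <- function(x, ...) {
  cat(sprintf("fir_pair: %s decomposition filters (fs = %g Hz)\n",
              x$wavelet$name, x$base_fs))
  cat("  lowpass :", paste(sprintf("%.3f", x$lowpass), collapse = " "), "\n")
  cat("  highpass:", paste(sprintf("%.3f", x$highpass), collapse = " "), "\n")
  invisible(x)
}

# causal zero-state FIR filtering: y[n] = sum_k h[k] x[n-k]
fir_filter_causal <- function(h, x) {
  y <- as.numeric(stats::filter(c(x), h, method = "convolution", sides = 1))
  # sides = 1 leaves the first length(h)-1 outputs NA; fill by direct sums
  for (n in seq_len(min(length(h) - 1, length(x)))) {
    k <- 1:n
    y[n] <- sum(h[k] * x[n - k + 1])
  }
  y
}

# circular (periodic-extension) FIR filtering
fir_filter_periodic <- function(h, x) {
  n <- length(x)
  H <- stats::fft(c(h, numeric(n - length(h))))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Multi-resolution DWT decomposition
#'
#' Recursive two-channel analysis filter bank with factor-2 decimation: at
#' each level the running approximation stream is filtered by both
#' decomposition filters and the odd-indexed outputs (0-based indexing, i.e.
#' every second sample starting from the second) are retained. Each retained
#' coefficient keeps the time stamp of the sample position it was computed at;
#' no group-delay correction is applied at this layer.
#'
#' @param x numeric signal vector or a [sampled_signal()].
#' @param wavelet wavelet name, order, or [wavelet_spec()].
#' @param levels number of decomposition levels.
#' @param fs sampling frequency in Hz (ignored when `x` is a
#'   `sampled_signal`).
#' @param mode boundary handling: `"causal"` (zero initial condition, the
#'   analog-comparison convention) or `"periodic"` (circular extension,
#'   energy-conserving).
#' @return object of class `dwt_decomposition`: per-level `details` (each a
#'   data.frame of `time`, `value`), final-level `approximation`, plus all
#'   intermediate approximations in `approx_levels`, `base_fs`, `wavelet`.
#' @export
dwt_multires <- function(x, wavelet, levels, fs = NULL,
                         mode = c("causal", "periodic")) {
  mode <- match.arg(mode)
  if (inherits(x, "sampled_signal")) {
    fs <- x$fs
    x <- c(x$value)
  }
  if (is.null(fs)) stop("fs required when x is a bare vector")
  if (!all(is.finite(x))) stop("non-finite samples in input")
  spec <- wavelet_spec(wavelet)
  fp <- daubechies_filters(spec, base_fs = fs)
  L <- length(fp$lowpass)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  if (length(x) < 2^levels * L)
    stop("signal too short for ", levels, " levels (need >= ",
         2^levels * L, " samples)")
  filt <- switch(mode, causal = fir_filter_causal,
                 periodic = fir_filter_periodic)
  tcur <- seq_along(x) / fs - 1 / fs
  acur <- x
  details <- vector("list", levels)
  approx_levels <- vector("list", levels)
  for (i in seq_len(levels)) {
    d <- filt(fp$highpass, acur)
    a <- filt(fp$lowpass, acur)
    keep <- seq(2, length(acur), by = 2)   # odd samples, 0-based
    details[[i]] <- data.frame(time = tcur[keep], value = d[keep])
    approx_levels[[i]] <- data.frame(time = tcur[keep], value = a[keep])
    acur <- a[keep]
    tcur <- tcur[keep]
  }
  structure(list(levels = levels, details = details,
                 approximation = approx_levels[[levels]],
                 approx_levels = approx_levels,
                 base_fs = fs, wavelet = spec, mode = mode),
            class = "dwt_decomposition")
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  cat(sprintf("dwt_decomposition: %s, %d levels, fs = %g Hz (%s mode)\n",
              x$wavelet$name, x$levels, x$base_fs, x$mode))
  for (i in seq_len(x$levels))
    cat(sprintf("  D%d: %d coefficients at %g Hz\n", i,
                nrow(x$details[[i]]), x$base_fs / 2^i))
  cat(sprintf("  A%d: %d coefficients\n", x$levels, nrow(x$approximation)))
  invisible(x)
}

#' Frequency band covered by a decomposition branch
#'
#' Details at level L span `[fs/2^(L+1), fs/2^L]`; the approximation at level
#' L spans `[0, fs/2^(L+1)]`. At 100 Hz and four levels this yields the EEG
#' sub-bands 12.5-25, 6.25-12.5, 3.125-6.25 and 0-3.125 Hz.
#'
#' @param base_fs base sampling frequency in Hz.
#' @param branch `"details"` or `"approximation"`.
#' @param level decomposition level (>= 1).
#' @return numeric length-2 vector, band edges in Hz.
#' @export
band_edges <- function(base_fs, branch = c("details", "approximation"), level) {
  branch <- match.arg(branch)
  level <- as.integer(level)
  stopifnot(base_fs > 0, level >= 1L)
  switch(branch,
         details = c(base_fs / 2^(level + 1), base_fs / 2^level),
         approximation = c(0, base_fs / 2^(level + 1)))
}
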