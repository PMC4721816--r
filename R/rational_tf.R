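#' Continuous-time rational transfer functions
#'
#' A `rational_tf` is an s-domain transfer function H(s) = k * prod(s - z_i) /
#' prod(s - p_j) with frequencies in rad/s. High-order filter polynomials at
#' physiological frequency scales span many orders of magnitude (the
#' fourth-order notch denominator reaches 1e16), so the object is carried as
#' zeros/poles/gain and expanded to polynomial coefficients only on demand.
#'
#' @param zeros complex vector of zeros (rad/s); must be closed under
#'   conjugation so the coefficients are real.
#' @param poles complex vector of poles (rad/s); same constraint.
#' @param gain real scalar gain multiplying the monic zero polynomial.
#' @return an object of class `rational_tf`.
#' @export
rational_tf <- function(zeros = complex(0), poles = complex(0), gain = 1) {
  zeros <- as.complex(zeros)
  poles <- as.complex(poles)
  stopifnot(is.numeric(gain) || is.complex(gain), length(gain) == 1L)
  if (abs(Im(gain)) > 1e-9 * max(1, abs(gain)))
    stop("gain must be real")
  gain <- Re(gain)
  if (!all(is.finite(c(Re(zeros), Im(zeros), Re(poles), Im(poles), gain))))
    stop("non-finite zero/pole/gain")
  if (length(zeros) > length(poles))
    stop("improper transfer function: more zeros than poles")
  check_conjugate <- function(r) {
    if (length(r) == 0L) return(TRUE)
    scale <- max(abs(r), 1)
    all(vapply(r, function(ri) {
      min(abs(Conj(ri) - r)) <= 1e-8 * scale
    }, logical(1)))
  }
  if (!check_conjugate(zeros) || !check_conjugate(poles))
    stop("zeros/poles must be closed under complex conjugation")
  structure(list(zeros = zeros, poles = poles, gain = gain),
            class = "rational_tf")
}

# expand a self-conjugate root set to real monic polynomial coefficients
# (descending powers)
real_poly <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0) - c(0, r * p)
  if (length(roots) && max(abs(Im(p))) > 1e-6 * max(abs(p)))
    stop("roots not conjugate-symmetric")
  Re(p)
}

#' Polynomial coefficients of a rational transfer function
#'
#' @param tf a [rational_tf()].
#' @return list with `num` and `den`, real coefficients in descending powers
#'   of s.
#' @export
tf_coeffs <- function(tf) {
  stopifnot(inherits(tf, "rational_tf"))
  list(num = tf$gain * real_poly(tf$zeros), den = real_poly(tf$poles))
}

#' Build a rational_tf from polynomial coefficients
#'
#' @param num,den real coefficients, descending powers of s.
#' @return a [rational_tf()].
#' @export
tf_from_coeffs <- function(num, den) {
  num <- as.numeric(num); den <- as.numeric(den)
  num <- num[cumsum(abs(num)) > 0]  # strip leading zeros
  den <- den[cumsum(abs(den)) > 0]
  if (!length(den)) stop("zero denominator")
  zeros <- if (length(num) > 1L) polyroot(rev(num)) else complex(0)
  poles <- if (length(den) > 1L) polyroot(rev(den)) else complex(0)
  rational_tf(zeros, poles, num[1] / den[1])
}

#' Frequency response of a rational transfer function
#'
#' Evaluates H(j 2 pi f) from the factored form (numerically stable at
#' high polynomial scales).
#'
#' @param tf a [rational_tf()].
#' @param freq_hz frequencies in Hz.
#' @return complex response values.
#' @export
freq_resp <- function(tf, freq_hz) {
  stopifnot(inherits(tf, "rational_tf"))
  s <- 2i * pi * freq_hz
  h <- rep(tf$gain + 0i, length(s))
  for (z in tf$zeros) h <- h * (s - z)
  for (p in tf$poles) h <- h / (s - p)
  h
}

#' @export
print.rational_tf <- function(x, ...) {
  co <- tf_coeffs(x)
  fmt <- function(v) paste(signif(v, 5), collapse = ", ")
  cat("rational_tf (s-domain, rad/s)\n")
  cat("  num:", fmt(co$num), "\n")
  cat("  den:", fmt(co$den), "\n")
  cat(sprintf("  %d zeros, %d poles, gain %.6g\n",
              length(x$zeros), length(x$poles), x$gain))
  invisible(x)
}

#' Sampled signal container
#'
#' @param value numeric vector (or matrix, one channel per column) of samples.
#' @param fs sampling frequency in Hz.
#' @param t0 time of the first sample in seconds.
#' @return object of class `sampled_signal` with `time`, `value`, `fs`.
#' @export
sampled_signal <- function(value, fs, t0 = 0) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  n <- if (is.matrix(value)) nrow(value) else length(value)
  structure(list(time = t0 + seq_len(n) / fs - 1 / fs,
                 value = value, fs = fs),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- if (is.matrix(x$value)) nrow(x$value) else length(x$value)
  ch <- if (is.matrix(x$value)) ncol(x$value) else 1L
  cat(sprintf("sampled_signal: %d samples, %d channel(s), fs = %g Hz, %.3f s\n",
              n, ch, x$fs, n / x$fs))
  invisible(x)
}
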