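# brute-force convolution oracle, independent of the implementation path
conv_oracle <- function(h, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    k <- seq_len(min(i, length(h)))
    y[i] <- sum(h[k] * x[i - k + 1])
  }
  y
}

# DTFT of an FIR filter at frequency f (Hz) for sampling rate fs
fir_dtft <- function(h, f, fs) {
  n <- seq_along(h) - 1
  vapply(f, function(ff) sum(h * exp(-1i * 2 * pi * ff / fs * n)), complex(1))
}

# greedy peak picking with a refractory separation
pick_peaks <- function(tv, env, n, min_sep = 0.3) {
  lm <- which(diff(sign(diff(env))) == -2) + 1
  lm <- lm[order(env[lm], decreasing = TRUE)]
  keep <- integer(0)
  for (i in lm) {
    if (all(abs(tv[i] - tv[keep]) > min_sep)) keep <- c(keep, i)
    if (length(keep) == n) break
  }
  sort(tv[keep])
}

moving_avg <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1, w) / w, sides = 2))
  y[is.na(y)] <- 0
  y
}
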