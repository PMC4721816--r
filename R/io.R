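#' Read a sampled signal from delimited text
#'
#' Comma-separated, header row, `#`-prefixed comment lines permitted (these
#' carry embedded run configuration in files the package writes). Either the
#' first column is `time_s` (validated uniform to 1e-6 relative, sampling
#' rate inferred) or all columns are values and `fs` must be supplied.
#'
#' @param path file path.
#' @param fs sampling frequency override in Hz (required when no time
#'   column is present).
#' @return a [sampled_signal()] (matrix-valued when several value columns).
#' @export
read_signal <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0) stop("empty signal file: ", path)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric columns in ", path)
  has_time <- tolower(names(df)[1]) %in% c("time_s", "time", "t")
  if (has_time) {
    tm <- df[[1]]
    dt <- diff(tm)
    if (length(dt) < 1) stop("need at least 2 samples to infer fs")
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
      stop("non-uniform time column; supply fs explicitly after resampling")
    fs_det <- 1 / dt[1]
    if (!is.null(fs) && abs(fs - fs_det) > 1e-6 * fs_det)
      stop("fs override disagrees with time column")
    v <- as.matrix(df[, -1, drop = FALSE])
    if (ncol(v) == 1) v <- c(v)
    return(sampled_signal(v, fs_det, t0 = tm[1]))
  }
  if (is.null(fs)) stop("no time column and no fs supplied")
  v <- as.matrix(df)
  if (ncol(v) == 1) v <- c(v)
  sampled_signal(v, fs)
}

#' Write a sampled signal to delimited text
#'
#' Mirrors [read_signal()]: a `time_s` column followed by one column per
#' channel, full precision, with any configuration serialized into `#`
#' comment lines at the top.
#'
#' @param sig a [sampled_signal()].
#' @param path output path.
#' @param config optional named list written as `# key=value` header lines.
#' @export
write_signal <- function(sig, path, config = NULL) {
  stopifnot(inherits(sig, "sampled_signal"))
  v <- sig$value
  if (!is.matrix(v)) v <- matrix(v, ncol = 1)
  df <- data.frame(time_s = sig$time, v)
  names(df)[-1] <- paste0("ch", seq_len(ncol(v)))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s=%s", k, format(config[[k]])), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a decomposition as one record per coefficient
#'
#' @param result a [dwt_multires()] or [adwt_multires()] result.
#' @param path output path; columns `level`, `branch`, `time_s`, `value`.
#' @param config optional named list of `#` header lines.
#' @export
write_decomposition <- function(result, path, config = NULL) {
  levels <- if (inherits(result, "dwt_decomposition")) result$levels
            else result$bank$levels
  rows <- list()
  for (i in seq_len(levels)) {
    for (br in c("D", "A")) {
      s <- branch_series(result, paste0(br, i))
      rows <- c(rows, list(data.frame(level = i, branch = br,
                                      time_s = s$time, value = s$value)))
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s=%s", k, format(config[[k]])), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a filter bank as structured text records
#'
#' One record per filter: branch, level, zeros, poles, gain, plus the
#' expanded polynomial coefficients for display.
#'
#' @param bank an [build_filter_bank()] result.
#' @return data.frame with character-encoded root lists.
#' @export
bank_as_table <- function(bank) {
  stopifnot(inherits(bank, "adwt_bank"))
  enc <- function(z) paste(sprintf("%.10g%+.10gi", Re(z), Im(z)),
                           collapse = ";")
  rows <- list()
  for (i in seq_len(bank$levels)) {
    for (br in c("A", "D")) {
      tf <- bank[[br]][[i]]
      co <- tf_coeffs(tf)
      rows <- c(rows, list(data.frame(
        branch = br, level = i, zeros = enc(tf$zeros), poles = enc(tf$poles),
        gain = tf$gain,
        num = paste(signif(co$num, 6), collapse = ";"),
        den = paste(signif(co$den, 6), collapse = ";"),
        base_fs = bank$design$base_fs, mode = bank$mode)))
    }
  }
  do.call(rbind, rows)
}
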