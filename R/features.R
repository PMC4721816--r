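#' Epoch band powers from a multi-resolution decomposition
#'
#' Splits each branch output into fixed non-overlapping epochs and computes
#' the per-sample mean square in every epoch. Using the mean (not the sum)
#' of squares puts decimated DWT coefficient streams and continuous analog
#' outputs on a common scale. An output sample at time t belongs to epoch
#' `floor(t / epoch_s)`; the trailing partial epoch is dropped.
#'
#' @param result a [dwt_multires()] or [adwt_multires()] result.
#' @param epoch_s epoch length in seconds (default 30).
#' @param branches character vector of branch names such as `"D2"`, `"A4"`.
#'   The default is the four sub-bands used for sleep/wake classification
#'   (level-1 details excluded).
#' @param log10_transform take log10 of the powers (features spanning decades
#'   become comparable; zero powers map to the smallest positive double).
#' @return data.frame: `epoch` (0-based) plus one power column per branch.
#' @export
epoch_band_powers <- function(result, epoch_s = 30,
                              branches = c("D2", "D3", "D4", "A4"),
                              log10_transform = FALSE) {
  stopifnot(epoch_s > 0)
  series <- lapply(branches, function(b) branch_series(result, b))
  n_epochs <- min(vapply(series, function(s) {
    floor((max(s$time) + time_step(result)) / epoch_s)
  }, numeric(1)))
  if (n_epochs < 1L) stop("no complete epoch in any branch")
  out <- data.frame(epoch = seq_len(n_epochs) - 1L)
  for (j in seq_along(branches)) {
    s <- series[[j]]
    ep <- floor(s$time / epoch_s)
    keep <- ep < n_epochs
    if (!any(keep)) stop("epoch with no samples in branch ", branches[j])
    p <- tapply(s$value[keep]^2, factor(ep[keep], levels = 0:(n_epochs - 1)),
                mean)
    if (anyNA(p)) {
      drop_ep <- which(is.na(p)) - 1L
      message("branch ", branches[j], ": epochs with no samples dropped: ",
              paste(drop_ep, collapse = ", "))
    }
    out[[branches[j]]] <- as.numeric(p)
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (log10_transform)
    for (b in branches) out[[b]] <- log10(pmax(out[[b]], .Machine$double.xmin))
  out
}

branch_series <- function(result, name) {
  m <- regmatches(name, regexec("^([AD])([0-9]+)$", name))[[1]]
  if (length(m) < 3L) stop("branch name must look like D2 or A4: ", name)
  br <- m[2]; lev <- as.integer(m[3])
  if (inherits(result, "dwt_decomposition")) {
    if (lev > result$levels) stop("level ", lev, " beyond decomposition")
    if (br == "D") result$details[[lev]] else result$approx_levels[[lev]]
  } else if (inherits(result, "adwt_multires_result")) {
    if (lev > result$bank$levels) stop("level ", lev, " beyond bank")
    v <- if (br == "D") result$D[[lev]] else result$A[[lev]]
    data.frame(time = result$time, value = v)
  } else stop("unsupported result type")
}

time_step <- function(result) {
  if (inherits(result, "adwt_multires_result")) 1 / result$fs_out
  else 2^result$levels / result$base_fs
}

#' Confusion counts for a two-class labelling
#'
#' @param truth,pred factors or character vectors of class labels.
#' @param positive the label treated as the positive class.
#' @return object of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == positive & pred == positive),
                 FP = sum(truth != positive & pred == positive),
                 FN = sum(truth == positive & pred != positive),
                 TN = sum(truth != positive & pred != positive)),
            class = "confusion_counts")
}

#' Sensitivity (true positive rate, percent)
#'
#' `100 * TP / (TP + FN)`: the fraction of expert-marked positives that are
#' correctly classified.
#'
#' @param c a [confusion_counts()].
#' @return percentage in `[0, 100]`.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0) stop("sensitivity undefined: no positives in truth")
  100 * c$TP / (c$TP + c$FN)
}

#' Selectivity (positive predictive value, percent)
#'
#' `100 * TP / (TP + FP)`: the fraction of positive classifications that are
#' correct.
#'
#' @param c a [confusion_counts()].
#' @return percentage in `[0, 100]`.
#' @export
selectivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FP == 0) stop("selectivity undefined: no positive predictions")
  100 * c$TP / (c$TP + c$FP)
}

#' Classifier specification
#'
#' @param classifier `"nnet"` (single-hidden-layer feed-forward network,
#'   logistic hidden units) or `"logistic"` (deterministic logistic
#'   regression, no random initialization).
#' @param hidden hidden layer size for `"nnet"`.
#' @param maxit maximum training iterations.
#' @param seed integer seed for weight initialization.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(classifier = c("nnet", "logistic"), hidden = 8,
                            maxit = 300, seed = 1) {
  classifier <- match.arg(classifier)
  stopifnot(hidden >= 1, maxit >= 1)
  structure(list(classifier = classifier, hidden = hidden,
                 maxit = maxit, seed = as.integer(seed)),
            class = "classifier_spec")
}

train_classifier <- function(xtr, ytr, spec) {
  ytr <- factor(ytr)
  if (spec$classifier == "nnet") {
    set.seed(spec$seed)
    fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = spec$hidden,
                      softmax = TRUE, maxit = spec$maxit, trace = FALSE)
    function(xte) {
      levels(ytr)[max.col(predict(fit, xte))]
    }
  } else {
    df <- data.frame(y = as.integer(ytr) - 1L, xtr)
    # complete separation is the expected regime for well-separated states;
    # the fitted class boundary is still usable, so silence glm's complaints
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    function(xte) {
      p <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(xte), type = "response"))
      levels(ytr)[1L + as.integer(p > 0.5)]
    }
  }
}

#' Leave-one-record-out cross-validated classification experiment
#'
#' Trains a classifier on all records but one and tests on the held-out
#' record, cycling through every record; reported metrics are the averages of
#' the out-of-sample fold metrics per class. Features are log10-transformed
#' (optional) and standardized with the training folds' statistics. With
#' `test_features = "adwt"` the networks are trained on the digital (DWT)
#' feature tables but the held-out record is evaluated on its paired analog
#' (ADWT) feature table — the transfer experiment probing whether the analog
#' band powers can substitute for the digital ones at deployment time.
#'
#' @param tables named-or-ordered list of per-record feature data.frames;
#'   each must hold a `label` column and identical feature columns.
#' @param spec a [classifier_spec()].
#' @param test_features `"same"` or `"adwt"`.
#' @param adwt_tables paired list of feature tables (same records, same
#'   epochs) used for testing when `test_features = "adwt"`.
#' @param log10_features apply log10 to the feature columns before
#'   standardization.
#' @return data.frame of class `loocv_report`: one row per class with
#'   averaged `sensitivity` and `selectivity` (percent) plus fold count.
#' @export
loocv_experiment <- function(tables, spec = classifier_spec(),
                             test_features = c("same", "adwt"),
                             adwt_tables = NULL, log10_features = TRUE) {
  test_features <- match.arg(test_features)
  stopifnot(length(tables) >= 2)
  if (test_features == "adwt") {
    stopifnot(!is.null(adwt_tables), length(adwt_tables) == length(tables))
  }
  feat_cols <- setdiff(colnames(tables[[1]]), c("label", "epoch", "record"))
  get_xy <- function(tab) {
    x <- as.matrix(tab[, feat_cols, drop = FALSE])
    if (log10_features) x <- log10(pmax(x, .Machine$double.xmin))
    list(x = x, y = as.character(tab$label))
  }
  classes <- sort(unique(unlist(lapply(tables, function(t) as.character(t$label)))))
  stopifnot(length(classes) == 2)
  folds <- list()
  for (k in seq_along(tables)) {
    tr <- do.call(rbind, lapply(tables[-k], function(t)
      t[, c(feat_cols, "label")]))
    trxy <- get_xy(tr)
    if (length(unique(trxy$y)) < 2L) {
      message("fold ", k, ": single-class training set; skipped")
      next
    }
    mu <- colMeans(trxy$x)
    sdv <- apply(trxy$x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    std <- function(x) sweep(sweep(x, 2, mu), 2, sdv, "/")
    predict_fun <- train_classifier(std(trxy$x), trxy$y, spec)
    te_tab <- if (test_features == "adwt") adwt_tables[[k]] else tables[[k]]
    texy <- get_xy(te_tab)
    pred <- predict_fun(std(texy$x))
    fold <- lapply(classes, function(cl) {
      cc <- confusion_counts(texy$y, pred, positive = cl)
      data.frame(class = cl,
                 sensitivity = if (cc$TP + cc$FN > 0) sensitivity(cc) else NA,
                 selectivity = if (cc$TP + cc$FP > 0) selectivity(cc) else NA)
    })
    folds <- c(folds, list(do.call(rbind, fold)))
  }
  if (!length(folds)) stop("no usable folds")
  all <- do.call(rbind, folds)
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- all[all$class == cl, ]
    data.frame(class = cl,
               sensitivity = mean(sub$sensitivity, na.rm = TRUE),
               selectivity = mean(sub$selectivity, na.rm = TRUE),
               n_folds = sum(!is.na(sub$sensitivity)))
  }))
  class(out) <- c("loocv_report", "data.frame")
  out
}

#' Per-record epoch feature table for a two-channel EEG-like record
#'
#' Decomposes each channel four levels with the requested transform and
#' returns the 8-feature epoch table (four sub-band powers per channel:
#' D2, D3, D4, A4) with the per-epoch state labels attached.
#'
#' @param record one record from [synth_eeg()] (fields `signal`, `labels`).
#' @param wavelet wavelet name or order.
#' @param transform `"dwt"` or `"adwt"`.
#' @param epoch_s epoch length in seconds.
#' @param levels decomposition levels.
#' @param oversample simulation oversampling for the analog transform (1 is
#'   adequate for band powers; the analog outputs are already band-limited).
#' @return data.frame: `epoch`, eight feature columns `ch<k>_<branch>`,
#'   `label`.
#' @export
record_features <- function(record, wavelet, transform = c("dwt", "adwt"),
                            epoch_s = 30, levels = 4, oversample = 1) {
  transform <- match.arg(transform)
  sig <- record$signal
  stopifnot(inherits(sig, "sampled_signal"), is.matrix(sig$value))
  branches <- c(paste0("D", 2:levels), paste0("A", levels))
  bank <- NULL
  if (transform == "adwt")
    bank <- build_filter_bank(adwt_design_params(wavelet, sig$fs),
                              levels, mode = "table2", gain_mode = "printed")
  tabs <- lapply(seq_len(ncol(sig$value)), function(ch) {
    x <- sig$value[, ch]
    res <- if (transform == "dwt") {
      dwt_multires(x, wavelet, levels, fs = sig$fs)
    } else {
      adwt_multires(x, bank, fs = sig$fs, oversample = oversample)
    }
    bp <- epoch_band_powers(res, epoch_s = epoch_s, branches = branches)
    names(bp)[-1] <- paste0("ch", ch, "_", branches)
    bp
  })
  out <- Reduce(function(a, b) merge(a, b, by = "epoch"), tabs)
  n <- min(nrow(out), length(record$labels))
  out <- out[seq_len(n), , drop = FALSE]
  out$label <- record$labels[seq_len(n)]
  out
}
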