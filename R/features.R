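# Time- and frequency-domain feature bank. Per selected axis: 15 statistics
# (min, max, median, quartiles, kurtosis, skewness, range, mean, variance,
# standard deviation, RMS, dominant frequency, spectral energy, spectral
# entropy). Per selected sensor: signal magnitude area, energy and entropy
# over its three axes. When the accelerometer is selected, the per-sample
# VeDBA magnitude sqrt(ax^2 + ay^2 + az^2) contributes the same 15
# statistics. Counts: accelerometer only 3x15 + 3 + 15 = 63; gyroscope only
# 3x15 + 3 = 48; both sensors 111.

# One-sided amplitude spectrum with the DC bin removed; N_bins = floor(n/2)
one_sided_spectrum <- function(x) {
  n <- length(x)
  nb <- floor(n / 2)
  Mod(stats::fft(x))[1 + seq_len(nb)]
}

# dominant frequency tolerant of flat windows (0 Hz by convention)
window_dominant_frequency <- function(x, fs) {
  if (max(x) == min(x)) return(0)
  Fk <- one_sided_spectrum(x)
  if (all(Fk == 0)) return(0)
  (which.max(Fk)) * fs / length(x)  # bin k (1-based, DC removed) -> k*fs/n
}

spectral_energy <- function(x) {
  Fk <- one_sided_spectrum(x)
  sum(Fk^2) / length(Fk)
}

# Shannon entropy of the normalized one-sided spectrum, in bits
spectral_entropy <- function(x) {
  Fk <- one_sided_spectrum(x)
  tot <- sum(Fk)
  if (tot == 0) return(0)
  p <- Fk[Fk > 0] / tot
  -sum(p * log2(p))
}

safe_moment <- function(x, fun) {
  if (stats::sd(x) == 0) return(0)  # undefined on zero-variance windows -> 0
  fun(x)
}

# the 15 per-series statistics
series_stats <- function(x, fs) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(min = min(x),
    max = max(x),
    median = q[2],
    q75 = q[3],
    q25 = q[1],
    kurtosis = safe_moment(x, e1071::kurtosis),
    skewness = safe_moment(x, e1071::skewness),
    range = max(x) - min(x),
    mean = mean(x),
    variance = stats::var(x),
    sd = stats::sd(x),
    rms = sqrt(mean(x^2)),
    domfreq = window_dominant_frequency(x, fs),
    spec_energy = spectral_energy(x),
    spec_entropy = spectral_entropy(x))
}

# Per-sensor three-axis summaries. The magnitude-area and entropy forms use
# s_i = |X_i| + |Y_i| + |Z_i| (the conventional SMA magnitude); energy is the
# mean summed squared magnitude.
sensor_stats <- function(m) {
  s <- abs(m[, 1]) + abs(m[, 2]) + abs(m[, 3])
  e <- m[, 1]^2 + m[, 2]^2 + m[, 3]^2
  c(sma = mean(s),
    energy = mean(e),
    entropy = mean((1 + s^2) * log(1 + s^2)))
}

#' Compute the feature vector of one window
#'
#' @param window A `window_view` (see [window_partition()]) or a numeric
#'   matrix of samples with the six channel columns.
#' @param sensors Which sensor group to use: `"both"`, `"acc"` or `"gyr"`.
#' @param fs Sampling frequency (Hz); taken per second of window data.
#' @return Named numeric vector: 63 features for `"acc"`, 48 for `"gyr"`,
#'   111 for `"both"`. All values are finite.
#' @examples
#' sim <- synthesize_imu(make_schedule("walking", 3), seed = 1)
#' w <- as.matrix(sim$stream$data)
#' length(compute_features(w, "both"))  # 111
#' length(compute_features(w, "acc"))   # 63
#' length(compute_features(w, "gyr"))   # 48
#' @export
compute_features <- function(window, sensors = c("both", "acc", "gyr"), fs = 20) {
  sensors <- match.arg(sensors)
  m <- if (inherits(window, "window_view")) window$data else as.matrix(window)
  stopifnot(all(CHANNELS %in% colnames(m)))
  if (any(!is.finite(m))) stop("non-finite samples in window", call. = FALSE)
  out <- numeric(0)
  axes <- switch(sensors, both = CHANNELS, acc = ACC_CHANNELS, gyr = GYR_CHANNELS)
  for (ch in axes) {
    st <- series_stats(m[, ch], fs)
    names(st) <- paste(ch, names(st), sep = "_")
    out <- c(out, st)
  }
  if (sensors %in% c("both", "acc")) {
    st <- sensor_stats(m[, ACC_CHANNELS])
    names(st) <- paste("acc", names(st), sep = "_")
    out <- c(out, st)
  }
  if (sensors %in% c("both", "gyr")) {
    st <- sensor_stats(m[, GYR_CHANNELS])
    names(st) <- paste("gyr", names(st), sep = "_")
    out <- c(out, st)
  }
  if (sensors %in% c("both", "acc")) {
    vedba <- sqrt(rowSums(m[, ACC_CHANNELS]^2))
    st <- series_stats(vedba, fs)
    names(st) <- paste("vedba", names(st), sep = "_")
    out <- c(out, st)
  }
  out
}

#' Build a feature table from a labelled stream
#'
#' Windows the stream, keeps training-quality windows (complete, purity 1,
#' real behavior) and computes one feature vector per window.
#'
#' @param stream A labelled `imu_stream`.
#' @param size Window length (s).
#' @param sensors `"both"`, `"acc"` or `"gyr"`.
#' @param mode Window mode passed to [window_partition()].
#' @param exclude Behaviors to drop from the table (e.g. `"running"` when
#'   bouts of that behavior are too short for the window size).
#' @return A data frame of features with a `label` column (factor over the
#'   behaviors present) and a `start` column (window offset, seconds).
#' @export
build_feature_table <- function(stream, size, sensors = "both", mode = "jump",
                                exclude = character()) {
  windows <- window_partition(stream, size, mode, training = TRUE)
  windows <- Filter(function(w) !(w$majority %in% exclude), windows)
  if (!length(windows)) stop("no pure training windows at size ", size, call. = FALSE)
  fs <- stream$sample_rate
  feats <- t(vapply(windows, compute_features, sensors = sensors, fs = fs,
                    FUN.VALUE = compute_features(windows[[1]], sensors, fs)))
  out <- as.data.frame(feats)
  out$label <- factor(vapply(windows, `[[`, "", "majority"))
  out$start <- vapply(windows, `[[`, 0, "start")
  out
}

#' Feature column names of a feature table
#' @param df A [build_feature_table()] result.
#' @return Character vector of feature column names (label/start excluded).
#' @export
feature_columns <- function(df) setdiff(names(df), c("label", "start"))

#' Stratified train/test split with z-score standardization
#'
#' Splits the rows of a feature table class-by-class at the given training
#' fraction, then standardizes every feature column to zero mean and unit
#' variance using statistics estimated on the training rows only; the test
#' rows are transformed with those same training statistics.
#'
#' @param features Data frame or matrix of feature columns.
#' @param labels Factor or character labels, one per row.
#' @param train_frac Training fraction (default 0.8 for an 80/20 split).
#' @param seed Integer seed for the random split.
#' @return A list of class `"feature_dataset"`: standardized `train` and
#'   `test` matrices, `train_labels`, `test_labels`, the training `center`
#'   and `scale` per feature, and the row indices of the split.
#' @export
split_standardize <- function(features, labels, train_frac = 0.8, seed = NULL) {
  x <- as.matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels), train_frac > 0, train_frac < 1)
  counts <- table(labels)
  if (any(counts < 5)) {
    stop("every class needs at least 5 rows; too few: ",
         paste(names(counts)[counts < 5], collapse = ", "), call. = FALSE)
  }
  idx_train <- with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      rows <- which(labels == cl)
      sample(rows, floor(length(rows) * train_frac))
    }))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(nrow(x)), idx_train)
  center <- colMeans(x[idx_train, , drop = FALSE])
  scale <- apply(x[idx_train, , drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1  # constant feature: leave centred, unscaled
  std <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  structure(list(train = std(x[idx_train, , drop = FALSE]),
                 test = std(x[idx_test, , drop = FALSE]),
                 train_labels = droplevels(labels[idx_train]),
                 test_labels = droplevels(labels[idx_test]),
                 center = center, scale = scale,
                 idx_train = idx_train, idx_test = idx_test),
            class = "feature_dataset")
}

#' Apply or invert stored standardization statistics
#'
#' @param x Feature matrix (raw for `standardize_features()`, standardized
#'   for `destandardize_features()`).
#' @param center,scale Per-feature statistics, as stored in a
#'   [split_standardize()] result or a fitted model bundle.
#' @return Transformed matrix.
#' @export
standardize_features <- function(x, center, scale) {
  x <- as.matrix(x)
  sweep(sweep(x[, names(center), drop = FALSE], 2, center), 2, scale, "/")
}

#' @rdname standardize_features
#' @export
destandardize_features <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, scale, "*"), 2, center, "+")
}

#' Rank features by boosted-tree importance
#'
#' Fits an AdaBoost ensemble (see [adaboost()]) on the full table and ranks
#' features by their accumulated, weight-adjusted split importance. Features
#' the ensemble never uses score zero. Ties are broken alphabetically by
#' feature name so the ranking is reproducible.
#'
#' @param x Feature matrix or data frame.
#' @param y Labels (>= 2 classes).
#' @param k Number of top features to return.
#' @param rounds,maxdepth Boosting rounds and tree depth for the ranking
#'   ensemble.
#' @param seed Integer seed.
#' @return Character vector of `k` feature names, most important first.
#' @export
rank_features <- function(x, y, k, rounds = 40, maxdepth = 3, seed = NULL) {
  x <- as.matrix(x)
  if (k > ncol(x)) stop("k = ", k, " exceeds the ", ncol(x), " features", call. = FALSE)
  if (nlevels(factor(y)) < 2) stop("need at least 2 classes", call. = FALSE)
  fit <- with_seed(seed, adaboost(x, y, rounds = rounds, maxdepth = maxdepth))
  imp <- numeric(ncol(x))
  names(imp) <- colnames(x)
  got <- fit$importance
  imp[names(got)] <- got
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}
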