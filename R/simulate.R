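# Synthetic ethogram/IMU generator. Emulates the per-behavior signal
# structure the downstream analysis assumes: strong periodicity for walking
# and running (running period about half of walking), quasi-periodic bite
# impulses for grazing, and near-static orientation offsets for standing and
# lying that differ only by posture. Channels are accelerometer (g, clipped
# to +/-2 g) and gyroscope (deg/s, clipped to +/-2000 dps) at 20 Hz.

#' Simulation parameters
#'
#' Defaults encode the observed movement structure of grazing sheep: a
#' typical walking movement period of 0.9 s (observed range 0.29--1.25 s), a
#' running period of about half that (0.45 s, range 0.21--0.45 s), and
#' grazing bite intervals jittered around 1.3 s and capped at the 2.15 s
#' maximum observed bite interval. Standing and lying produce low-variance
#' static signals that differ only by their orientation offsets, so the two
#' classes are deliberately confusable. White Gaussian noise plus an explicit
#' high-frequency buzz component is added to every channel so that denoising
#' is a meaningful step.
#'
#' @param sample_rate Sampling frequency in Hz.
#' @param walking_period,running_period Dominant movement period (s) on the
#'   fundamental axes for walking and running.
#' @param grazing_bite_mean,grazing_bite_sd,grazing_bite_min,grazing_bite_max
#'   Inter-bite interval distribution (s); intervals are Gaussian-jittered
#'   and clipped to `[min, max]`.
#' @param walking_acc_amp,running_acc_amp Oscillation amplitude (g).
#' @param walking_gyr_amp,running_gyr_amp Oscillation amplitude (deg/s).
#' @param bite_acc_amp,bite_gyr_amp Amplitude of one bite impulse.
#' @param bite_width Gaussian half-width of a bite impulse (s).
#' @param orient_standing,orient_lying,orient_grazing,orient_dynamic Static
#'   acceleration offset (g) per axis `c(x, y, z)` for the neck-mounted unit.
#' @param noise_sd_acc,noise_sd_gyr White-noise standard deviation per channel.
#' @param hf_amp_acc,hf_amp_gyr,hf_freq Amplitude and frequency of the added
#'   high-frequency buzz.
#' @param harmonic_weight Relative amplitude of the secondary component: on
#'   fundamental-dominant axes the harmonic at twice the fundamental
#'   frequency, on harmonic-dominant axes the fundamental itself. Axes split
#'   into two groups (`acc_x`, `acc_z`, `gyr_y` fundamental-dominant;
#'   `acc_y`, `gyr_x`, `gyr_z` harmonic-dominant) so that the six channels
#'   show two distinct dominant periods, as real gait signals do.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(sample_rate = 20,
                       walking_period = 0.9,
                       running_period = 0.45,
                       grazing_bite_mean = 1.3,
                       grazing_bite_sd = 0.35,
                       grazing_bite_min = 0.5,
                       grazing_bite_max = 2.15,
                       walking_acc_amp = 0.30,
                       running_acc_amp = 0.55,
                       walking_gyr_amp = 60,
                       running_gyr_amp = 150,
                       bite_acc_amp = 0.35,
                       bite_gyr_amp = 80,
                       bite_width = 0.06,
                       orient_standing = c(0.10, -0.05, 0.98),
                       orient_lying = c(0.45, 0.20, 0.85),
                       orient_grazing = c(0.80, 0.05, 0.55),
                       orient_dynamic = c(0.10, -0.05, 0.95),
                       noise_sd_acc = 0.03,
                       noise_sd_gyr = 3,
                       hf_amp_acc = 0.02,
                       hf_amp_gyr = 1.5,
                       hf_freq = 8.7,
                       harmonic_weight = 0.35) {
  stopifnot(sample_rate > 0,
            walking_period >= 0.29, walking_period <= 1.25,
            running_period >= 0.21, running_period <= 0.45,
            grazing_bite_max <= 2.15, grazing_bite_min > 0,
            noise_sd_acc >= 0, noise_sd_gyr >= 0)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
ACC_CHANNELS <- CHANNELS[1:3]
GYR_CHANNELS <- CHANNELS[4:6]
# axes whose dominant spectral peak sits at the fundamental frequency
FUNDAMENTAL_AXES <- c("acc_x", "acc_z", "gyr_y")

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

new_imu_stream <- function(data, sample_rate, start_time = as.POSIXct("2022-05-15 09:00:00", tz = "UTC")) {
  stopifnot(identical(names(data), CHANNELS))
  structure(list(data = data, sample_rate = sample_rate,
                 start_time = start_time, label = NULL,
                 second_labels = NULL),
            class = "imu_stream")
}

#' Number of samples in a stream
#' @param stream An `imu_stream`.
#' @return Integer sample count (per channel).
#' @export
n_samples <- function(stream) nrow(stream$data)

#' Duration of a stream in seconds
#' @param stream An `imu_stream`.
#' @return Numeric seconds.
#' @export
stream_duration <- function(stream) n_samples(stream) / stream$sample_rate

#' @export
print.imu_stream <- function(x, ...) {
  cat("IMU stream:", n_samples(x), "samples x 6 channels @",
      x$sample_rate, "Hz (", stream_duration(x), "s )\n")
  cat("start:", format(x$start_time, "%Y-%m-%d %H:%M:%OS2 %Z"), "\n")
  if (!is.null(x$second_labels)) {
    cat("labelled seconds:", length(x$second_labels), "\n")
    print(label_counts(x))
  }
  invisible(x)
}

# one dynamic (walking/running) segment: fundamental sinusoid + one harmonic,
# axis-specific phases; some axes carry the fundamental, some its double
dynamic_segment <- function(nsec, fs, period, acc_amp, gyr_amp, orient, hw) {
  t <- seq_len(nsec * fs) / fs
  f0 <- 1 / period
  out <- matrix(0, length(t), 6, dimnames = list(NULL, CHANNELS))
  phases <- stats::runif(6, 0, 2 * pi)
  for (j in seq_along(CHANNELS)) {
    ch <- CHANNELS[j]
    amp <- if (ch %in% ACC_CHANNELS) acc_amp else gyr_amp
    fund <- amp * sin(2 * pi * f0 * t + phases[j])
    harm <- amp * sin(2 * pi * 2 * f0 * t + phases[j] + pi / 3)
    out[, j] <- if (ch %in% FUNDAMENTAL_AXES) fund + hw * harm else hw * fund + harm
  }
  out[, ACC_CHANNELS] <- sweep(out[, ACC_CHANNELS], 2, orient, "+")
  out
}

# grazing: head-down orientation offset plus irregular bite impulses with
# jittered inter-bite intervals (no strong periodicity)
grazing_segment <- function(nsec, fs, p) {
  n <- nsec * fs
  t <- seq_len(n) / fs
  out <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
  bite_t <- numeric(0)
  tt <- 0
  repeat {
    gap <- stats::rnorm(1, p$grazing_bite_mean, p$grazing_bite_sd)
    gap <- min(max(gap, p$grazing_bite_min), p$grazing_bite_max)
    tt <- tt + gap
    if (tt > nsec) break
    bite_t <- c(bite_t, tt)
  }
  pulse <- numeric(n)
  reach <- 5 * p$bite_width  # beyond this the Gaussian pulse is negligible
  for (tb in bite_t) {
    i <- max(1L, ceiling((tb - reach) * fs)):min(n, floor((tb + reach) * fs))
    pulse[i] <- pulse[i] + exp(-((t[i] - tb)^2) / (2 * p$bite_width^2))
  }
  out[, "acc_x"] <- p$bite_acc_amp * pulse
  out[, "acc_z"] <- -0.7 * p$bite_acc_amp * pulse
  out[, "gyr_y"] <- p$bite_gyr_amp * pulse
  out[, "gyr_x"] <- 0.4 * p$bite_gyr_amp * pulse
  out[, ACC_CHANNELS] <- sweep(out[, ACC_CHANNELS], 2, p$orient_grazing, "+")
  out
}

static_segment <- function(nsec, fs, orient) {
  n <- nsec * fs
  out <- matrix(0, n, 6, dimnames = list(NULL, CHANNELS))
  out[, ACC_CHANNELS] <- matrix(orient, n, 3, byrow = TRUE)
  out
}

behavior_segment <- function(behavior, nsec, p) {
  fs <- p$sample_rate
  switch(behavior,
    walking = dynamic_segment(nsec, fs, p$walking_period, p$walking_acc_amp,
                              p$walking_gyr_amp, p$orient_dynamic, p$harmonic_weight),
    running = dynamic_segment(nsec, fs, p$running_period, p$running_acc_amp,
                              p$running_gyr_amp, p$orient_dynamic, p$harmonic_weight),
    grazing = grazing_segment(nsec, fs, p),
    standing = static_segment(nsec, fs, p$orient_standing),
    lying = static_segment(nsec, fs, p$orient_lying),
    unknown = static_segment(nsec, fs, c(0, 0, 1)),
    stop("unhandled behavior: ", behavior))
}

#' Synthesize a labelled IMU stream from a behavior schedule
#'
#' Generates one six-channel stream whose per-second truth follows
#' `schedule`. Dynamic behaviors carry a fundamental sinusoid at the
#' configured movement period plus one harmonic with axis-specific phases;
#' grazing carries a head-down offset plus jittered bite impulses; standing
#' and lying are constant orientation offsets. White noise and a
#' high-frequency buzz are added to every channel, and channels are clipped
#' to the sensor ranges (+/-2 g, +/-2000 dps).
#'
#' @param schedule A [make_schedule()] object.
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed and parameters give a
#'   bit-identical stream. `NULL` uses the current RNG state.
#' @return A list with components `stream` (an `imu_stream`) and `labels`
#'   (the per-second truth track, character).
#' @examples
#' sim <- synthesize_imu(make_schedule("walking", 10), seed = 1)
#' n_samples(sim$stream)  # 200
#' @export
synthesize_imu <- function(schedule, params = sim_params(), seed = NULL) {
  stopifnot(inherits(schedule, "behavior_schedule"), inherits(params, "sim_params"))
  fs <- params$sample_rate
  with_seed(seed, {
    segs <- lapply(seq_len(nrow(schedule)), function(i) {
      behavior_segment(schedule$behavior[i], schedule$seconds[i], params)
    })
    sig <- do.call(rbind, segs)
    n <- nrow(sig)
    t <- seq_len(n) / fs
    hf <- sin(2 * pi * params$hf_freq * t)
    for (ch in ACC_CHANNELS) {
      sig[, ch] <- sig[, ch] + stats::rnorm(n, 0, params$noise_sd_acc) +
        params$hf_amp_acc * hf
    }
    for (ch in GYR_CHANNELS) {
      sig[, ch] <- sig[, ch] + stats::rnorm(n, 0, params$noise_sd_gyr) +
        params$hf_amp_gyr * hf
    }
    sig[, ACC_CHANNELS] <- pmin(pmax(sig[, ACC_CHANNELS], -2), 2)
    sig[, GYR_CHANNELS] <- pmin(pmax(sig[, GYR_CHANNELS], -2000), 2000)
    stream <- new_imu_stream(as.data.frame(sig), fs)
    list(stream = stream, labels = expand_schedule(schedule))
  })
}

#' Link a per-second label track to an IMU stream
#'
#' Each sample inherits the label of the second it falls in, mirroring the
#' timestamp linkage between video labelling and sensor records. Samples
#' labelled `"unknown"` remain in the stream but are excluded from training
#' sets downstream. The per-behavior bookkeeping (labelled seconds and data
#' rows, rows = seconds x sample rate) is attached and available through
#' [label_counts()].
#'
#' @param stream An `imu_stream`.
#' @param labels Character per-second track whose length must equal the
#'   stream duration in whole seconds.
#' @return The stream with `label` (per sample) and `second_labels` fields.
#' @export
link_labels <- function(stream, labels) {
  stopifnot(inherits(stream, "imu_stream"))
  assert_behavior(labels)
  fs <- stream$sample_rate
  if (length(labels) * fs != n_samples(stream)) {
    stop("label track (", length(labels), " s) does not cover the stream (",
         stream_duration(stream), " s): timestamp mismatch", call. = FALSE)
  }
  stream$label <- rep(labels, each = fs)
  stream$second_labels <- labels
  stream
}

#' Per-behavior seconds and data rows of a labelled stream
#'
#' @param stream A labelled `imu_stream` (see [link_labels()]).
#' @param drop_unknown Drop the `"unknown"` row (those samples never enter
#'   training).
#' @return Data frame with columns `behavior`, `seconds`, `rows`.
#' @export
label_counts <- function(stream, drop_unknown = FALSE) {
  stopifnot(inherits(stream, "imu_stream"), !is.null(stream$second_labels))
  labs <- stream$second_labels
  keep <- intersect(LABELS, unique(labs))
  if (drop_unknown) keep <- setdiff(keep, "unknown")
  secs <- vapply(keep, function(b) sum(labs == b), integer(1))
  data.frame(behavior = keep, seconds = secs,
             rows = secs * stream$sample_rate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read and write IMU streams as delimited text
#'
#' One row per sample: ISO timestamp, six channel columns, and a label
#' column when the stream is labelled.
#'
#' @param stream An `imu_stream`.
#' @param path File path.
#' @param sample_rate Sampling frequency to assume when reading.
#' @return `write_imu_csv()` returns `path` invisibly; `read_imu_csv()`
#'   returns an `imu_stream`.
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(inherits(stream, "imu_stream"))
  t <- stream$start_time + (seq_len(n_samples(stream)) - 1) / stream$sample_rate
  df <- cbind(data.frame(timestamp = format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")),
              stream$data)
  if (!is.null(stream$label)) df$label <- stream$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, sample_rate = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(CHANNELS %in% names(df)))
  start <- as.POSIXct(df$timestamp[1], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  stream <- new_imu_stream(df[, CHANNELS], sample_rate, start)
  if ("label" %in% names(df)) {
    fs <- sample_rate
    stream$label <- df$label
    stream$second_labels <- df$label[seq(1, nrow(df), by = fs)]
  }
  stream
}
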