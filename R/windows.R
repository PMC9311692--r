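# Fixed-length time windows over a labelled stream. Jump mode tiles the
# stream with consecutive non-overlapping windows from t = 0 (the trailing
# partial window is kept for decoding but never enters training); slide mode
# places one window at every whole-second offset that fits fully inside the
# stream. Training keeps only pure windows (every second sharing the
# majority label) and drops windows labelled unknown.

majority_label <- function(labels) {
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # tie rule: the tied behavior whose seconds start earliest in the window
  top[which.min(vapply(top, function(b) match(b, labels), integer(1)))]
}

new_window_view <- function(data, start, seconds) {
  maj <- if (is.null(seconds)) NA_character_ else majority_label(seconds)
  purity <- if (is.null(seconds)) NA_real_ else mean(seconds == maj)
  structure(list(data = data, start = start, seconds = seconds,
                 majority = maj, purity = purity),
            class = "window_view")
}

#' Partition a stream into fixed-length windows
#'
#' @param stream An `imu_stream`, labelled via [link_labels()] (unlabelled
#'   streams are allowed when `training = FALSE`; windows then carry no
#'   majority label).
#' @param size Window length in whole seconds (any positive integer; 3, 5
#'   and 11 s are the usual choices).
#' @param mode `"jump"` (non-overlapping tiling from t = 0, trailing partial
#'   window retained) or `"slide"` (one window per whole-second offset,
#'   fully inside the stream).
#' @param training If `TRUE`, keep only complete windows of purity 1 whose
#'   label is a real behavior (not `"unknown"`): one behavior per training
#'   window.
#' @return List of `window_view` objects; each has fields `data` (samples x
#'   6 channels), `start` (offset in seconds, 0-based), `seconds`
#'   (per-second labels), `majority`, `purity`, and attribute `partial` on a
#'   trailing jump window.
#' @examples
#' sim <- synthesize_imu(cbs_demo_schedule(), seed = 1)
#' st <- link_labels(sim$stream, sim$labels)
#' length(window_partition(st, 3, "jump"))    # 11
#' length(window_partition(st, 11, "slide"))  # 23
#' @export
window_partition <- function(stream, size, mode = c("jump", "slide"),
                             training = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(stream, "imu_stream"), size >= 1, size == round(size))
  fs <- stream$sample_rate
  total <- floor(stream_duration(stream))
  if (total < size) stop("stream (", total, " s) shorter than one ", size,
                         " s window", call. = FALSE)
  labs <- stream$second_labels
  dat <- as.matrix(stream$data)
  starts <- if (mode == "jump") seq(0L, total - size, by = size)
            else seq(0L, total - size, by = 1L)
  take <- function(start, len) {
    rows <- (start * fs + 1):((start + len) * fs)
    secs <- if (is.null(labs)) NULL else labs[(start + 1):(start + len)]
    new_window_view(dat[rows, , drop = FALSE], start, secs)
  }
  windows <- lapply(starts, take, len = size)
  if (mode == "jump" && total %% size != 0L) {
    tail_start <- (total %/% size) * size
    w <- take(tail_start, total - tail_start)
    attr(w, "partial") <- TRUE
    windows <- c(windows, list(w))
  }
  if (training) {
    keep <- vapply(windows, function(w) {
      isTRUE(w$purity == 1) && w$majority %in% BEHAVIORS &&
        !isTRUE(attr(w, "partial"))
    }, logical(1))
    windows <- windows[keep]
  }
  windows
}

#' @export
print.window_view <- function(x, ...) {
  cat(sprintf("Window [%d, %d) s: %d samples, majority %s (purity %.2f)\n",
              x$start, x$start + length(x$seconds), nrow(x$data),
              x$majority, x$purity))
  invisible(x)
}
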