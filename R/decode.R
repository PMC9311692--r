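# Continuous-segment decoding. A trained model scores fixed-length windows;
# the decoder turns window scores into one label per second. Jump mode
# broadcasts each non-overlapping window's label to its seconds (the
# trailing partial window is scored from its available samples). Slide mode
# places windows at every whole-second offset and labels each second with
# the behavior of highest accumulated score over all windows covering it.

labels_to_scores <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

new_secondwise_decoding <- function(labels, scores, mode, size) {
  structure(list(labels = labels, scores = scores, mode = mode, size = size),
            class = "secondwise_decoding")
}

#' @export
print.secondwise_decoding <- function(x, ...) {
  cat("Second-wise decoding (", x$mode, "-moving ", x$size, " s windows): ",
      length(x$labels), " s\n", sep = "")
  r <- rle(x$labels)
  cat(paste0(r$values, " x", r$lengths, "s", collapse = ", "), "\n")
  invisible(x)
}

# shared engine: scores is windows x classes, starts are 0-based window
# offsets, sizes the per-window length in seconds
decode_engine <- function(scores, starts, sizes, total_seconds, mode) {
  classes <- colnames(scores)
  stopifnot(!is.null(classes), length(starts) == nrow(scores),
            length(sizes) == nrow(scores), total_seconds >= 1)
  acc <- matrix(0, total_seconds, length(classes),
                dimnames = list(NULL, classes))
  win_label <- classes[max.col(scores, ties.method = "first")]
  for (w in seq_along(starts)) {
    secs <- (starts[w] + 1):(starts[w] + sizes[w])
    acc[secs, ] <- acc[secs, , drop = FALSE] +
      matrix(scores[w, ], length(secs), length(classes), byrow = TRUE)
  }
  labels <- character(total_seconds)
  for (s in seq_len(total_seconds)) {
    top <- which(acc[s, ] == max(acc[s, ]))
    if (length(top) > 1L) {
      # tie: dynamic behaviors beat static ones ...
      dyn <- top[classes[top] %in% DYNAMIC_BEHAVIORS]
      if (length(dyn)) top <- dyn
      if (length(top) > 1L) {
        # ... then the earliest covering window whose own label is tied decides
        covering <- which(starts < s & starts + sizes >= s)
        covering <- covering[order(starts[covering])]
        pick <- NA_integer_
        for (w in covering) {
          hit <- top[classes[top] == win_label[w]]
          if (length(hit)) { pick <- hit[1]; break }
        }
        top <- if (is.na(pick)) top[1] else pick
      }
    }
    labels[s] <- classes[top[1]]
  }
  list(labels = labels, scores = acc)
}

#' Decode continuous behavior with jump-moving windows
#'
#' @param scores Window score matrix (windows x classes, named columns), or
#'   a character vector of window labels (converted to unit scores).
#' @param size Window length in seconds.
#' @param total_seconds Length of the decoded span; defaults to the span the
#'   windows cover.
#' @param starts 0-based window offsets in seconds; defaults to the jump
#'   tiling `0, size, 2*size, ...` with a trailing partial window when
#'   `total_seconds` is not a multiple of `size`.
#' @param classes Class set when `scores` is a label vector.
#' @return A `"secondwise_decoding"`: per-second `labels` plus the
#'   per-second accumulated `scores`.
#' @examples
#' decode_jump(rep("grazing", 3), size = 3)$labels  # 9 s of grazing
#' @export
decode_jump <- function(scores, size, total_seconds = NULL, starts = NULL,
                        classes = BEHAVIORS) {
  if (is.character(scores)) scores <- labels_to_scores(scores, classes)
  nw <- nrow(scores)
  if (nw == 0) stop("empty decoding span", call. = FALSE)
  if (is.null(starts)) starts <- (seq_len(nw) - 1L) * size
  if (is.null(total_seconds)) total_seconds <- max(starts) + size
  sizes <- pmin(size, total_seconds - starts)
  out <- decode_engine(scores, starts, sizes, total_seconds, "jump")
  new_secondwise_decoding(out$labels, out$scores, "jump", size)
}

#' Decode continuous behavior with slide-moving windows
#'
#' Windows sit at every whole-second offset; each second's final label is
#' the behavior with the highest prediction score accumulated over all
#' windows containing that second. Score ties prefer dynamic behaviors over
#' static ones, then follow window order.
#'
#' @inheritParams decode_jump
#' @return A `"secondwise_decoding"`.
#' @export
decode_slide <- function(scores, size, total_seconds = NULL, starts = NULL,
                         classes = BEHAVIORS) {
  if (is.character(scores)) scores <- labels_to_scores(scores, classes)
  nw <- nrow(scores)
  if (nw == 0) stop("empty decoding span", call. = FALSE)
  if (is.null(starts)) starts <- seq_len(nw) - 1L
  if (is.null(total_seconds)) total_seconds <- max(starts) + size
  sizes <- rep(size, nw)
  out <- decode_engine(scores, starts, sizes, total_seconds, "slide")
  new_secondwise_decoding(out$labels, out$scores, "slide", size)
}

#' Perfect-classifier decoding of a behavior schedule
#'
#' Replaces the trained classifier with a truth-majority labeller: every
#' window is labelled with the majority behavior of its seconds (score 1)
#' and decoded as usual. This is the executable form of the worked
#' continuous-segment example, and an upper bound for what window/consensus
#' decoding can achieve at a given window size.
#'
#' @param schedule A [make_schedule()] object.
#' @param size Window length in seconds.
#' @param mode `"jump"` or `"slide"`.
#' @return List with `accuracy` (fraction of seconds correct), `decoding`
#'   (the `"secondwise_decoding"`) and `truth` (per-second track).
#' @examples
#' oracle_decode(cbs_demo_schedule(), 3, "jump")$accuracy   # 32/33
#' oracle_decode(cbs_demo_schedule(), 11, "slide")$accuracy # 29/33
#' @export
oracle_decode <- function(schedule, size, mode = c("jump", "slide")) {
  mode <- match.arg(mode)
  truth <- expand_schedule(schedule)
  total <- length(truth)
  if (total < size) stop("schedule shorter than one window", call. = FALSE)
  classes <- intersect(LABELS, unique(truth))
  if (mode == "jump") {
    starts <- seq(0L, total - size, by = size)
    sizes <- rep(size, length(starts))
    if (total %% size != 0L) {
      starts <- c(starts, (total %/% size) * size)
      sizes <- c(sizes, total %% size)
    }
  } else {
    starts <- seq(0L, total - size, by = 1L)
    sizes <- rep(size, length(starts))
  }
  maj <- vapply(seq_along(starts), function(w) {
    majority_label(truth[(starts[w] + 1):(starts[w] + sizes[w])])
  }, character(1))
  scores <- labels_to_scores(maj, classes)
  out <- decode_engine(scores, starts, sizes, total, mode)
  dec <- new_secondwise_decoding(out$labels, out$scores, mode, size)
  list(accuracy = mean(out$labels == truth), decoding = dec, truth = truth)
}

#' Decode a stream with a trained model
#'
#' Windows the stream, computes features, applies the training
#' standardization, scores each window with the model and decodes
#' per-second labels. Models trained without some behavior (e.g. running at
#' large window sizes) simply emit no score for it.
#'
#' @param model A fitted classifier accepted by [predict_scores()].
#' @param stream An `imu_stream`.
#' @param size Window length (s).
#' @param mode `"jump"` or `"slide"`.
#' @param sensors Sensor group used at training time.
#' @param center,scale Standardization statistics from the training split.
#' @param features Optional selected feature names (in training order).
#' @return A `"secondwise_decoding"`.
#' @export
decode_stream <- function(model, stream, size, mode = c("jump", "slide"),
                          sensors = "both", center = NULL, scale = NULL,
                          features = NULL) {
  mode <- match.arg(mode)
  windows <- window_partition(stream, size, mode, training = FALSE)
  fs <- stream$sample_rate
  fmat <- t(vapply(windows, compute_features, sensors = sensors, fs = fs,
                   FUN.VALUE = compute_features(windows[[1]], sensors, fs)))
  if (!is.null(center)) fmat <- standardize_features(fmat, center, scale)
  if (!is.null(features)) fmat <- fmat[, features, drop = FALSE]
  scores <- predict_scores(model, fmat)
  starts <- vapply(windows, `[[`, 0, "start")
  total <- floor(stream_duration(stream))
  if (mode == "jump") {
    decode_jump(scores, size, total_seconds = total, starts = starts)
  } else {
    decode_slide(scores, size, total_seconds = total, starts = starts)
  }
}

#' Write a decoded track as delimited text
#'
#' One row per second: second index, label, per-class accumulated scores.
#'
#' @param decoding A `"secondwise_decoding"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_decoding <- function(decoding, path) {
  df <- data.frame(second = seq_along(decoding$labels),
                   label = decoding$labels)
  df <- cbind(df, as.data.frame(decoding$scores))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
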