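# Shared fixtures, generated in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# balanced 5-behavior labelled stream with well-separated signatures
fixture_stream <- function() {
  cached("stream", {
    sched <- make_schedule(rep(c("walking", "standing", "grazing", "lying", "running"), 8),
                           rep(12, 40))
    sim <- synthesize_imu(sched, seed = 2024)
    link_labels(sim$stream, sim$labels)
  })
}

# standardized 3 s / both-sensor feature dataset from fixture_stream()
fixture_dataset <- function() {
  cached("dataset", {
    tab <- build_feature_table(fixture_stream(), 3, "both")
    split_standardize(tab[, feature_columns(tab)], tab$label, seed = 99)
  })
}

random_schedule <- function(n_segments, min_dur = 1, max_dur = 15,
                            behaviors = BEHAVIORS) {
  make_schedule(sample(behaviors, n_segments, replace = TRUE),
                sample(min_dur:max_dur, n_segments, replace = TRUE))
}

# Independent per-second majority-consensus decoder used as the oracle for
# the continuous-segment worked example: naive loops straight from the
# definitions, no shared code with the package's decoder.
naive_consensus_accuracy <- function(truth, size, mode) {
  total <- length(truth)
  starts <- if (mode == "jump") seq(0, total - size, by = size) else 0:(total - size)
  ends <- pmin(starts + size, total)
  if (mode == "jump" && max(ends) < total) {
    starts <- c(starts, max(ends))
    ends <- c(ends, total)
  }
  maj <- character(length(starts))
  for (w in seq_along(starts)) {
    secs <- truth[(starts[w] + 1):ends[w]]
    tab <- table(secs)
    top <- names(tab)[tab == max(tab)]
    first_pos <- vapply(top, function(b) match(b, secs), integer(1))
    maj[w] <- top[which.min(first_pos)]
  }
  pred <- character(total)
  for (s in seq_len(total)) {
    cover <- which(starts < s & ends >= s)
    votes <- table(maj[cover])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      dyn <- intersect(top, c("walking", "grazing", "running"))
      if (length(dyn)) top <- dyn
      if (length(top) > 1) {
        for (w in cover) if (maj[w] %in% top) { top <- maj[w]; break }
      }
    }
    pred[s] <- top[1]
  }
  mean(pred == truth)
}
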