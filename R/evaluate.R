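# Evaluation: per-second accuracy, Cohen's kappa from the confusion matrix,
# per-class precision / recall / F-score, and behavior time budgets.

#' Evaluate predictions against truth
#'
#' @param pred Predicted labels (character/factor) or a
#'   `"secondwise_decoding"`.
#' @param truth True labels, same length.
#' @return An object of class `"eval_report"`: `confusion` (truth rows x
#'   prediction columns), `accuracy`, `kappa`, and `per_class` (precision,
#'   recall, F-score per behavior; `NaN` where a class was never predicted
#'   or never occurred).
#' @examples
#' r <- evaluate(c("a", "a", "b"), c("a", "b", "b"))
#' r$accuracy
#' @export
evaluate <- function(pred, truth) {
  if (inherits(pred, "secondwise_decoding")) pred <- pred$labels
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("prediction and truth tracks differ in length", call. = FALSE)
  if (length(pred) == 0) stop("empty tracks", call. = FALSE)
  classes <- unique(c(intersect(LABELS, c(truth, pred)),
                      setdiff(unique(c(truth, pred)), LABELS)))
  conf <- table(factor(truth, classes), factor(pred, classes))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  tp <- diag(conf)
  precision <- tp / colSums(conf)
  recall <- tp / rowSums(conf)
  fscore <- 2 * precision * recall / (precision + recall)
  structure(list(confusion = conf,
                 accuracy = po,
                 kappa = kappa,
                 per_class = data.frame(behavior = classes,
                                        precision = as.numeric(precision),
                                        recall = as.numeric(recall),
                                        fscore = as.numeric(fscore),
                                        row.names = NULL)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Accuracy: %.1f%%   Kappa: %.3f\n", 100 * x$accuracy, x$kappa))
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("Per-class performance:\n")
  pc <- x$per_class
  pc[, -1] <- round(pc[, -1], digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as a machine-readable key-value file
#'
#' @param report An `"eval_report"`.
#' @param path File path (JSON).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(accuracy = report$accuracy,
                            kappa = report$kappa,
                            per_class = report$per_class,
                            confusion = as.data.frame(report$confusion)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Behavior time budget
#'
#' Proportion of decoded (or true) time spent in each behavior. Standing and
#' lying are merged into `resting` by default, the convention for grazing
#' time-budget summaries.
#'
#' @param x A `"secondwise_decoding"` or a label vector.
#' @param merge_resting Merge standing + lying into `resting`.
#' @return Named numeric proportions (sum to 1) of class `"time_budget"`.
#' @examples
#' time_budget(expand_schedule(cbs_demo_schedule()))
#' @export
time_budget <- function(x, merge_resting = TRUE) {
  labels <- if (inherits(x, "secondwise_decoding")) x$labels else as.character(x)
  if (!length(labels)) stop("empty decoding", call. = FALSE)
  if (merge_resting) {
    labels[labels %in% c("standing", "lying")] <- "resting"
  }
  order_ref <- c("walking", "grazing", "resting", "standing", "lying",
                 "running", "unknown")
  tab <- table(labels) / length(labels)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out <- out[order(match(names(out), order_ref))]
  class(out) <- "time_budget"
  out
}

#' @export
print.time_budget <- function(x, ...) {
  cat("Behavior time budget:\n")
  for (b in names(x)) cat(sprintf("  %-9s %5.1f%%\n", b, 100 * unclass(x)[b]))
  invisible(x)
}
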