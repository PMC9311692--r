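#' Multiclass AdaBoost (SAMME) over classification trees
#'
#' Stagewise additive boosting with the multiclass exponential loss: each
#' round fits a weighted shallow `rpart` tree, upweights the rows it
#' misclassifies, and contributes votes scaled by
#' `log((1 - err) / err) + log(K - 1)`. Also the importance ranker for
#' feature selection: variable importances of the round trees accumulate
#' with the round weights.
#'
#' @param x Feature matrix or data frame.
#' @param y Class labels (>= 2 classes).
#' @param rounds Number of boosting rounds.
#' @param maxdepth Depth of each tree (stumps with `maxdepth = 1`).
#' @param ... Passed between methods.
#' @return An object of class `"adaboost"` with the round trees, their vote
#'   weights `alpha`, `classes`, and the accumulated `importance` (named,
#'   normalized to sum to 1).
#' @examples
#' x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
#' y <- ifelse(x[, 1] > 0, "pos", "neg")
#' fit <- adaboost(x, y, rounds = 10)
#' mean(predict(fit, x) == y)
#' @export
adaboost <- function(x, y, rounds = 100, maxdepth = 3, ...) {
  x <- as.data.frame(x)
  y <- factor(y)
  n <- nrow(x)
  K <- nlevels(y)
  stopifnot(n == length(y), rounds >= 1)
  if (K < 2) stop("need at least 2 classes", call. = FALSE)
  w <- rep(1 / n, n)
  trees <- list()
  alpha <- numeric(0)
  imp <- numeric(0)
  df <- cbind(x, .y = y)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2,
                               xval = 0, maxsurrogate = 0, maxcompete = 0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 1 - 1 / K) break       # weak learner no better than chance
    err <- max(err, 1e-10)            # perfect fit: cap the vote weight
    a <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(a * miss)
    w <- w / sum(w)
    trees[[length(trees) + 1L]] <- fit
    alpha <- c(alpha, a)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      for (v in names(vi)) imp[v] <- (if (v %in% names(imp)) imp[v] else 0) + a * vi[v]
    }
  }
  if (!length(trees)) stop("boosting found no useful weak learner", call. = FALSE)
  if (length(imp)) imp <- sort(imp / sum(imp), decreasing = TRUE)
  structure(list(trees = trees, alpha = alpha, classes = levels(y),
                 importance = imp, rounds = length(trees),
                 maxdepth = maxdepth, call = match.call()),
            class = "adaboost")
}

#' @rdname adaboost
#' @param object A fitted `"adaboost"`.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param type `"class"` or `"prob"` (normalized vote shares).
#' @export
predict.adaboost <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  K <- length(object$classes)
  votes <- matrix(0, nrow(newdata), K, dimnames = list(NULL, object$classes))
  for (m in seq_along(object$trees)) {
    pred <- predict(object$trees[[m]], newdata, type = "class")
    votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(newdata)), as.integer(pred))] + object$alpha[m]
  }
  if (type == "prob") return(votes / rowSums(votes))
  object$classes[max.col(votes, ties.method = "first")]
}

#' @export
print.adaboost <- function(x, ...) {
  cat("AdaBoost (SAMME):", x$rounds, "trees of depth", x$maxdepth, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}
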