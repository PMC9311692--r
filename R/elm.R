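#' Extreme learning machine classifier
#'
#' A single-hidden-layer feedforward network whose input weights and biases
#' are random and fixed; only the output weights are learned, in closed form,
#' as the minimum-norm least-squares solution of `H B = Y` where `H` is the
#' hidden-layer activation matrix and `Y` the one-hot class targets. No
#' iterative training takes place, which is what makes the method fast, and
#' the solve is exact interpolation whenever the hidden width reaches the row
#' count on noiseless data.
#'
#' @param x Numeric feature matrix (rows = observations), or a formula.
#' @param y Class labels (factor or character), >= 2 classes.
#' @param hidden Hidden-layer width (>= 1).
#' @param seed Integer seed for the random input weights; the same seed
#'   reproduces the model exactly.
#' @param data,formula Standard modelling-interface arguments.
#' @param ... Passed between methods.
#' @return An object of class `"elm"` with components `w` (input weights),
#'   `b` (biases), `beta` (output weights), `classes`, `hidden`, `seed` and
#'   `feature_names`.
#' @examples
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
#' colnames(x) <- c("f1", "f2")
#' y <- rep(c("a", "b"), each = 50)
#' fit <- elm(x, y, hidden = 30, seed = 1)
#' mean(predict(fit, x) == y)
#' @export
elm <- function(x, ...) UseMethod("elm")

#' @rdname elm
#' @export
elm.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- elm.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname elm
#' @export
elm.default <- function(x, y, hidden = 100, seed = NULL, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y), hidden >= 1)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  p <- ncol(x)
  wb <- with_seed(seed, {
    list(w = matrix(stats::runif(p * hidden, -1, 1), p, hidden),
         b = stats::runif(hidden, -1, 1))
  })
  H <- elm_hidden(x, wb$w, wb$b)
  targets <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  beta <- MASS::ginv(H) %*% targets  # minimum-norm least squares
  structure(list(w = wb$w, b = wb$b, beta = beta, classes = levels(y),
                 hidden = hidden, seed = seed, feature_names = colnames(x),
                 call = match.call()),
            class = "elm")
}

elm_hidden <- function(x, w, b) {
  a <- x %*% w
  a <- sweep(a, 2, b, "+")
  1 / (1 + exp(-a))  # logistic sigmoid activation
}

#' @rdname elm
#' @param object A fitted `"elm"`.
#' @param newdata Feature matrix with the training feature columns.
#' @param type `"class"` for labels, `"prob"` for softmax-normalized scores,
#'   `"raw"` for the linear output scores.
#' @export
predict.elm <- function(object, newdata, type = c("class", "prob", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata))) {
      stop("newdata lacks training features", call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  raw <- elm_hidden(newdata, object$w, object$b) %*% object$beta
  colnames(raw) <- object$classes
  switch(type,
         raw = raw,
         prob = softmax_rows(raw),
         class = object$classes[max.col(raw, ties.method = "first")])
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' @export
print.elm <- function(x, ...) {
  cat("Extreme learning machine\n")
  cat("  features:", length(x$feature_names), " hidden units:", x$hidden, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.elm <- function(object, ...) {
  print(object)
  cat("  output-weight norm:", format(sqrt(sum(object$beta^2)), digits = 4), "\n")
  invisible(object)
}
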