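# Stacking ensemble: heterogeneous first-layer learners (AdaBoost, random
# forest, SVM) whose out-of-fold class-probability outputs train a
# second-layer ELM meta-learner. Meta-features are strictly out-of-fold so
# no base learner ever scores a row it was trained on; the base learners are
# refit on all rows for prediction time.

BASE_LEARNERS <- c("adaboost", "rf", "svm")

#' Stacking ensemble controls
#'
#' @param folds Internal stratified folds used to build the out-of-fold
#'   meta-features.
#' @param adaboost_rounds,adaboost_maxdepth AdaBoost base-learner settings.
#' @param rf_trees Random-forest tree count.
#' @param svm_cost,svm_gamma RBF-kernel SVM settings (`svm_gamma = NULL`
#'   uses the kernel default 1/p).
#' @param meta_hidden Hidden width of the ELM meta-learner.
#' @return List of class `"stacking_control"`.
#' @export
stacking_control <- function(folds = 5, adaboost_rounds = 100,
                             adaboost_maxdepth = 3, rf_trees = 200,
                             svm_cost = 1, svm_gamma = NULL,
                             meta_hidden = 120) {
  structure(as.list(environment()), class = "stacking_control")
}

fit_base <- function(name, x, y, ctrl) {
  switch(name,
    adaboost = adaboost(x, y, rounds = ctrl$adaboost_rounds,
                        maxdepth = ctrl$adaboost_maxdepth),
    rf = randomForest::randomForest(x = x, y = factor(y), ntree = ctrl$rf_trees),
    svm = {
      args <- list(x = x, y = factor(y), kernel = "radial", cost = ctrl$svm_cost,
                   probability = TRUE)
      if (!is.null(ctrl$svm_gamma)) args$gamma <- ctrl$svm_gamma
      do.call(e1071::svm, args)
    },
    stop("unknown base learner: ", name))
}

base_probs <- function(name, fit, x, classes) {
  p <- switch(name,
    adaboost = predict(fit, x, type = "prob"),
    rf = predict(fit, x, type = "prob"),
    svm = attr(predict(fit, x, probability = TRUE), "probabilities"))
  out <- matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

#' Stratified fold assignment
#'
#' Assigns each row a fold id such that every class is spread across folds
#' as evenly as possible (per-class counts differ by at most one row).
#'
#' @param y Labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(y, k, seed = NULL) {
  y <- factor(y)
  if (any(table(y) < k)) {
    stop("every class needs at least ", k, " rows for ", k, "-fold stratification",
         call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

#' Stacking ensemble with an ELM meta-learner
#'
#' @param x Feature matrix (rows = observations), or a formula.
#' @param y Class labels (>= 2 classes).
#' @param control A [stacking_control()].
#' @param seed Integer seed covering fold assignment, the base learners and
#'   the meta-ELM; the same seed reproduces the fit.
#' @param data,formula Standard modelling-interface arguments.
#' @param ... Passed between methods.
#' @return An object of class `"stacking"` holding the refit base learners,
#'   the meta-ELM, `classes` and the fold scheme.
#' @examples
#' \donttest{
#' x <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 3), 100))
#' colnames(x) <- c("f1", "f2")
#' y <- rep(c("a", "b"), each = 100)
#' fit <- stacking(x, y, seed = 1)
#' mean(predict(fit, x) == y)
#' }
#' @export
stacking <- function(x, ...) UseMethod("stacking")

#' @rdname stacking
#' @export
stacking.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- stacking.default(x, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname stacking
#' @export
stacking.default <- function(x, y, control = stacking_control(), seed = NULL, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  classes <- levels(y)
  with_seed(seed, {
    fold <- stratified_folds(y, control$folds)
    meta <- matrix(NA_real_, nrow(x), length(BASE_LEARNERS) * length(classes))
    colnames(meta) <- as.vector(outer(classes, BASE_LEARNERS,
                                      function(cl, b) paste(b, cl, sep = ".")))
    for (f in seq_len(control$folds)) {
      in_rows <- fold != f
      for (b in BASE_LEARNERS) {
        fit <- fit_base(b, x[in_rows, , drop = FALSE], y[in_rows], control)
        p <- base_probs(b, fit, x[!in_rows, , drop = FALSE], classes)
        meta[!in_rows, paste(b, classes, sep = ".")] <- p
      }
    }
    meta_fit <- elm(meta, y, hidden = control$meta_hidden,
                    seed = sample.int(.Machine$integer.max, 1))
    base_fits <- lapply(stats::setNames(BASE_LEARNERS, BASE_LEARNERS),
                        function(b) fit_base(b, x, y, control))
    structure(list(base = base_fits, meta = meta_fit, classes = classes,
                   control = control, fold = fold, seed = seed,
                   feature_names = colnames(x), call = match.call()),
              class = "stacking")
  })
}

stack_meta_features <- function(object, newdata) {
  classes <- object$classes
  cols <- lapply(BASE_LEARNERS, function(b) {
    p <- base_probs(b, object$base[[b]], newdata, classes)
    colnames(p) <- paste(b, classes, sep = ".")
    p
  })
  do.call(cbind, cols)
}

#' @rdname stacking
#' @param object A fitted `"stacking"`.
#' @param newdata Feature matrix with the training feature columns.
#' @param type `"class"` or `"prob"`.
#' @export
predict.stacking <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(newdata))) {
      stop("newdata lacks training features", call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  meta <- stack_meta_features(object, newdata)
  predict(object$meta, meta, type = if (type == "class") "class" else "prob")
}

#' @export
print.stacking <- function(x, ...) {
  cat("Stacking ensemble: base learners", paste(BASE_LEARNERS, collapse = ", "),
      "-> ELM meta-learner\n")
  cat("  classes:", paste(x$classes, collapse = ", "),
      " folds:", x$control$folds, "\n")
  invisible(x)
}

#' Per-class prediction scores
#'
#' Uniform accessor used by the consensus decoder: one non-negative score
#' per trained class per row (probabilities for all bundled model types).
#'
#' @param model A fitted `elm`, `adaboost`, `stacking`, `randomForest` or
#'   `svm` model.
#' @param features Feature matrix with the model's training columns.
#' @return Matrix rows x classes of non-negative scores.
#' @export
predict_scores <- function(model, features) UseMethod("predict_scores")

#' @export
predict_scores.elm <- function(model, features) predict(model, features, type = "prob")

#' @export
predict_scores.adaboost <- function(model, features) predict(model, features, type = "prob")

#' @export
predict_scores.stacking <- function(model, features) predict(model, features, type = "prob")

#' @export
predict_scores.randomForest <- function(model, features) {
  predict(model, features, type = "prob")
}

#' @export
predict_scores.svm <- function(model, features) {
  attr(predict(model, features, probability = TRUE), "probabilities")
}

#' Cross-validated hyperparameter selection
#'
#' Stratified k-fold cross validation over a configuration grid for one
#' model family, recording per-fold training and validation accuracies (the
#' learning-curve view). The winning configuration has the highest mean
#' validation accuracy; ties go to the earlier grid row, so ordering the
#' grid from simplest to most complex model prefers the simpler one.
#'
#' @param family `"elm"`, `"adaboost"`, `"rf"`, `"svm"` or `"stacking"`.
#' @param x Feature matrix.
#' @param y Labels.
#' @param grid Data frame of configurations, one row each; column names are
#'   the fitting arguments of the family (`hidden` for ELM; `rounds`,
#'   `maxdepth` for AdaBoost; `rf_trees`, `svm_cost`, `meta_hidden`, ... for
#'   stacking; `ntree` for rf; `cost`, `gamma` for svm).
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return List of class `"cv_result"`: `best` (named list), `curve` (data
#'   frame of per-config per-fold accuracies) and `summary` (mean accuracies
#'   per config).
#' @export
cross_validate <- function(family = c("elm", "adaboost", "rf", "svm", "stacking"),
                           x, y, grid, folds = 5, seed = NULL) {
  family <- match.arg(family)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty configuration grid", call. = FALSE)
  x <- as.matrix(x)
  y <- factor(y)
  fit_one <- function(params, xt, yt, fit_seed) {
    switch(family,
      elm = elm(xt, yt, hidden = params$hidden, seed = fit_seed),
      adaboost = adaboost(xt, yt, rounds = params$rounds,
                          maxdepth = if (is.null(params$maxdepth)) 3 else params$maxdepth),
      rf = randomForest::randomForest(x = xt, y = yt, ntree = params$ntree),
      svm = e1071::svm(x = xt, y = yt, kernel = "radial", cost = params$cost,
                       probability = TRUE),
      stacking = stacking(xt, yt, control = do.call(stacking_control,
                          params[intersect(names(params),
                                           names(formals(stacking_control)))]),
                          seed = fit_seed))
  }
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit_seed <- sample.int(.Machine$integer.max, 1)
        fit <- fit_one(params, x[tr, , drop = FALSE], droplevels(y[tr]), fit_seed)
        acc <- function(rowsel) {
          pred <- if (family %in% c("rf", "svm")) {
            as.character(predict(fit, x[rowsel, , drop = FALSE]))
          } else {
            predict(fit, x[rowsel, , drop = FALSE], type = "class")
          }
          mean(pred == as.character(y[rowsel]))
        }
        rows[[length(rows) + 1L]] <- data.frame(config = g, fold = f,
                                                train_acc = acc(tr),
                                                val_acc = acc(!tr))
      }
    }
    curve <- do.call(rbind, rows)
    means <- stats::aggregate(cbind(train_acc, val_acc) ~ config, curve, mean)
    best_idx <- means$config[which.max(means$val_acc)]  # first max: simpler wins ties
    structure(list(best = as.list(grid[best_idx, , drop = FALSE]),
                   best_config = best_idx, curve = curve, summary = means,
                   family = family),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation over", max(x$curve$config), "configuration(s) of", x$family, "\n")
  print(x$summary, row.names = FALSE)
  cat("best configuration:", x$best_config, "\n")
  invisible(x)
}
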