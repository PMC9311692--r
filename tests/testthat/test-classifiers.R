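make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[k, ], each = n_per), sd = sd),
           n_per, ncol(centers))
  }))
  colnames(x) <- paste0("f", seq_len(ncol(centers)))
  list(x = x, y = factor(rep(rownames(centers), each = n_per)))
}

test_that("the ELM separates two well-separated Gaussian blobs perfectly", {
  d <- make_blobs(100, rbind(a = c(0, 0), b = c(5, 5)), sd = 0.5, seed = 2)
  fit <- elm(d$x, d$y, hidden = 40, seed = 7)
  expect_equal(mean(predict(fit, d$x) == as.character(d$y)), 1)
})

test_that("the same seed reproduces the ELM exactly", {
  d <- make_blobs(30, rbind(a = c(0, 0), b = c(3, 3)), seed = 4)
  f1 <- elm(d$x, d$y, hidden = 25, seed = 11)
  f2 <- elm(d$x, d$y, hidden = 25, seed = 11)
  f3 <- elm(d$x, d$y, hidden = 25, seed = 12)
  expect_identical(f1$beta, f2$beta)
  expect_false(identical(f1$beta, f3$beta))
})

test_that("the minimum-norm solve interpolates when hidden width reaches the row count", {
  d <- make_blobs(4, rbind(a = c(0, 0), b = c(2, 2), c = c(-2, 2)), sd = 0.3, seed = 6)
  fit <- elm(d$x, d$y, hidden = 30, seed = 1)  # width > 12 rows
  raw <- predict(fit, d$x, type = "raw")
  onehot <- diag(3)[as.integer(d$y), ]
  expect_lt(max(abs(raw - onehot)), 1e-6)
})

test_that("a one-unit ELM beats chance but trails a wide one on 3-class data", {
  d <- make_blobs(60, rbind(a = c(0, 0), b = c(4, 0), c = c(0, 4)), sd = 0.6, seed = 8)
  accs <- vapply(1:5, function(s) {
    narrow <- mean(predict(elm(d$x, d$y, hidden = 1, seed = s), d$x) == as.character(d$y))
    wide <- mean(predict(elm(d$x, d$y, hidden = 60, seed = s), d$x) == as.character(d$y))
    c(narrow, wide)
  }, numeric(2))
  expect_gte(mean(accs[1, ]), 1 / 3)
  expect_gt(mean(accs[2, ]), mean(accs[1, ]))
  expect_gt(mean(accs[2, ]), 0.95)
})

test_that("degenerate and invalid classifier inputs are handled", {
  d <- make_blobs(20, rbind(a = c(0, 0), b = c(3, 3)), seed = 3)
  expect_error(elm(d$x, rep("a", 40)), "2 classes")
  # duplicated rows make the hidden matrix rank-deficient; the minimum-norm
  # solution still goes through
  xdup <- d$x[rep(c(1:5, 21:25), 4), ]
  ydup <- d$y[rep(c(1:5, 21:25), 4)]
  expect_s3_class(elm(xdup, ydup, hidden = 50, seed = 1), "elm")
  expect_error(stacking(d$x, rep("a", 40)), "2 classes")
  expect_error(adaboost(d$x, rep("a", 40)), "2 classes")
})

test_that("probability scores are non-negative and rows sum to one", {
  d <- make_blobs(30, rbind(a = c(0, 0), b = c(3, 0), c = c(0, 3)), seed = 5)
  fits <- list(elm(d$x, d$y, hidden = 30, seed = 1),
               adaboost(d$x, d$y, rounds = 10),
               stacking(d$x, d$y, stacking_control(adaboost_rounds = 5, rf_trees = 50,
                                                   meta_hidden = 30), seed = 2))
  for (fit in fits) {
    p <- predict_scores(fit, d$x)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, nrow(d$x)), tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(sort(colnames(p)), sort(levels(d$y)))
  }
})

test_that("stacking matches or beats its best base learner on held-out data", {
  ds <- fixture_dataset()
  ctrl <- stacking_control(adaboost_rounds = 20, rf_trees = 100, meta_hidden = 60)
  margins <- vapply(1:3, function(rep) {
    seed <- 100 + rep
    stack <- stacking(ds$train, ds$train_labels, ctrl, seed = seed)
    stack_acc <- mean(predict(stack, ds$test) == as.character(ds$test_labels))
    base_acc <- max(vapply(ovisense:::BASE_LEARNERS, function(b) {
      fit <- ovisense:::fit_base(b, ds$train, ds$train_labels, ctrl)
      p <- ovisense:::base_probs(b, fit, ds$test, levels(ds$train_labels))
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      mean(pred == as.character(ds$test_labels))
    }, numeric(1)))
    stack_acc - base_acc
  }, numeric(1))
  expect_true(all(margins >= -0.02))
})

test_that("out-of-fold meta-features cannot leak labels", {
  # with pure-noise features, any in-fold leakage would let the overfit base
  # learners feed the meta-ELM optimistic scores; held-out accuracy must
  # stay near chance
  set.seed(77)
  x <- matrix(rnorm(160 * 6), 160, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(rep(c("a", "b"), each = 80))
  tr <- c(1:60, 81:140)
  fit <- stacking(x[tr, ], y[tr],
                  stacking_control(adaboost_rounds = 10, rf_trees = 50,
                                   meta_hidden = 30), seed = 5)
  acc <- mean(predict(fit, x[-tr, ]) == as.character(y[-tr]))
  expect_lt(acc, 0.75)
  # and the fit is reproducible under its seed
  fit2 <- stacking(x[tr, ], y[tr],
                   stacking_control(adaboost_rounds = 10, rf_trees = 50,
                                    meta_hidden = 30), seed = 5)
  expect_identical(predict(fit, x[-tr, ]), predict(fit2, x[-tr, ]))
})

test_that("stratified folds spread every class evenly", {
  y <- factor(rep(c("a", "b", "c"), times = c(40, 25, 10)))
  fold <- stratified_folds(y, 5, seed = 1)
  for (cl in levels(y)) {
    per_fold <- table(fold[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 40))), 5), "at least 5")
})

test_that("cross-validation records learning curves and picks the best grid point", {
  d <- make_blobs(40, rbind(a = c(0, 0), b = c(2.5, 2.5)), sd = 0.8, seed = 9)
  one <- cross_validate("elm", d$x, d$y, grid = data.frame(hidden = 20), seed = 1)
  expect_equal(one$best$hidden, 20)
  expect_equal(nrow(one$curve), 5)

  cv <- cross_validate("elm", d$x, d$y, grid = data.frame(hidden = c(2, 40, 200)),
                       folds = 5, seed = 2)
  expect_true(cv$best_config %in% 1:3)
  # a flexible model does not validate better than it trains, on average
  flex <- subset(cv$curve, config == 3)
  expect_lte(mean(flex$val_acc), mean(flex$train_acc) + 1e-9)
  expect_error(cross_validate("elm", d$x, d$y, grid = data.frame()), "empty")
})

test_that("all three model families exceed 95% held-out accuracy on separable behaviors", {
  ds <- fixture_dataset()
  truth <- as.character(ds$test_labels)
  fits <- list(
    elm = elm(ds$train, ds$train_labels, hidden = 150, seed = 42),
    adaboost = adaboost(ds$train, ds$train_labels, rounds = 30),
    stacking = stacking(ds$train, ds$train_labels,
                        stacking_control(adaboost_rounds = 20, rf_trees = 100),
                        seed = 42))
  for (name in names(fits)) {
    pred <- if (name == "elm") predict(fits[[name]], ds$test)
            else predict(fits[[name]], ds$test, type = "class")
    expect_gt(mean(pred == truth), 0.95)
  }
})
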