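test_that("the feature bank emits 63/48/111 features regardless of window size", {
  st <- fixture_stream()
  for (size in c(3, 4, 5, 11)) {
    w <- window_partition(st, size, "jump")[[1]]
    expect_length(compute_features(w, "acc"), 63)
    expect_length(compute_features(w, "gyr"), 48)
    both <- compute_features(w, "both")
    expect_length(both, 111)
    expect_true(all(is.finite(both)))
  }
})

test_that("window counts follow the jump and slide arithmetic", {
  sim <- synthesize_imu(cbs_demo_schedule(), seed = 1)
  st <- link_labels(sim$stream, sim$labels)
  expect_length(window_partition(st, 3, "jump"), 11)       # 33 / 3
  jump5 <- window_partition(st, 5, "jump")
  expect_length(jump5, 7)                                   # 6 full + trailing 3 s
  expect_true(isTRUE(attr(jump5[[7]], "partial")))
  expect_equal(nrow(jump5[[7]]$data), 3 * 20)
  expect_length(window_partition(st, 11, "slide"), 23)      # 33 - 11 + 1
  expect_length(window_partition(st, 33, "slide"), 1)
  expect_error(window_partition(st, 40, "jump"), "shorter")
})

test_that("training keeps only pure complete windows of real behaviors", {
  sim <- synthesize_imu(cbs_demo_schedule(), seed = 1)
  st <- link_labels(sim$stream, sim$labels)
  train11 <- window_partition(st, 11, "jump", training = TRUE)
  expect_length(train11, 2)  # [0,11) grazing and [22,33) standing
  expect_identical(vapply(train11, `[[`, "", "majority"), c("grazing", "standing"))
  expect_true(all(vapply(train11, `[[`, 0, "purity") == 1))
})

test_that("larger windows discard a larger share of mixed-behavior windows", {
  sim <- synthesize_imu(cbs_demo_schedule(), seed = 1)
  st <- link_labels(sim$stream, sim$labels)
  impure_frac <- vapply(c(3, 5, 11), function(size) {
    all_w <- Filter(function(w) !isTRUE(attr(w, "partial")),
                    window_partition(st, size, "jump"))
    kept <- window_partition(st, size, "jump", training = TRUE)
    1 - length(kept) / length(all_w)
  }, numeric(1))
  expect_true(all(diff(impure_frac) >= 0))
  expect_gt(impure_frac[3], impure_frac[1])
})

test_that("window majorities break ties toward the earliest-starting behavior", {
  expect_identical(ovisense:::majority_label(c("walking", "standing", "standing", "walking")),
                   "walking")
  expect_identical(ovisense:::majority_label(c("lying", "running", "running", "lying")),
                   "lying")
})

test_that("constant windows give the degenerate statistics by convention", {
  m <- matrix(2.5, 60, 6, dimnames = list(NULL, c("acc_x", "acc_y", "acc_z",
                                                  "gyr_x", "gyr_y", "gyr_z")))
  f <- compute_features(m, "acc")
  expect_equal(unname(f["acc_x_mean"]), 2.5)
  expect_equal(unname(f["acc_x_variance"]), 0)
  expect_equal(unname(f["acc_x_range"]), 0)
  expect_equal(unname(f["acc_x_rms"]), 2.5)
  expect_equal(unname(f["acc_x_kurtosis"]), 0)
  expect_equal(unname(f["acc_x_skewness"]), 0)
  expect_equal(unname(f["acc_x_domfreq"]), 0)
  expect_error(compute_features(m * NA, "acc"), "non-finite")
})

test_that("a pure sine window has the closed-form RMS and dominant frequency", {
  t <- seq_len(60) / 20  # first 3 s of a unit 2 Hz sine at 20 Hz
  m <- matrix(0.0, 60, 6, dimnames = list(NULL, c("acc_x", "acc_y", "acc_z",
                                                  "gyr_x", "gyr_y", "gyr_z")))
  m[, "acc_x"] <- sin(2 * pi * 2 * t)
  f <- compute_features(m, "acc", fs = 20)
  expect_equal(unname(f["acc_x_domfreq"]), 2)
  expect_equal(unname(f["acc_x_rms"]), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(f["acc_x_mean"]), 0, tolerance = 1e-9)
})

test_that("split is stratified 80/20 and standardization uses training statistics only", {
  set.seed(42)
  x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("a", "b"), each = 100)
  ds <- split_standardize(x, y, seed = 3)
  expect_equal(as.numeric(table(ds$train_labels)), c(80, 80))
  expect_length(ds$test_labels, 40)
  expect_equal(colMeans(ds$train), rep(0, 4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(ds$train, 2, sd), rep(1, 4), tolerance = 1e-10, ignore_attr = TRUE)
  # test rows use the training statistics, not their own
  expect_equal(ds$test,
               standardize_features(x[ds$idx_test, ], ds$center, ds$scale),
               ignore_attr = TRUE)
  # round trip
  back <- destandardize_features(ds$train, ds$center, ds$scale)
  expect_equal(back, x[ds$idx_train, ], tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(split_standardize(x[1:8, ], y[c(1:4, 101:104)]), "at least 5 rows")
})

test_that("feature ranking is deterministic and finds a planted informative feature", {
  set.seed(10)
  n <- 120
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("noise", 1:10)))
  y <- rep(c("a", "b"), each = n / 2)
  x[, 4] <- ifelse(y == "a", 0, 5) + rnorm(n, 0, 0.1)
  colnames(x)[4] <- "planted"
  top <- rank_features(x, y, k = 3, seed = 1)
  expect_identical(top[1], "planted")
  expect_identical(rank_features(x, y, k = 3, seed = 1), top)
  all_ranked <- rank_features(x, y, k = ncol(x), seed = 1)
  expect_setequal(all_ranked, colnames(x))
  expect_error(rank_features(x, y, k = 11), "exceeds")
  expect_error(rank_features(x, rep("a", n), k = 2), "2 classes")
})
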