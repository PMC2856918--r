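# Pattern classifier: feature selection statistics, network training,
# cross-validation hygiene, and the maintenance threshold rule.

test_that("feature selection has the nominal type-I rate on pure noise", {
  hits <- 0; bins <- 0
  for (r in 1:40) {
    tf <- noise_tf(seed = 100 + r)
    m <- tryCatch(select_features(tf, 0), error = function(e) NULL)
    hits <- hits + if (is.null(m)) 0 else nrow(m)
    bins <- bins + 8 * 34
  }
  rate <- hits / bins
  se <- sqrt(0.05 * 0.95 / bins)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("a strongly separated bin is essentially always selected", {
  # analytic oracle: paired t power at d = 3, n = 20 pairs, alpha 0.05 is
  # 1 - pt(qt(0.975, 19), 19, ncp = 3 * sqrt(20)) ~ 1 - 1e-9
  hit <- vapply(1:50, function(r) {
    tf <- noise_tf(seed = 300 + r)
    tf$amplitude[tf$info$category == "indoor", 3, 5, 1] <-
      tf$amplitude[tf$info$category == "indoor", 3, 5, 1] + 3
    m <- select_features(tf, 0)
    any(m$sensor == 3 & m$freq_idx == 5)
  }, TRUE)
  expect_equal(mean(hit), 1)
})

test_that("alpha = 0 refuses to select features", {
  expect_error(select_features(noise_tf(), 0, alpha = 0), "refused")
})

sep_tf <- function(d = 5, seed = 1, n_per = 20) {
  tf <- noise_tf(n_per = n_per, seed = seed)
  ind <- tf$info$category == "indoor"
  tf$amplitude[ind, 1:2, 1:5, 1] <- tf$amplitude[ind, 1:2, 1:5, 1] + d
  tf$amplitude[!ind, 5:6, 8:12, 1] <- tf$amplitude[!ind, 5:6, 8:12, 1] + d
  tf
}

test_that("training on separable clouds reaches perfect, confident training accuracy", {
  tf <- sep_tf()
  mask <- select_features(tf, 0)
  clf <- train_classifier(tf, mask, seed = 5)
  y <- predict(clf, tf)[, , 1]
  expect_true(all(y >= 0 & y <= 1))
  own <- ifelse(tf$info$category == "indoor", y[, 1], y[, 2])
  expect_true(all(own > 0.95))
  expect_equal(mean((CATEGORIES[max.col(y)] == tf$info$category)), 1)
})

test_that("training is deterministic given the seed", {
  tf <- sep_tf()
  mask <- select_features(tf, 0)
  a <- train_classifier(tf, mask, seed = 9)
  b <- train_classifier(tf, mask, seed = 9)
  expect_identical(a$weights, b$weights)
  c <- train_classifier(tf, mask, seed = 10)
  expect_false(identical(a$weights, c$weights))
})

test_that("LOOCV is perfect on separable data and near chance on shuffled labels", {
  tf <- sep_tf()
  expect_equal(loocv_accuracy(tf, 0, seed = 2), 1)

  set.seed(42)
  shuf <- sample(tf$info$category)
  acc <- loocv_accuracy(tf, 0, labels = shuf, seed = 2)
  # 95% binomial band around 0.5 at n = 40
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / 40))
})

test_that("the held-out trial never influences the fold's model", {
  tf <- sep_tf(seed = 3)
  tf_mut <- tf
  tf_mut$amplitude[1, , , 1] <- tf_mut$amplitude[1, , , 1] + 50  # corrupt trial 1
  # the model of the fold that excludes trial 1 must be unchanged
  keep <- 2:40
  sub <- function(x, i) {
    x$amplitude <- x$amplitude[i, , , , drop = FALSE]
    x$info <- x$info[i, , drop = FALSE]
    x
  }
  m1 <- select_features(sub(tf, keep), 0, tf$info$category[keep])
  m2 <- select_features(sub(tf_mut, keep), 0, tf$info$category[keep])
  expect_identical(m1, m2)
  c1 <- train_classifier(sub(tf, keep), m1, tf$info$category[keep], seed = 4)
  c2 <- train_classifier(sub(tf_mut, keep), m2, tf$info$category[keep], seed = 4)
  expect_identical(c1$weights, c2$weights)
})

test_that("LOOCV refuses degenerate inputs", {
  tf <- sep_tf()
  expect_error(loocv_accuracy(tf, 0, labels = rep("indoor", 40)),
               "degenerate|categor")
  tiny <- sep_tf(n_per = 2)
  tiny$amplitude <- tiny$amplitude[1:3, , , , drop = FALSE]
  tiny$info <- tiny$info[1:3, , drop = FALSE]
  expect_error(loocv_accuracy(tiny, 0), "at least 4")
})

test_that("the 0.95 output threshold follows the published decision rule", {
  r <- thetareplay:::threshold_correct(0.96, 0.31, "indoor")
  expect_equal(r$correct, 1L)
  r <- thetareplay:::threshold_correct(0.42, 0.98, "outdoor")
  expect_equal(r$correct, 1L)
  r <- thetareplay:::threshold_correct(0.94, 0.10, "indoor")
  expect_equal(r$correct, 0L)
  # both outputs confident: flagged ambiguous, not counted correct
  r <- thetareplay:::threshold_correct(0.97, 0.99, "indoor")
  expect_equal(r$correct, 0L)
  expect_true(r$ambiguous)
})

test_that("maintenance test grid spans 3250-7750 ms with 250 points", {
  grid <- seq(-1000, 7996, by = 4)
  tp <- maintenance_test_points(grid)
  expect_length(tp, 250)
  expect_lt(abs(min(tp) - 3250), 4)  # snapped to the 4 ms grid
  expect_lt(abs(max(tp) - 7750), 4)
  expect_lt(max(abs(diff(tp) - 4500 / 249)), 4)
})

test_that("classify_maintenance applies the rule per trial and time", {
  tf <- sep_tf()
  # give the tf a maintenance-like time axis with 3 points
  tf$amplitude <- array(tf$amplitude[, , , 1], c(40, 8, 34, 3))
  tf$time_ms <- c(4000, 5000, 6000)
  mask <- select_features(tf, 4000)
  clf <- train_classifier(tf, mask, seed = 6)
  rec <- classify_maintenance(clf, tf, test_points = c(4000, 5000, 6000))
  expect_equal(nrow(rec), 40 * 3)
  # features identical across the three times -> identical records
  expect_equal(rec$correct[rec$time_ms == 4000], rec$correct[rec$time_ms == 6000])
  # separable training data at these very features -> all correct
  expect_true(all(rec$correct == 1))
  # a tf without the classifier's bins is refused
  tf_bad <- tf
  tf_bad$amplitude <- tf$amplitude[, 1:2, 1:2, , drop = FALSE]
  expect_error(predict(clf, tf_bad), "absent")
})

test_that("maintenance decoding rate grows with the generator replay rate", {
  accs <- vapply(c(0.4, 2), function(lam) {
    p <- generator_params(n_subjects = 1, n_trials_per_category = 6,
                          n_sensors = 16,
                          replay_rate = c(control = 0, nonconfigural = lam,
                                          configural = lam),
                          rng_seed = 31)
    gs <- generate_subject(p, 1)
    idx <- which(gs$epochs$info$condition == "configural")
    sub <- thetareplay:::subset_epochs(gs$epochs, idx)
    grid <- seq(-1000, 7996, by = 4)
    times <- sort(unique(c(grid[grid >= -500 & grid <= -100], 364,
                           maintenance_test_points(grid, n = 100))))
    tf <- baseline_normalize(cwt_amplitude(sub, wavelet_spec(),
                                           times_ms = times))
    mask <- select_features(tf, 364)
    clf <- train_classifier(tf, mask, seed = 8)
    rec <- classify_maintenance(clf, tf,
                                test_points = maintenance_test_points(grid, n = 100))
    mean(rec$correct)
  }, 0)
  expect_gt(accs[2], accs[1])
})
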