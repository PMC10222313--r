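test_that("confusion matrix counts exactly and conserves totals", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(cm), matrix(c(1, 0, 1, 1), 2))

  set.seed(21)
  truth <- rep(0:9, each = 3)
  cm2 <- confusion_matrix(truth, truth, 10)
  expect_equal(unname(cm2), diag(3L, 10, 10))
  pred <- sample(0:9, 30, replace = TRUE)
  cm3 <- confusion_matrix(truth, pred, 10)
  expect_equal(sum(cm3), 30)
  expect_equal(unname(rowSums(cm3)), rep(3, 10))

  expect_error(confusion_matrix(integer(), integer(), 2), "empty")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "out of range")
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
})

test_that("per-class accuracy is 100 * diagonal / row sums", {
  expect_equal(per_class_accuracy(matrix(c(3, 0, 0, 3), 2)), c(100, 100))
  expect_equal(per_class_accuracy(matrix(c(1, 0, 1, 2), 2)), c(50, 100))
  # relabeling permutes but preserves the accuracy multiset
  cm <- matrix(c(8, 1, 0, 2, 7, 1, 0, 2, 9), 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  expect_setequal(per_class_accuracy(cm[perm, perm]), per_class_accuracy(cm))
  expect_error(per_class_accuracy(matrix(c(1, 0, 0, 0), 2)), "class 1")
})

test_that("the reference table's Average row is the unweighted column mean", {
  ref <- reference_accuracies()
  expected_avg <- c(
    time_domain_8ch = 88.6, time_domain_16ch = 93.8,
    spectrogram_8ch = 90.3, spectrogram_16ch = 95.6,
    enhanced_8ch = 95.4, enhanced_16ch = 98.6
  )
  got <- vapply(ref[-1], function(col) {
    round_half_up(average_accuracy(col), 1)
  }, numeric(1))
  expect_equal(got, expected_avg)

  # channel-count gains and 8-channel encoder gains, as printed
  expect_equal(expected_avg[["time_domain_16ch"]] -
                 expected_avg[["time_domain_8ch"]], 5.2)
  expect_equal(expected_avg[["spectrogram_16ch"]] -
                 expected_avg[["spectrogram_8ch"]], 5.3)
  expect_equal(expected_avg[["enhanced_16ch"]] -
                 expected_avg[["enhanced_8ch"]], 3.2, tolerance = 1e-12)
  expect_equal(expected_avg[["enhanced_8ch"]] -
                 expected_avg[["time_domain_8ch"]], 6.8)
  expect_equal(expected_avg[["enhanced_8ch"]] -
                 expected_avg[["spectrogram_8ch"]], 5.1, tolerance = 1e-12)

  expect_equal(average_accuracy(rep(77, 10)), 77)
  expect_error(average_accuracy(numeric()), "non-empty")
})

test_that("round_half_up rounds trailing halves upward at 1 decimal", {
  expect_equal(round_half_up(95.55, 1), 95.6)   # base round() would give 95.5
  expect_equal(round_half_up(90.26, 1), 90.3)
  expect_equal(round_half_up(88.63, 1), 88.6)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})

test_that("evaluation reports aggregate correctly and tidy cleanly", {
  truth <- rep(0:4, each = 4)
  pred <- truth
  pred[c(1, 6)] <- c(1L, 0L)  # two mistakes
  rep5 <- evaluation_report(truth, pred, 5,
                            condition = list(encoder = "spectrogram",
                                             n_channels = 16))
  expect_equal(sum(rep5$confusion), 20)
  expect_equal(rep5$per_class_accuracy, c(75, 75, 100, 100, 100),
               ignore_attr = TRUE)
  expect_equal(rep5$average_accuracy, 90)
  td <- tidy(rep5)
  expect_equal(td$accuracy, c(75, 75, 100, 100, 100))
  expect_equal(glance(rep5)$average_accuracy, 90)
})

test_that("average accuracy is invariant to a global relabeling permutation", {
  set.seed(33)
  truth <- sample(0:9, 200, replace = TRUE, prob = rep(0.1, 10))
  truth <- c(truth, 0:9)  # every class present
  pred <- ifelse(stats::runif(210) < 0.8, truth, sample(0:9, 210, TRUE))
  perm <- sample(0:9)
  r1 <- evaluation_report(truth, pred, 10)
  r2 <- evaluation_report(perm[truth + 1], perm[pred + 1], 10)
  expect_equal(r1$average_accuracy, r2$average_accuracy)
})

test_that("grouped splitting keeps repetitions intact and classes covered", {
  d <- simulate_dataset(gesture_profiles()[1:4, ],
                        tiny_sim_config(hold = 0.5, subjects = 2, reps = 3))
  imgs <- encode_dataset(d, "time_domain", n_channels = 8)
  parts <- split_train_test(imgs, prop = 0.8, seed = 5)
  expect_equal(nrow(parts$train) + nrow(parts$test), nrow(imgs))
  key <- function(x) unique(paste(x$subject_id, x$repetition))
  expect_length(intersect(key(parts$train), key(parts$test)), 0)
  expect_setequal(unique(parts$train$gesture_id), 0:3)
  expect_setequal(unique(parts$test$gesture_id), 0:3)
})
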