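test_that("generator reproduces its labelling rule and is deterministic", {
  d <- generate_printability_data(200, seed = 3)
  rule <- printability_rule(d$yield_stress_Pa, d$viscosity_Pa_s,
                            d$nozzle_diameter_um)
  expect_identical(d$printable == "printable", rule)
  d2 <- generate_printability_data(200, seed = 3)
  expect_identical(d, d2)
  expect_false(identical(d, generate_printability_data(200, seed = 4)))
  # label noise flips roughly the requested fraction
  dn <- generate_printability_data(2000, seed = 5, label_noise = 0.1)
  rn <- printability_rule(dn$yield_stress_Pa, dn$viscosity_Pa_s,
                          dn$nozzle_diameter_um)
  expect_equal(mean((dn$printable == "printable") != rn), 0.1, tolerance = 0.25)
})

test_that("class balance stays within 20-80% across seeds", {
  bal <- vapply(1:10, function(s)
    mean(generate_printability_data(400, seed = s)$printable == "printable"), 0)
  expect_true(all(bal >= 0.2 & bal <= 0.8))
})

test_that("generator validates its inputs", {
  expect_error(generate_printability_data(5), ">= 20")
  expect_error(generate_printability_data(100, label_noise = 0.6), "label_noise")
  expect_error(generate_printability_data(100, tau_y_range = c(5, 5)),
               "degenerate")
})

test_that("all seven families recover the separable boundary", {
  # Y-limited regime: the tearing clause is inactive, so the ground truth
  # is a single plane in log-feature space and every family can represent it
  d <- generate_printability_data(500, seed = 7, viscosity_range = c(10, 2e4))
  bank <- suppressWarnings(train_classifiers(d, "all", cv_folds = 5, seed = 3))
  acc <- summary(bank)
  expect_identical(nrow(acc), 7L)
  expect_true(all(acc$mean_accuracy >= 0.9),
              info = paste(acc$family, round(acc$mean_accuracy, 3),
                           collapse = "; "))
})

test_that("the two-clause rule favors nonlinear families over linear ones", {
  # with the tearing clause active the printable set is an intersection of
  # half-spaces; trees and kernels track the corner, a single plane cannot
  d <- generate_printability_data(500, seed = 7)
  bank <- suppressWarnings(train_classifiers(
    d, c("random_forest", "svm", "logistic"), cv_folds = 5, seed = 3))
  acc <- summary(bank)
  expect_gt(acc["random_forest", "mean_accuracy"], 0.93)
  expect_gt(acc["svm", "mean_accuracy"], 0.93)
  expect_gt(acc["random_forest", "mean_accuracy"],
            acc["logistic", "mean_accuracy"])
})

test_that("permuted labels collapse accuracy to chance", {
  d <- generate_printability_data(500, seed = 7)
  set.seed(11)
  d$printable <- sample(d$printable)
  bank <- suppressWarnings(
    train_classifiers(d, c("random_forest", "logistic"), cv_folds = 5, seed = 3))
  acc <- summary(bank)$mean_accuracy
  expect_true(all(abs(acc - 0.5) <= 0.1))
})

test_that("logistic coefficients carry the signs of the generating rule", {
  # Y-limited regime: viscosities kept below the tearing threshold
  d <- generate_printability_data(600, seed = 9, viscosity_range = c(10, 2e4))
  bank <- train_classifiers(d, "logistic", cv_folds = 3, seed = 2)
  cf <- bank$logistic$report$boundary
  expect_gt(cf[["log_tau_y"]], 0)
  expect_gt(cf[["log_d"]], 0)
  expect_lt(abs(cf[["log_mu"]]), 0.5 * cf[["log_tau_y"]])
})

test_that("training rejects degenerate inputs", {
  d <- generate_printability_data(100, seed = 1)
  d$printable <- factor("printable", levels = levels(d$printable))
  expect_error(train_classifiers(d), "single class")
})

test_that("predictions follow the rule deep in each region with boundary doubt", {
  d <- generate_printability_data(500, seed = 7)
  bank <- suppressWarnings(
    train_classifiers(d, c("random_forest", "logistic"), cv_folds = 3, seed = 3))
  deep_in <- data.frame(yield_stress_Pa = 500, viscosity_Pa_s = 1e3,
                        nozzle_diameter_um = 1500)
  deep_out <- data.frame(yield_stress_Pa = 1.5, viscosity_Pa_s = 5e5,
                         nozzle_diameter_um = 120)
  for (m in bank) {
    pin <- predict_printability(m, deep_in)
    pout <- predict_printability(m, deep_out)
    expect_identical(as.character(pin$label), "printable")
    expect_gte(pin$score, 0.9)
    expect_identical(as.character(pout$label), "not-printable")
    expect_lte(pout$score, 0.1)
  }
  # on the Y boundary (tau_y * R / sigma = Y_crit): calibrated doubt
  on_boundary <- data.frame(yield_stress_Pa = 0.1 * 0.025 / (500e-6 / 2),
                            viscosity_Pa_s = 1e3, nozzle_diameter_um = 500)
  sc <- predict_printability(bank$logistic, on_boundary)$score
  expect_gte(sc, 0.2); expect_lte(sc, 0.8)
  expect_error(predict_printability(bank$logistic,
                                    data.frame(yield_stress_Pa = 1)),
               "missing feature")
})

test_that("printability tables round-trip and reject malformed rows", {
  d <- generate_printability_data(100, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_printability_csv(d, path)
  d2 <- read_printability_csv(path)
  expect_equal(d2$yield_stress_Pa, d$yield_stress_Pa, tolerance = 1e-9)
  expect_identical(d2$printable, d$printable)
  expect_identical(nrow(attr(d2, "rejections")), 0L)
  # corrupt one row of 100: 99 records plus a logged rejection
  lines <- readLines(path)
  lines[10] <- "abc,10,500,printable"
  writeLines(lines, path)
  d3 <- read_printability_csv(path)
  expect_identical(nrow(d3), 99L)
  rej <- attr(d3, "rejections")
  expect_identical(nrow(rej), 1L)
  expect_match(rej$reason, "non-numeric")
  # empty file errors
  p2 <- tempfile(fileext = ".csv")
  writeLines("yield_stress_Pa,viscosity_Pa_s,nozzle_diameter_um,printable", p2)
  expect_error(read_printability_csv(p2), "empty")
})

test_that("training and prediction are deterministic under fixed seeds", {
  d <- generate_printability_data(200, seed = 5)
  b1 <- suppressWarnings(train_classifiers(d, c("random_forest", "xgboost"),
                                           cv_folds = 3, seed = 8))
  b2 <- suppressWarnings(train_classifiers(d, c("random_forest", "xgboost"),
                                           cv_folds = 3, seed = 8))
  expect_identical(summary(b1), summary(b2))
  nd <- generate_printability_data(50, seed = 6)
  expect_identical(predict_printability(b1$random_forest, nd),
                   predict_printability(b2$random_forest, nd))
})
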