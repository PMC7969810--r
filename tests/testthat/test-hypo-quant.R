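test_that("calibration recovers the fit-to-activity constant", {
  # single published pair fixes C near 8.328
  expect_equal(calibrate_constant(11.8863, 0.000276612), 8.3281,
               tolerance = 1e-3)
  # noiseless synthetic law is recovered exactly
  fits <- seq(2, 11, length.out = 20)
  expect_equal(calibrate_constant(fits, 10^(7 - fits)), 7, tolerance = 1e-12)
  # lognormal noise: recovery within 3 standard errors of the mean
  set.seed(99)
  fits <- stats::runif(200, 2, 11)
  ic50 <- 10^(7 - fits + stats::rnorm(200, 0, 0.3))
  expect_lt(abs(calibrate_constant(fits, ic50) - 7), 3 * 0.3 / sqrt(200))
  expect_error(calibrate_constant(numeric(0), numeric(0)), "non-empty")
  expect_error(calibrate_constant(1, -2), "positive")
})

test_that("predicted IC50 follows the log-linear mapping", {
  C <- calibrate_constant(11.8863, 0.000276612)
  expect_equal(predict_activity(10.1918, C), 0.013691, tolerance = 1e-5 / 0.0137)
  expect_equal(predict_activity(11.8863, C), 2.76612e-4, tolerance = 1e-6 / 2.7e-4)
  expect_equal(predict_activity(C, C), 1.0)
  # composition with calibration is the identity on noiseless data
  fits <- seq(3, 10, by = 0.5)
  ic50 <- 10^(6.5 - fits)
  C2 <- calibrate_constant(fits, ic50)
  expect_equal(predict_activity(fits, C2), ic50, tolerance = 1e-10)
})

test_that("error factors reproduce the signed fold-error convention", {
  expect_equal(error_factor(0.0002, 0.000276612), 1.38306, tolerance = 1e-5)
  expect_equal(error_factor(0.025, 0.0126119), -1.98225, tolerance = 1e-5)
  expect_identical(error_factor(0.37, 0.37), 1)
  # antisymmetry: swapping arguments flips the sign, keeps the magnitude
  set.seed(4)
  a <- stats::runif(20, 0.01, 10); b <- stats::runif(20, 0.01, 10)
  keep <- abs(a - b) > 1e-12
  ef_ab <- error_factor(a, b); ef_ba <- error_factor(b, a)
  expect_equal(abs(ef_ab[keep]), abs(ef_ba[keep]))
  expect_true(all(sign(ef_ab[keep]) == -sign(ef_ba[keep])))
  expect_true(all(abs(error_factor(a, b)) >= 1))
  expect_error(error_factor(0, 1), "positive")
})

test_that("activity scales partition the positive axis with inclusive bounds", {
  expect_identical(activity_scale(0.0002), "+++")
  expect_identical(activity_scale(0.1), "+++")
  expect_identical(activity_scale(0.1000001), "++")
  expect_identical(activity_scale(2.9999), "++")
  expect_identical(activity_scale(3), "+")
  expect_identical(activity_scale(3.32), "+")
  grid <- 10^seq(-5, 2, length.out = 200)
  labs <- activity_scale(grid)
  expect_true(all(labs %in% c("+++", "++", "+")))
  expect_error(activity_scale(-1), "positive")
})

test_that("assessment summarises correlation and scale agreement", {
  ic50 <- 10^seq(-3, 1, length.out = 10)
  perfect <- assess_predictions(tibble::tibble(experimental = ic50,
                                               predicted = ic50))
  expect_equal(perfect$pearson_r_log, 1)
  expect_identical(perfect$scale_agreement, 10L)
  mirrored <- assess_predictions(tibble::tibble(
    experimental = ic50, predicted = 10^(-log10(ic50))))
  expect_equal(mirrored$pearson_r_log, -1)
  expect_error(assess_predictions(tibble::tibble(experimental = 1:2,
                                                 predicted = 1:2)), "at least 3")
  g <- glance(perfect)
  expect_identical(g$n, 10L)
  expect_equal(g$r_squared_log, 1)
  td <- tidy(perfect)
  expect_identical(nrow(td), 10L)
  expect_s3_class(autoplot(perfect), "ggplot")
})

test_that("quantitative construction recovers a planted arrangement", {
  world <- quant_training_world(n = 10, noise = 0.2, seed = 21)
  cfg <- quant_config(min_features = 4L, max_features = 4L)
  model <- construct_quantitative_model(world$mols, world$activities, cfg)
  expect_identical(sort(model$constraints$kind),
                   sort(world$model$constraints$kind))
  # pairwise geometry of the recovered constraints matches the planted one
  rec <- sort(as.numeric(stats::dist(as.matrix(
    model$constraints[, c("x", "y", "z")]))))
  tru <- sort(as.numeric(stats::dist(as.matrix(
    world$model$constraints[, c("x", "y", "z")]))))
  expect_lt(max(abs(rec - tru)), 0.5)
  # calibration near the generating constant; strong training correlation
  expect_lt(abs(model$calibration_C - 8.3), 0.5)
  expect_gt(attr(model, "training_score"), 0.8)
  log <- attr(model, "evaluation_log")
  expect_s3_class(log, "tbl_df")
  expect_true(all(c("candidate", "score") %in% names(log)))
})

test_that("degenerate training inputs are rejected", {
  world <- quant_training_world(n = 8, seed = 33)
  expect_error(construct_quantitative_model(world$mols[1:2, ],
                                            world$activities[1:2, ]),
               "at least 8")
  flat <- world$activities
  flat$ic50 <- stats::runif(nrow(flat), 1, 1.5)  # span < 1 log unit
  expect_error(construct_quantitative_model(world$mols, flat), "span")
})
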