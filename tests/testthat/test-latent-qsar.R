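test_that("activity labeling follows the Ki thresholds", {
  expect_identical(
    as.character(label_activity(c(100, 101, 50, 9999, 10000, 20000))),
    c("active", "inactive", "active", "inactive", "excluded", "excluded")
  )
  expect_error(label_activity(c(10, -1)), class = "profis_invalid_measurement")
  expect_error(label_activity(NaN), class = "profis_invalid_measurement")
})

test_that("distance-to-model matches hand-computed cosine cases", {
  tz <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(distance_to_model(c(1, 0), tz, 3),
               1 - (1 + 0 + 1 / sqrt(2)) / 3, tolerance = 1e-12)
  # duplicated training point: distance zero
  tz2 <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(distance_to_model(c(1, 2), tz2, 3), 0, tolerance = 1e-12)
  # orthogonal query
  tz3 <- rbind(c(1, 0), c(1, 0), c(1, 0))
  expect_equal(distance_to_model(c(0, 1), tz3, 3), 1, tolerance = 1e-12)
  # invariance to positive rescaling of the query
  withr::with_seed(4, {
    tzr <- matrix(rnorm(30), 10, 3)
    q <- rnorm(3)
    expect_equal(distance_to_model(q, tzr), distance_to_model(5 * q, tzr))
  })
  expect_error(distance_to_model(c(0, 0), tz, 3),
               class = "profis_undefined_direction")
})

test_that("nested CV separates constructed classes and is seed-stable", {
  act <- activity_bundle()
  z <- separable_latents(act)
  cv <- nested_cv(z, act$activity, scaffolds = act$scaffold,
                  models = c("svm", "mlp"), seed = 7)
  expect_true(all(glance(cv)$roc_auc_mean > 0.9))
  cv2 <- nested_cv(z, act$activity, scaffolds = act$scaffold,
                   models = c("svm", "mlp"), seed = 7)
  expect_identical(glance(cv), glance(cv2))
  # metrics bounded
  expect_true(all(tidy(cv)$roc_auc >= 0 & tidy(cv)$roc_auc <= 1))
})

test_that("nested CV rejects degenerate single-class folds", {
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep("active", 20), levels = c("active", "inactive"))
  expect_error(nested_cv(x, y, models = "mlp", seed = 1),
               class = "profis_degenerate_fold")
})

test_that("DM error profile bins are half-open and empty bins are reported", {
  p <- c(0.9, 0.8, 0.4, 0.2)
  y <- factor(c("active", "active", "inactive", "inactive"))
  dm <- c(0.01, 0.05, 0.12, 0.3)
  prof <- dm_error_profile(p, y, dm)
  expect_equal(prof$n, c(1L, 1L, 1L, 1L))
  # 0.05 falls in the second (half-open) bin
  expect_equal(prof$median_abs_error[2], 0.2)
  prof2 <- dm_error_profile(p[1], y[1], dm[1])
  expect_equal(prof2$n, c(1L, 0L, 0L, 0L))
  expect_true(all(is.na(prof2$median_abs_error[2:4])))
})

test_that("an oracle classifier has near-zero error in every populated bin", {
  act <- activity_bundle()
  z <- separable_latents(act)
  y01 <- as.integer(act$activity == "active")
  # the generative rule itself as predictor
  p_oracle <- y01 * 0.98 + 0.01
  dm <- distance_to_model(z, z[1:100, ], 3)
  prof <- dm_error_profile(p_oracle, act$activity, dm)
  populated <- prof$n > 0
  expect_true(all(prof$median_abs_error[populated] < 0.05))
})
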