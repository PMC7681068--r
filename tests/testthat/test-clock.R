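test_that("self-standardization yields mean 0 / sd 1 and external params are applied verbatim", {
  g <- tiny_cohort(n = 50, p = 10, seed = 14)
  std <- log_standardize(g$cohort)
  expect_equal(unname(colMeans(std$z)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(std$z, 2, sd)), rep(1, 10), tolerance = 1e-10)

  # applying training params to the same cohort reproduces self-standardization
  again <- log_standardize(g$cohort, params = std$params)
  expect_equal(again$z, std$z)

  # constant column with external params -> constant (log10(v) - m)/s
  cohort <- proteomic_cohort(
    matrix(100, 5, 1, dimnames = list(paste0("S", 1:5), "A1")),
    data.frame(subject_id = paste0("S", 1:5), age = 1:5),
    data.frame(analyte_id = "A1"))
  p <- data.frame(analyte_id = "A1", mean = 1.5, sd = 2)
  z <- log_standardize(cohort, params = p)$z
  expect_equal(unname(z[, 1]), rep((2 - 1.5) / 2, 5))

  # zero-variance analyte dropped with a warning when estimating params
  g$cohort$intensities[, 3] <- 7
  expect_warning(s2 <- log_standardize(g$cohort), "zero-variance")
  expect_equal(ncol(s2$z), 9L)
})

test_that("train/test split follows the rounding contract and is a seeded partition", {
  g <- tiny_cohort(n = 90, p = 3, seed = 16)
  s <- split_train_test(g$cohort, fraction = 2/3, seed = 5)
  expect_length(s$train_ids, 60L)
  expect_length(intersect(s$train_ids, s$test_ids), 0L)
  expect_setequal(c(s$train_ids, s$test_ids), subject_ids_of(g$cohort))
  s2 <- split_train_test(g$cohort, fraction = 2/3, seed = 5)
  expect_identical(s, s2)
  expect_error(split_train_test(g$cohort, fraction = 1.2), "fraction")
})

test_that("prediction evaluation computes Pearson r and median absolute error", {
  ev <- evaluate_clock(c(30, 40, 50), c(30, 40, 50))
  expect_equal(ev$r, 1)
  expect_equal(ev$mae, 0)
  ev2 <- evaluate_clock(-c(30, 40, 50) + 10, c(30, 40, 50))
  expect_equal(ev2$r, -1)
  ev3 <- evaluate_clock(c(1, 3, 2), c(1, 2, 3))
  expect_equal(ev3$r, 0.5)
  expect_equal(ev3$mae, 1)
  expect_error(evaluate_clock(1:3, c(2, 2, 2)), "constant")
  expect_error(evaluate_clock(1:3, 1:4), "equal length")
})

test_that("clock predictions follow b0 + sum(beta * z) and ignore column order", {
  g <- tiny_cohort(n = 80, p = 15, seed = 17)
  ck <- train_clock(g$cohort, alpha = 0, seed = 17, n_lambda = 30)

  pred <- predict(ck, g$cohort)
  # manual evaluation from stored parameters
  z <- log_standardize(g$cohort, params = ck$standardization)$z
  manual <- drop(z %*% ck$beta) + ck$intercept
  expect_equal(pred, manual, tolerance = 1e-12)

  # permute analyte columns: predictions unchanged (alignment is by id)
  perm <- sample(ncol(g$cohort$intensities))
  shuffled <- proteomic_cohort(g$cohort$intensities[, perm],
                               g$cohort$subjects,
                               g$cohort$analytes[perm, , drop = FALSE])
  expect_equal(predict(ck, shuffled), pred, tolerance = 1e-12)

  # all-zero weights predict the constant intercept
  ck0 <- ck
  ck0$beta[] <- 0
  expect_equal(unname(predict(ck0, g$cohort)),
               rep(ck0$intercept, nrow(g$cohort$intensities)))
})

test_that("missing clock features raise an error pointing at subset prediction", {
  g <- tiny_cohort(n = 60, p = 10, seed = 18)
  ck <- train_clock(g$cohort, alpha = 0, seed = 18, n_lambda = 20)
  masked <- apply_platform_mask(g$cohort, analyte_ids(g$cohort)[1:6])
  expect_error(predict(ck, masked), "features")
  # explicit subset works
  pred <- predict(ck, masked, features = analyte_ids(masked))
  expect_length(pred, 60L)
  expect_error(predict(ck, masked, features = "not-a-feature"), "not part")
})

test_that("a trained clock on default-style synthetic data is accurate and seeded", {
  g <- generate_cohort(cohort_spec(n_subjects = 500, n_analytes = 200,
                                   seed = 19))
  ck <- train_clock(g$cohort, alpha = 0, seed = 19)
  expect_gt(ck$evaluation$test$r, 0.9)
  ck2 <- train_clock(g$cohort, alpha = 0, seed = 19)
  expect_identical(ck$beta, ck2$beta)
  # training-set mean prediction equals mean training age
  tr <- ck$split$train_ids
  sub <- g$cohort$subjects
  expect_equal(mean(predict(ck, g$cohort)[tr]),
               mean(sub$age[match(tr, sub$subject_id)]),
               tolerance = 1e-6)
})

test_that("global scaling option standardizes on the whole cohort", {
  g <- tiny_cohort(n = 100, p = 8, seed = 20)
  ck <- train_clock(g$cohort, alpha = 0, seed = 20, n_lambda = 20,
                    scaling = "global")
  L <- log10(g$cohort$intensities)
  expect_equal(ck$standardization$mean, unname(colMeans(L)), tolerance = 1e-12)
})
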