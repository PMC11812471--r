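test_that("fit_mccp partitions calibration scores per class across folds", {
  dat <- toy_training(n = 100)
  model <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 5,
                    seed = 3)
  per_class <- sapply(c("case", "control"), function(cl) {
    sum(vapply(model$folds, function(f) length(f$calib[[cl]]), integer(1)))
  })
  expect_equal(unname(per_class), c(50L, 50L))
  expect_equal(model$k, 5L)

  expect_error(fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 1),
               "at least 2")
  few <- dat[c(1:2, which(dat$status == "control")[1:20]), ]
  expect_error(fit_mccp(few[, c("prs", "age", "sex")], few$status, k = 5),
               "at least k")
  expect_error(fit_mccp(dat[, c("prs", "age", "sex")],
                        rep("sick", nrow(dat))), "unknown class")

  again <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 5,
                    seed = 3)
  expect_identical(model$folds, again$folds)
})

test_that("conformal p-values follow the counting formula", {
  # single fold, 9 calibration scores per class, identity model on prs
  m <- manual_mccp(calib_case = seq(0.1, 0.9, by = 0.1),
                   calib_control = seq(0.1, 0.9, by = 0.1))
  x_extreme <- data.frame(prs = -20, age = 0, sex = 0)  # P(case) ~ 0
  # alpha(case) ~ 1 > all 9 scores -> p = 1/10
  expect_equal(conformal_p(m, x_extreme, "case"), 1 / 10)
  # alpha(control) ~ 0 < all 9 scores -> p = 10/10 = 1
  expect_equal(conformal_p(m, x_extreme, "control"), 1)
  expect_error(conformal_p(m, x_extreme, "healthy"))

  # a duplicate of a calibration point counts its own tie
  alpha_tie <- 1 - stats::plogis(1)       # nonconformity of prs = 1 as case
  m_tie <- manual_mccp(calib_case = c(0.05, 0.1, alpha_tie, 0.8, 0.9),
                       calib_control = c(0.5))
  x_tie <- data.frame(prs = 1, age = 0, sex = 0)
  # scores >= alpha: the tie itself plus 0.8 and 0.9 -> (3+1)/(5+1)
  expect_equal(conformal_p(m_tie, x_tie, "case"), 4 / 6)
  expect_gte(conformal_p(m_tie, x_tie, "case"), 1 / 6)
})

test_that("fitted-model p-values match the brute-force oracle", {
  dat <- toy_training(n = 120)
  model <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 4,
                    seed = 5)
  newdata <- toy_training(n = 30, seed = 99)
  for (y in c("case", "control")) {
    expect_equal(conformal_p(model, newdata, y),
                 conformal_p_oracle(model, newdata, y), tolerance = 1e-12)
  }
  p <- conformal_p(model, newdata, "case")
  expect_true(all(p > 0 & p <= 1))
})

test_that("predict builds prediction sets, point labels and probabilities", {
  m <- manual_mccp(calib_case = seq(0.05, 0.95, by = 0.1),
                   calib_control = seq(0.05, 0.95, by = 0.1))
  strong_case <- data.frame(prs = 8, age = 0, sex = 0)
  # smallest attainable p is 1/11 with 10 calibration scores, so epsilon
  # must sit above it for the control label to drop out of the set
  pred <- predict(m, strong_case, epsilon = 0.1)
  expect_equal(pred$p_control, 1 / 11)
  expect_equal(pred$label_set, "case")
  expect_equal(pred$point_label, "case")
  expect_gt(pred$prob_affected, 0.99)

  # exactly symmetric input: p_case = p_control -> undecided
  sym <- data.frame(prs = 0, age = 0, sex = 0)
  pred_sym <- predict(m, sym, epsilon = 0.05)
  expect_equal(pred_sym$p_case, pred_sym$p_control)
  expect_equal(pred_sym$point_label, "undecided")
  expect_equal(pred_sym$label_set, "case,control")

  # epsilon above both p-values: empty set, flagged by empty label_set
  pred_none <- predict(m, strong_case, epsilon = 0.95)
  expect_equal(pred_none$label_set, "case")  # p_case = 1 > 0.95
  pred_mid <- predict(m, sym, epsilon = 0.9) # both p = 6/11 <= 0.9
  expect_equal(pred_mid$label_set, "")
  expect_error(predict(m, sym, epsilon = 0), "between 0 and 1")
  expect_error(predict(m, sym, epsilon = 1), "between 0 and 1")
})

test_that("prob_affected is monotone in PRS at fixed age and sex", {
  dat <- toy_training(n = 200)
  model <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 5,
                    seed = 6)
  grid <- data.frame(prs = seq(20, 50, length.out = 40), age = 70, sex = "F")
  pred <- predict(model, grid)
  expect_true(all(diff(pred$prob_affected) >= 0))
})

test_that("margin nonconformity is rank-equivalent to prob in binary classification", {
  # with two classes the margin is a strictly monotone transform of the
  # probability score, so the conformal p-values must coincide exactly
  dat <- toy_training(n = 120)
  m1 <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, seed = 8)
  m2 <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, seed = 8,
                 nonconformity = "margin")
  newdata <- toy_training(n = 10, seed = 13)
  p1 <- conformal_p(m1, newdata, "case")
  p2 <- conformal_p(m2, newdata, "case")
  expect_true(all(p2 > 0 & p2 <= 1))
  expect_equal(conformal_p_oracle(m2, newdata, "case"), p2,
               tolerance = 1e-12)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("MCCP models serialize to JSON and back without drift", {
  dat <- toy_training(n = 100)
  model <- fit_mccp(dat[, c("prs", "age", "sex")], dat$status, k = 3,
                    seed = 9)
  path <- tempfile(fileext = ".json")
  write_mccp(model, path)
  back <- read_mccp(path)
  newdata <- toy_training(n = 25, seed = 14)
  expect_equal(predict(back, newdata), predict(model, newdata),
               tolerance = 1e-12)
  expect_equal(back$centre, model$centre)
  expect_error(read_mccp(write_predictions(predict(model, newdata),
                                           tempfile())), "not an amdprs")
})
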