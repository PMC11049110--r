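test_that("noise-free 4PL data are recovered essentially exactly", {
  d <- rep(c(0.5, 1, 2, 5, 10, 20, 50, 100), each = 2)
  y <- four_pl(d, top = 100, bottom = 0, ec50 = 10, hill = 2)
  fit <- fit_four_parameter_logistic(d, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 10) / 10, 1e-4)
  expect_lt(abs(fit$hill - 2), 1e-3)
  expect_lt(abs(fit$top - 100), 1e-3)
  expect_lt(abs(fit$bottom - 0), 1e-3)
  expect_gt(fit$r2, 1 - 1e-8)
})

test_that("an increasing (death-type) curve is recovered too", {
  d <- c(1, 3, 10, 30, 100, 300)
  y <- four_pl(d, top = 0, bottom = 100, ec50 = 30, hill = 1.5)
  fit <- fit_four_parameter_logistic(d, y)
  expect_lt(abs(fit$ec50 - 30) / 30, 1e-4)
  # `top` reports the zero-dose asymptote regardless of direction
  expect_lt(abs(fit$top - 0), 1e-3)
  expect_lt(abs(fit$bottom - 100), 1e-3)
})

test_that("constant responses yield a failed fit", {
  d <- c(1, 3, 10, 30, 100)
  fit <- fit_four_parameter_logistic(d, rep(50, 5))
  expect_false(fit$converged)
  expect_identical(fit$rejection_reason, "fit_failed")
  expect_false(assess_fit_acceptance(fit)$accepted)
})

test_that("zero doses are excluded and too-few doses rejected", {
  expect_error(fit_four_parameter_logistic(c(0, 1, 2, 4), c(100, 90, 50, 10)),
               "4 distinct positive")
  d <- c(0, 1, 3, 10, 30)
  y <- four_pl(d, 100, 0, 5, 2)
  fit <- fit_four_parameter_logistic(d, y)
  expect_identical(sort(unique(fit$data$dose)), c(1, 3, 10, 30))
})

test_that("noisy EC50 recovery has small median relative error", {
  set.seed(21)
  errs <- replicate(60, {
    d <- rep(c(0.5, 1, 2, 5, 10, 20, 50, 100), each = 8)
    y <- four_pl(d, 100, 0, 10, 2) + rnorm(length(d), sd = 5)
    fit <- fit_four_parameter_logistic(d, y)
    abs(fit$ec50 - 10) / 10
  })
  expect_lt(median(errs), 0.15)
})

test_that("dose-unit relabeling rescales EC50 exactly and nothing else", {
  set.seed(5)
  d <- rep(c(1, 3, 10, 30, 100, 300), each = 3)
  y <- four_pl(d, 100, 5, 20, 1.5) + rnorm(length(d), sd = 2)
  f1 <- fit_four_parameter_logistic(d, y)
  f2 <- fit_four_parameter_logistic(d * 1000, y)  # ug/mL -> ng/mL
  expect_equal(f2$ec50, 1000 * f1$ec50, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
})

test_that("monotone sigmoid data are accepted", {
  set.seed(6)
  d <- rep(c(1, 3, 10, 30, 100), each = 4)
  y <- four_pl(d, 100, 0, 10, 2) + rnorm(length(d), sd = 2)
  fit <- assess_fit_acceptance(fit_four_parameter_logistic(d, y))
  expect_true(fit$accepted)
  expect_identical(fit$rejection_reason, "none")
})

test_that("a rebound dose-response is rejected as non-monotonic", {
  # drug-loaded-particle pattern: strong drop at low dose, partial recovery
  # at intermediate doses, final drop at the highest doses
  d <- c(0.002, 0.02, 0.2, 2, 4, 8, 32, 256, 512)
  y <- c(98, 95, 40, 42, 68, 72, 25, 8, 5)
  reps <- rep(d, each = 3)
  yy <- rep(y, each = 3) + rep(c(-1, 0, 1), times = length(d))
  fit <- assess_fit_acceptance(fit_four_parameter_logistic(reps, yy))
  expect_false(fit$accepted)
  expect_identical(fit$rejection_reason, "non_monotonic")
})

test_that("an EC50 far outside the tested range is flagged", {
  d <- rep(c(1, 2, 4, 8), each = 3)
  # shallow curve whose midpoint lies far above the tested range
  y <- four_pl(rep(d, 1), 100, 0, 80, 1)
  fit <- fit_four_parameter_logistic(d, y)
  fit <- assess_fit_acceptance(fit)
  expect_false(fit$accepted)
  expect_identical(fit$rejection_reason, "ec50_out_of_range")
})

test_that("complete separation from the control earns three stars", {
  df <- tibble::tibble(dose = rep(c(0, 1), each = 3),
                       response = c(100, 100, 100, 0, 0, 0))
  out <- compare_to_control(df)
  expect_identical(out$stars, "***")
})

test_that("identical groups earn no stars", {
  df <- tibble::tibble(dose = rep(c(0, 1, 2), each = 3),
                       response = rep(c(1, 2, 3), 3))
  out <- compare_to_control(df)
  expect_identical(out$stars, c("", ""))
})

test_that("the family-wise false-positive rate is controlled under the null", {
  set.seed(31)
  n_rep <- 400
  hits <- replicate(n_rep, {
    df <- tibble::tibble(dose = rep(c(0, 1, 2, 4, 8), each = 3),
                         response = rnorm(15))
    any(compare_to_control(df)$stars != "")
  })
  fwer <- mean(hits)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("EC50 summaries report mean, SD and not-determined conditions", {
  fits <- tibble::tibble(
    assay = rep(c("DHM", "WST-8"), each = 3),
    condition = "PACA",
    ec50 = c(9, 10, 8, 1, 2, 3),
    accepted = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  out <- summarize_ec50_across_experiments(fits)
  dhm <- out[out$assay == "DHM", ]
  expect_equal(dhm$ec50_mean, 9)
  expect_equal(dhm$ec50_sd, 1)
  expect_true(dhm$determined)
  wst <- out[out$assay == "WST-8", ]
  expect_false(wst$determined)
  expect_identical(wst$label, "not determined")
  one <- summarize_ec50_across_experiments(
    tibble::tibble(assay = "LDH", condition = "PACA", ec50 = 5,
                   accepted = TRUE))
  expect_true(is.na(one$ec50_sd))
})

test_that("tidy, glance and autoplot work on a fit", {
  d <- rep(c(1, 3, 10, 30, 100), each = 2)
  y <- four_pl(d, 100, 0, 10, 2)
  fit <- assess_fit_acceptance(fit_four_parameter_logistic(d, y))
  td <- tidy(fit)
  expect_identical(td$term, c("bottom", "top", "ec50", "hill"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$accepted)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
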