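make_wst8 <- function(sample_od450, sample_od620,
                      bg = c(0.15, 0.05), neg = c(1.5, 0.1)) {
  tibble::tibble(
    well_id = c("B1", "B2", "N1", "N2", "S1"),
    role = c("background", "background", "negative_control",
             "negative_control", "sample"),
    od450 = c(bg[1], bg[1], neg[1], neg[1], sample_od450),
    od620 = c(bg[2], bg[2], neg[2], neg[2], sample_od620))
}

test_that("WST-8 normalization identities hold exactly", {
  # sample at the negative-control means -> exactly 100%
  p <- make_wst8(1.5, 0.1)
  expect_equal(wst8_viability(p)$viability_percent[5], 100, tolerance = 0)
  # sample at the background means -> exactly 0%
  p0 <- make_wst8(0.15, 0.05)
  expect_equal(wst8_viability(p0)$viability_percent[5], 0, tolerance = 0)
})

test_that("WST-8 mid case matches the hand-computed value", {
  p <- make_wst8(0.8, 0.1)
  got <- wst8_viability(p)$viability_percent[5]
  expect_equal(got, 100 * (0.7 - 0.1) / (1.4 - 0.1), tolerance = 1e-9)
  expect_equal(got, 46.1538461538, tolerance = 1e-6)
})

test_that("WST-8 viability is invariant to adding a constant to every OD450", {
  p <- make_wst8(0.8, 0.1)
  v1 <- wst8_viability(p)$viability_percent
  p2 <- dplyr::mutate(p, od450 = od450 + 0.3)
  expect_equal(wst8_viability(p2)$viability_percent, v1, tolerance = 1e-12)
})

test_that("a control signal below background flags the plate invalid", {
  p <- make_wst8(0.8, 0.1, neg = c(0.1, 0.05))
  expect_warning(out <- wst8_viability(p), "invalid")
  expect_false(out$plate_valid[1])
  expect_true(all(is.na(out$viability_percent)))
})

test_that("missing control roles raise layout errors", {
  p <- make_wst8(0.8, 0.1)
  expect_error(wst8_viability(p[p$role != "background", ]),
               class = "holotox_layout_error")
})

test_that("an exactly linear LDH series returns its slope over the full range", {
  t <- 0:30
  out <- ldh_kinetic_slope(t, 0.05 + 0.02 * t)
  expect_equal(out$slope, 0.02, tolerance = 1e-12)
  expect_equal(c(out$t_start, out$t_end), c(0, 30))
  expect_false(out$nonlinear_kinetics)
})

test_that("a plateaued series is fitted on the linear segment only", {
  t <- 0:30
  y <- 0.05 + 0.02 * pmin(t, 20)
  out <- ldh_kinetic_slope(t, y)
  expect_equal(out$slope, 0.02, tolerance = 1e-6)
  expect_lte(out$t_end, 20)
  expect_gte(out$r2, 0.99)
})

test_that("a constant series gives slope zero over the full window", {
  out <- ldh_kinetic_slope(0:30, rep(0.4, 31))
  expect_equal(out$slope, 0)
  expect_equal(c(out$t_start, out$t_end), c(0, 30))
  expect_false(out$nonlinear_kinetics)
})

test_that("series with no linear window fall back with a flag", {
  set.seed(8)
  t <- 0:30
  y <- sin(t / 3) + rnorm(31, sd = 0.4)
  out <- ldh_kinetic_slope(t, y)
  expect_true(out$nonlinear_kinetics)
  expect_equal(c(out$t_start, out$t_end), c(0, 30))
})

test_that("LDH release normalization maps controls to exactly 0 and 100", {
  slopes <- tibble::tibble(
    well_id = c("N1", "N2", "P1", "P2", "S1"),
    role = c("negative_control", "negative_control",
             "positive_control", "positive_control", "sample"),
    slope = c(0.2, 0.2, 0.8, 0.8, 0.5))
  out <- ldh_release_percent(slopes)
  expect_equal(out$release_percent[1:2], c(0, 0), tolerance = 0)
  expect_equal(out$release_percent[3:4], c(100, 100), tolerance = 0)
  expect_equal(out$release_percent[5], 50, tolerance = 1e-9)
})

test_that("LDH release is invariant under positive scaling of all slopes", {
  slopes <- tibble::tibble(
    role = c("negative_control", "positive_control", "sample", "sample"),
    slope = c(0.1, 0.9, 0.3, 1.1))
  r1 <- ldh_release_percent(slopes)$release_percent
  slopes2 <- dplyr::mutate(slopes, slope = slope * 7)
  expect_equal(ldh_release_percent(slopes2)$release_percent, r1,
               tolerance = 1e-12)
  # values outside [0, 100] are reported unclamped
  expect_gt(max(r1), 100)
})

test_that("a positive control not exceeding the negative flags the plate", {
  slopes <- tibble::tibble(
    role = c("negative_control", "positive_control", "sample"),
    slope = c(0.5, 0.4, 0.45))
  expect_warning(out <- ldh_release_percent(slopes), "invalid")
  expect_false(out$plate_valid[1])
})

test_that("simulated plates round-trip their truths through the normalizations", {
  layout <- plate_layout(c(1, 3, 10, 30, 100), n_replicates = 4)
  tv <- dose_effect_truth(10, hill = 1.5, endpoint = "viability")
  td <- dose_effect_truth(10, hill = 1.5, top = 0, bottom = 1,
                          endpoint = "death")
  # noise off: exact recovery
  p0 <- simulate_absorbance_plate(layout, tv, td, noise = plate_noise(off = TRUE),
                                  seed = 1)
  v0 <- wst8_viability(p0$wst8)
  s0 <- ldh_release_percent(ldh_slopes(p0$ldh))
  samp <- v0$role == "sample"
  expect_equal(v0$viability_percent[samp],
               100 * four_pl(v0$concentration[samp], 1, 0, 10, 1.5),
               tolerance = 1e-9)
  samp_l <- s0$role == "sample"
  expect_equal(s0$release_percent[samp_l],
               100 * four_pl(s0$concentration[samp_l], 0, 1, 10, 1.5),
               tolerance = 1e-6)
  # default noise: mean recovery within a few percent over seeded plates
  err_v <- err_d <- numeric(40)
  for (s in seq_len(40)) {
    p <- simulate_absorbance_plate(layout, tv, td, seed = s)
    v <- wst8_viability(p$wst8)
    r <- ldh_release_percent(ldh_slopes(p$ldh))
    err_v[s] <- mean(v$viability_percent[v$role == "sample"] -
                       100 * four_pl(v$concentration[v$role == "sample"],
                                     1, 0, 10, 1.5))
    err_d[s] <- mean(r$release_percent[r$role == "sample"] -
                       100 * four_pl(r$concentration[r$role == "sample"],
                                     0, 1, 10, 1.5))
  }
  expect_lt(abs(mean(err_v)), 3)
  expect_lt(abs(mean(err_d)), 3)
})

test_that("simulator demands the control roles", {
  layout <- plate_layout(c(1, 10))
  tv <- dose_effect_truth(10, endpoint = "viability")
  td <- dose_effect_truth(10, top = 0, bottom = 1, endpoint = "death")
  broken <- layout[layout$role != "positive_control", ]
  expect_error(simulate_absorbance_plate(broken, tv, td, seed = 1),
               class = "holotox_layout_error")
})
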