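test_that("carrier location finds a synthetic carrier to sub-bin precision", {
  cfg <- optical_config(pixel_count_x = 128, pixel_count_y = 128,
                        carrier_frequency = c(0.25, 0.15),
                        frames_per_stack = 1)
  sc <- generate_phase_scene(cfg, 4, seed = 1)
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(off = TRUE),
                                  seed = 2)
  est <- locate_carrier(st$frames[[1]])
  expect_lt(abs(est[1] - 0.25), 1 / (2 * 128))
  expect_lt(abs(est[2] - 0.15), 1 / (2 * 128))
})

test_that("a pure DC image raises a no-sideband error", {
  flat <- matrix(1, 64, 64)
  expect_error(locate_carrier(flat), class = "holotox_no_sideband")
})

test_that("the returned sideband lies in the positive-fx half-plane", {
  cfg <- optical_config(pixel_count_x = 64, pixel_count_y = 64,
                        carrier_frequency = c(0.25, 0.125),
                        frames_per_stack = 1)
  sc <- generate_phase_scene(cfg, 0, seed = 1)
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(off = TRUE),
                                  seed = 2)
  est <- locate_carrier(st$frames[[1]])
  expect_gt(est[1], 0)
})

test_that("noise-free demodulation round-trips the scene phase", {
  cfg <- small_config(256, frames = 1)
  sc <- generate_phase_scene(cfg, 12, seed = 5)
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(off = TRUE),
                                  seed = 2)
  fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
  rec <- unwrap_phase(fld$wrapped_phase)
  expect_lt(border_rmse(rec, sc$phase_map), 0.05)
})

test_that("a zero-phase scene reconstructs to (nearly) zero phase", {
  cfg <- small_config(128, frames = 1)
  sc <- generate_phase_scene(cfg, 0, seed = 1)
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(off = TRUE),
                                  seed = 2)
  fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
  expect_lt(abs(mean(fld$wrapped_phase)), 0.01)
})

test_that("reconstruction is linear in the scene phase within unwrap range", {
  cfg <- small_config(128, frames = 1)
  sc <- generate_phase_scene(cfg, 6, seed = 5)
  sc$phase_map <- sc$phase_map * (1.2 / max(sc$phase_map))
  sc2 <- sc
  sc2$phase_map <- sc$phase_map * 2
  rec <- function(s) {
    st <- synthesize_hologram_stack(s, cfg, noise = hologram_noise(off = TRUE),
                                    seed = 2)
    fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
    u <- unwrap_phase(fld$wrapped_phase)
    u - median(u)
  }
  r1 <- rec(sc); r2 <- rec(sc2)
  expect_lt(border_rmse(r2, 2 * r1), 0.05)
})

test_that("a filter radius reaching DC is rejected", {
  cfg <- small_config(64, frames = 1)
  h <- matrix(rnorm(64 * 64), 64, 64)
  expect_error(
    demodulate_to_phase(h, c(0.2, 0.1), cfg, filter_radius = 0.3),
    class = "holotox_filter_overlap")
})

test_that("unwrapping recovers a ramp exceeding 2 pi up to a 2 pi offset", {
  ramp <- outer(rep(1, 48), seq(0, 7 * pi, length.out = 96))
  u <- unwrap_phase(wrap_to_pi(ramp))
  d <- u - ramp
  expect_lt(max(d) - min(d), 1e-9)                 # constant offset only
  expect_equal((d[1, 1] / (2 * pi)) %% 1, 0, tolerance = 1e-9)
})

test_that("unwrapping is the identity on already-continuous input", {
  set.seed(1)
  smooth <- 0.5 * holotox:::smooth_noise_field(64, 64, 8)
  expect_equal(unwrap_phase(wrap_to_pi(smooth)), smooth, tolerance = 1e-9)
})

test_that("a 5-radian synthetic cell unwraps to the true peak", {
  cfg <- small_config(128, frames = 1)
  sc <- generate_phase_scene(cfg, 1, mass_cv = 0, radius_cv = 0, seed = 2)
  ph <- sc$phase_map * (5 / max(sc$phase_map))
  u <- unwrap_phase(wrap_to_pi(ph))
  u <- u - median(u) + median(ph)
  expect_lt(abs(max(u) - 5), 0.05)
})

test_that("propagation by zero is the identity and +d/-d is unitary", {
  cfg <- native_pitch_config(128)
  sc <- generate_phase_scene(cfg, 6, seed = 3)
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(off = TRUE),
                                  seed = 2)
  fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
  expect_identical(propagate_field(fld, 0)$values, fld$values)
  back <- propagate_field(propagate_field(fld, 37), -37)
  expect_lt(max(Mod(back$values - fld$values)) / max(Mod(fld$values)), 1e-6)
})

test_that("autofocus recovers introduced defocus within one search step", {
  cfg <- native_pitch_config(256)
  sc <- generate_phase_scene(cfg, 20, seed = 2)
  step <- 200 / 40
  # weak-phase population (thin, flat cells): full +-100 um search range
  weak <- sc
  weak$phase_map <- sc$phase_map * (1.2 / max(sc$phase_map))
  for (dz in c(40, -60, 80, -90)) {
    st <- synthesize_hologram_stack(weak, cfg,
                                    noise = hologram_noise(off = TRUE),
                                    defocus_um = dz, seed = 3)
    fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
    af <- refocus_autofocus(fld, search_range = c(-100, 100), steps = 41)
    expect_lte(abs(af$distance_um - (-dz)), step + 1e-9)
  }
  # full-strength population: moderate defocus (sideband truncation limits
  # the usable range for strong phase objects; see the methods vignette)
  for (dz in c(40, -30)) {
    st <- synthesize_hologram_stack(sc, cfg,
                                    noise = hologram_noise(off = TRUE),
                                    defocus_um = dz, seed = 3)
    fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
    af <- refocus_autofocus(fld, search_range = c(-100, 100), steps = 41)
    expect_lte(abs(af$distance_um - (-dz)), step + 1e-9)
  }
})

test_that("autofocus works at default noise", {
  cfg <- native_pitch_config(256)
  sc <- generate_phase_scene(cfg, 20, seed = 2)
  sc$phase_map <- sc$phase_map * (1.2 / max(sc$phase_map))
  st <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(),
                                  defocus_um = -25, seed = 4)
  fld <- demodulate_to_phase(st$frames[[1]], cfg$carrier_frequency, cfg)
  af <- refocus_autofocus(fld, search_range = c(-100, 100), steps = 41)
  expect_lte(abs(af$distance_um - 25), 5 + 1e-9)
})

test_that("stack averaging reduces independent speckle by about sqrt(n)", {
  set.seed(11)
  ratios <- replicate(50, {
    frames <- lapply(1:10, function(k)
      holotox:::smooth_noise_field(64, 64, 4) * 0.1)
    avg <- average_phase_stack(frames, mask = matrix(TRUE, 64, 64))
    stats::sd(frames[[1]]) / stats::sd(avg$phase)
  })
  expect_lt(abs(mean(ratios) - sqrt(10)) / sqrt(10), 0.2)
})

test_that("averaging a single frame is the identity", {
  f <- matrix(rnorm(32 * 32), 32, 32)
  avg <- average_phase_stack(list(f), mask = matrix(TRUE, 32, 32))
  expect_equal(avg$phase, f - median(f))
  expect_identical(avg$n_frames_averaged, 1L)
})

test_that("frames offset by 0 and 2 pi average without offset bias", {
  base <- matrix(0.2, 32, 32)
  avg <- average_phase_stack(list(base, base + 2 * pi),
                             mask = matrix(TRUE, 32, 32))
  expect_lt(max(abs(avg$phase)), 1e-12)
})

test_that("an empty stack is rejected", {
  expect_error(average_phase_stack(list()), "non-empty")
})

test_that("spectral filtering never increases total spectral power", {
  cfg <- small_config(128, frames = 1)
  sc <- generate_phase_scene(cfg, 8, seed = 6)
  st <- synthesize_hologram_stack(sc, cfg, seed = 7)
  h <- st$frames[[1]] - mean(st$frames[[1]])
  p_in <- sum(Mod(stats::fft(h))^2)
  fld <- demodulate_to_phase(h, cfg$carrier_frequency, cfg, flatten = FALSE)
  p_out <- sum(Mod(stats::fft(fld$values))^2)
  expect_lte(p_out, p_in)
})

test_that("full stack reconstruction recovers truth within tolerance over seeds", {
  cfg <- small_config(256, frames = 3)
  for (s in 1:3) {
    sc <- generate_phase_scene(cfg, 12, seed = s)
    st0 <- synthesize_hologram_stack(sc, cfg,
                                     noise = hologram_noise(off = TRUE),
                                     seed = 50 + s)
    q0 <- reconstruct_stack(st0, cfg, carrier = cfg$carrier_frequency)
    expect_lt(border_rmse(q0$phase, sc$phase_map), 0.05)
    st1 <- synthesize_hologram_stack(sc, cfg, noise = hologram_noise(),
                                     seed = 70 + s)
    q1 <- reconstruct_stack(st1, cfg, carrier = cfg$carrier_frequency)
    expect_lt(border_rmse(q1$phase, sc$phase_map), 0.1)
  }
})
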