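test_that("empty scene has zero phase and zero dry mass", {
  cfg <- small_config(64)
  sc <- generate_phase_scene(cfg, n_cells = 0, seed = 1)
  expect_true(all(sc$phase_map == 0))
  expect_equal(sc$true_total_dry_mass, 0)
  expect_equal(sc$cell_count, 0L)
})

test_that("single-cell scene mass matches the dry-mass relation exactly", {
  cfg <- small_config(128)
  sc <- generate_phase_scene(cfg, n_cells = 1, mean_cell_mass = 300,
                             mass_cv = 0, radius_cv = 0, seed = 7)
  # independent evaluation of dm = lambda/(2 pi alpha) * sum(phi) * A_px
  lambda_um <- 532e-9 * 1e6
  dm <- lambda_um / (2 * pi * 0.19) * sum(sc$phase_map) * cfg$pixel_area
  expect_equal(dm, 300, tolerance = 1e-9)
  expect_equal(sc$true_total_dry_mass, 300, tolerance = 1e-9)
})

test_that("scene generation is bitwise deterministic under a fixed seed", {
  cfg <- small_config(64)
  a <- generate_phase_scene(cfg, 8, seed = 42)
  b <- generate_phase_scene(cfg, 8, seed = 42)
  expect_identical(a$phase_map, b$phase_map)
  expect_identical(a$cells, b$cells)
  c <- generate_phase_scene(cfg, 8, seed = 43)
  expect_false(identical(a$phase_map, c$phase_map))
})

test_that("scene truth is self-consistent for populated scenes", {
  cfg <- small_config(128)
  for (s in 1:5) {
    sc <- generate_phase_scene(cfg, 20, seed = s)
    dm <- dry_mass_from_phase(mean(sc$phase_map), cfg)
    expect_equal(dm, sc$true_total_dry_mass, tolerance = 1e-9)
  }
})

test_that("impossible cell packing raises an explicit error", {
  cfg <- small_config(64)
  expect_error(
    generate_phase_scene(cfg, n_cells = 500, cell_radius_um = 60,
                         radius_cv = 0, seed = 1),
    class = "holotox_packing_error")
})

test_that("zero-dose evolution scales mass by the control growth factor", {
  cfg <- small_config(64)
  sc0 <- generate_phase_scene(cfg, 6, seed = 3)
  truth <- dose_effect_truth(10, hill = 2, endpoint = "proliferation")
  sc24 <- apply_dose_response_truth(sc0, 0, truth, control_growth = 2.0,
                                    seed = 4)
  expect_equal(sc24$true_total_dry_mass, 2 * sc0$true_total_dry_mass,
               tolerance = 1e-9)
  expect_equal(sc24$timestamp, 24)
})

test_that("dose at true EC50 lands midway between control and floor growth", {
  cfg <- small_config(64)
  sc0 <- generate_phase_scene(cfg, 6, seed = 3)
  truth <- dose_effect_truth(10, hill = 2, top = 1, bottom = 0,
                             endpoint = "proliferation")
  sc24 <- apply_dose_response_truth(sc0, 10, truth, control_growth = 2.0,
                                    floor_growth = 0.4, seed = 4)
  mid <- 0.4 + (2.0 - 0.4) * 0.5
  expect_equal(sc24$true_total_dry_mass, mid * sc0$true_total_dry_mass,
               tolerance = 1e-9)
})

test_that("saturating dose with steep hill gives net mass loss", {
  cfg <- small_config(64)
  sc0 <- generate_phase_scene(cfg, 6, seed = 3)
  truth <- dose_effect_truth(1, hill = 4, endpoint = "proliferation")
  # growth multiplier at 100 x EC50: 0.4 + 1.6/(1 + 100^4) -> about 0.4
  sc24 <- apply_dose_response_truth(sc0, 100, truth, control_growth = 2.0,
                                    floor_growth = 0.4, seed = 4)
  expect_lt(sc24$true_total_dry_mass, sc0$true_total_dry_mass)
  expect_equal(sc24$true_total_dry_mass / sc0$true_total_dry_mass,
               0.4 + 1.6 / (1 + 100^4), tolerance = 1e-6)
})

test_that("monotone truth gives monotone noise-free simulated responses", {
  doses <- c(0, 1, 3, 10, 30, 100)
  tr_dec <- dose_effect_truth(10, hill = 1.5, endpoint = "viability")
  expect_true(all(diff(true_response(tr_dec, doses)) <= 0))
  tr_inc <- dose_effect_truth(10, hill = 1.5, top = 0, bottom = 1,
                              endpoint = "death")
  expect_true(all(diff(true_response(tr_inc, doses)) >= 0))
  # and through the scene generator: per-dose t24 masses decrease
  cfg <- small_config(64)
  sc0 <- generate_phase_scene(cfg, 6, seed = 5)
  m <- vapply(doses, function(d)
    apply_dose_response_truth(sc0, d, tr_dec, seed = 6)$true_total_dry_mass,
    numeric(1))
  expect_true(all(diff(m) <= 1e-9))
})

test_that("truth objects validate their invariants", {
  expect_error(dose_effect_truth(-1), "ec50")
  expect_error(dose_effect_truth(10, top = 0, bottom = 1,
                                 endpoint = "viability"), "top >= bottom")
  expect_error(dose_effect_truth(10, top = 1, bottom = 0,
                                 endpoint = "death"), "increasing")
})
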