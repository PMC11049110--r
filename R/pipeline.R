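#' Configuration for a full multimodal simulated experiment
#'
#' Collects everything one run of [run_multimodal_pipeline()] needs: the
#' imaging model, the dose series and plate design, the per-endpoint
#' ground truths, the analysis parameters, and the experiment seeds (one
#' independent experiment per seed).
#'
#' @param optics An [optical_config()]. The demo default uses a 128 x 128
#'   grid so a full run stays desk-scale; the field of view is unchanged.
#' @param doses Dose series in ug/mL (all > 0).
#' @param truth_proliferation,truth_viability,truth_death
#'   [dose_effect_truth()] objects driving the DHM, WST-8 and LDH branches
#'   of the same simulated populations.
#' @param seeds Integer vector, one per independent experiment.
#' @param n_wells Imaged wells per condition, `n_fovs` fields of view per
#'   well (DHM measurements per condition = `n_wells * n_fovs`).
#' @param n_cells_t0 Cells per field of view at t = 0.
#' @param n_replicates Technical replicates per dose on the absorbance
#'   plates.
#' @param control_growth,floor_growth 24 h dry-mass multipliers of the
#'   medium control and of the saturating-dose floor.
#' @param hologram_noise_spec,plate_noise_spec Noise specifications.
#' @param rolling_ball_radius Radius (px) of the background correction.
#' @param rules [acceptance_rules()] for the fits.
#' @param out_dir Optional directory; when given, result tables and a
#'   provenance record are written there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(optics = optical_config(pixel_count_x = 128,
                                                      pixel_count_y = 128,
                                                      frames_per_stack = 3),
                              doses = c(2, 4, 8, 32, 64, 128, 256, 512),
                              truth_proliferation =
                                dose_effect_truth(9, hill = 1.8,
                                                  endpoint = "proliferation"),
                              truth_viability =
                                dose_effect_truth(22, hill = 1.8,
                                                  endpoint = "viability"),
                              truth_death =
                                dose_effect_truth(60, hill = 1.8,
                                                  top = 0, bottom = 1,
                                                  endpoint = "death"),
                              seeds = c(101L, 202L, 303L),
                              n_wells = 2L, n_fovs = 2L,
                              n_cells_t0 = 30L,
                              n_replicates = 4L,
                              control_growth = 2.0, floor_growth = 0.4,
                              hologram_noise_spec = hologram_noise(),
                              plate_noise_spec = plate_noise(),
                              rolling_ball_radius = 12,
                              rules = acceptance_rules(),
                              out_dir = NULL) {
  if (!length(seeds)) abort("`seeds` must be non-empty in simulation mode.")
  if (any(doses <= 0)) abort("`doses` must be positive.")
  structure(list(optics = optics, doses = doses,
                 truth_proliferation = truth_proliferation,
                 truth_viability = truth_viability,
                 truth_death = truth_death,
                 seeds = as.integer(seeds),
                 n_wells = as.integer(n_wells), n_fovs = as.integer(n_fovs),
                 n_cells_t0 = as.integer(n_cells_t0),
                 n_replicates = as.integer(n_replicates),
                 control_growth = control_growth,
                 floor_growth = floor_growth,
                 hologram_noise_spec = hologram_noise_spec,
                 plate_noise_spec = plate_noise_spec,
                 rolling_ball_radius = rolling_ball_radius,
                 rules = rules, out_dir = out_dir),
            class = "experiment_config")
}

# one DHM measurement: scene -> hologram stack -> reconstruction ->
# rolling ball -> mean phase -> dry mass (pg)
measure_dry_mass <- function(scene, config, noise, radius, seed) {
  stack <- synthesize_hologram_stack(scene, config, noise = noise,
                                     seed = seed)
  qpi <- reconstruct_stack(stack, config,
                           carrier = config$carrier_frequency)
  corr <- subtract_rolling_ball(qpi, radius = radius)
  dry_mass_from_phase(mean_phase_shift(corr$image), config)
}

#' Run the full multimodal cytotoxicity pipeline on simulated data
#'
#' For every experiment seed, simulates the same cell populations through
#' three measurement branches and analyzes each exactly as a laboratory
#' run would be: (1) DHM: phase scenes at t = 0 and t = 24 h per dose,
#' well and field of view are imaged as off-axis hologram stacks,
#' reconstructed, background-corrected and converted to dry-mass
#' increments, then normalized to relative proliferation; (2) WST-8:
#' absorbance plates are simulated from the viability truth and normalized
#' to the medium control; (3) LDH: kinetic plates are simulated from the
#' death truth, slope-fitted over the linear range and normalized between
#' the medium and digitonin controls. Each branch's per-experiment
#' dose-response is fitted with the four-parameter logistic, acceptance
#' rules are applied, and EC50s are summarized across experiments.
#'
#' @param config An [experiment_config()].
#' @param progress Print stage timing messages.
#' @return A list of class `holotox_report`: `ec50_table` (per-assay
#'   summary), `fits` (per assay x experiment tibble with fit columns),
#'   `dhm_records`, `wst8`, `ldh_release`, `stars` (per-dose significance
#'   vs control for each assay, final experiment set pooled), `config`.
#' @export
run_multimodal_pipeline <- function(config = experiment_config(),
                                    progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  optics <- config$optics
  say <- function(...) if (progress) message(sprintf(...))

  dhm_records <- list()
  wst8_all <- list()
  ldh_all <- list()
  fits <- list()

  for (e in seq_along(config$seeds)) {
    seed_e <- config$seeds[e]
    t_start <- Sys.time()
    # conditions: medium control (dose 0) + dose series
    cond <- tibble::tibble(dose = c(0, config$doses))
    recs <- list()
    ctr <- 0L
    for (ci in seq_len(nrow(cond))) {
      dose <- cond$dose[ci]
      noise <- config$hologram_noise_spec
      noise$dose <- dose
      for (w in seq_len(config$n_wells)) {
        for (f in seq_len(config$n_fovs)) {
          ctr <- ctr + 1L
          s0 <- derive_seed(seed_e, ctr * 4L)
          scene0 <- generate_phase_scene(optics, config$n_cells_t0,
                                         seed = s0)
          scene24 <- apply_dose_response_truth(
            scene0, dose, config$truth_proliferation,
            control_growth = config$control_growth,
            floor_growth = config$floor_growth,
            seed = derive_seed(seed_e, ctr * 4L + 1L))
          dm0 <- measure_dry_mass(scene0, optics, noise,
                                  config$rolling_ball_radius,
                                  derive_seed(seed_e, ctr * 4L + 2L))
          dm24 <- measure_dry_mass(scene24, optics, noise,
                                   config$rolling_ball_radius,
                                   derive_seed(seed_e, ctr * 4L + 3L))
          recs[[length(recs) + 1L]] <- tibble::tibble(
            experiment = e, condition = ifelse(dose == 0, "medium", "PACA"),
            concentration = dose, well = w, fov = f,
            dm_t0 = dm0, dm_t24 = dm24,
            dmi = dry_mass_increment(dm0, dm24),
            true_dmi = scene24$true_total_dry_mass -
              scene0$true_total_dry_mass)
        }
      }
    }
    # each dose is its own condition for the normalization reference
    # (max per-condition mean DMI, in practice the medium control)
    dhm <- dplyr::bind_rows(recs)
    cond_label <- dhm$condition
    dhm$condition <- paste0(cond_label, "_", dhm$concentration)
    dhm <- normalize_increments(dhm, group_vars = "experiment")
    dhm$condition <- ifelse(dhm$concentration == 0, "medium", "PACA")
    dhm_records[[e]] <- dhm
    say("experiment %d: DHM branch done (%.1f s)", e,
        as.numeric(difftime(Sys.time(), t_start, units = "secs")))

    # plate branches on the same ground truths
    layout <- plate_layout(config$doses,
                           condition = "PACA",
                           n_replicates = config$n_replicates)
    plates <- simulate_absorbance_plate(
      layout, config$truth_viability, config$truth_death,
      noise = config$plate_noise_spec,
      seed = derive_seed(seed_e, 900000L))
    wst8 <- wst8_viability(plates$wst8) |>
      dplyr::mutate(experiment = e)
    ldh <- ldh_release_percent(ldh_slopes(plates$ldh)) |>
      dplyr::mutate(experiment = e)
    wst8_all[[e]] <- wst8
    ldh_all[[e]] <- ldh

    # per-experiment dose-response fits
    fit_one <- function(df, assay) {
      ft <- tryCatch(fit_dose_response(df), error = function(err) NULL)
      if (is.null(ft)) {
        return(tibble::tibble(assay = assay, experiment = e,
                              condition = "PACA", ec50 = NA_real_,
                              hill = NA_real_, r2 = NA_real_,
                              accepted = FALSE,
                              rejection_reason = "fit_failed"))
      }
      ft <- assess_fit_acceptance(ft, config$rules)
      tibble::tibble(assay = assay, experiment = e, condition = "PACA",
                     ec50 = ft$ec50, hill = ft$hill, r2 = ft$r2,
                     accepted = isTRUE(ft$accepted),
                     rejection_reason = ft$rejection_reason)
    }
    fits[[length(fits) + 1L]] <- fit_one(
      dhm |> dplyr::filter(.data$concentration > 0) |>
        dplyr::transmute(dose = .data$concentration,
                         response = .data$relative_proliferation), "DHM")
    fits[[length(fits) + 1L]] <- fit_one(
      wst8 |> dplyr::filter(.data$role == "sample") |>
        dplyr::transmute(dose = .data$concentration,
                         response = .data$viability_percent), "WST-8")
    fits[[length(fits) + 1L]] <- fit_one(
      ldh |> dplyr::filter(.data$role == "sample") |>
        dplyr::transmute(dose = .data$concentration,
                         response = .data$release_percent), "LDH")
    say("experiment %d complete (%.1f s)", e,
        as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  }

  fits_tbl <- dplyr::bind_rows(fits) |>
    dplyr::mutate(assay = factor(.data$assay, c("DHM", "WST-8", "LDH")))
  ec50_table <- summarize_ec50_across_experiments(fits_tbl,
                                                  by = c("assay", "condition"))

  # per-dose significance vs medium control, pooled over experiments
  dhm_pool <- dplyr::bind_rows(dhm_records)
  stars_dhm <- compare_to_control(
    dhm_pool |> dplyr::transmute(dose = .data$concentration,
                                 response = .data$relative_proliferation))
  wst8_pool <- dplyr::bind_rows(wst8_all)
  stars_wst8 <- compare_to_control(
    wst8_pool |> dplyr::filter(.data$role %in% c("sample", "negative_control")) |>
      dplyr::transmute(dose = .data$concentration,
                       response = .data$viability_percent))
  ldh_pool <- dplyr::bind_rows(ldh_all)
  stars_ldh <- compare_to_control(
    ldh_pool |> dplyr::filter(.data$role %in% c("sample", "negative_control")) |>
      dplyr::transmute(dose = .data$concentration,
                       response = .data$release_percent))
  stars <- dplyr::bind_rows(
    dplyr::mutate(stars_dhm, assay = "DHM"),
    dplyr::mutate(stars_wst8, assay = "WST-8"),
    dplyr::mutate(stars_ldh, assay = "LDH"))

  report <- structure(
    list(ec50_table = ec50_table, fits = fits_tbl,
         dhm_records = dhm_pool, wst8 = wst8_pool, ldh_release = ldh_pool,
         stars = stars, config = config),
    class = "holotox_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.holotox_report <- function(x, ...) {
  cat("<holotox_report>\n")
  cat("EC50 summary (", length(x$config$seeds), "experiments ):\n")
  print(as.data.frame(x$ec50_table))
  invisible(x)
}

#' Write the tables of a pipeline report to disk
#'
#' @param report A `holotox_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "holotox_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$ec50_table, file.path(dir, "ec50_summary.csv"))
  readr::write_csv(report$fits, file.path(dir, "dose_response_fits.csv"))
  readr::write_csv(report$dhm_records, file.path(dir, "dhm_dry_mass.csv"))
  readr::write_csv(report$wst8, file.path(dir, "wst8_viability.csv"))
  readr::write_csv(report$ldh_release, file.path(dir, "ldh_release.csv"))
  readr::write_csv(report$stars, file.path(dir, "significance_stars.csv"))
  prov <- list(
    seeds = report$config$seeds,
    doses = report$config$doses,
    optics = report$config$optics[c("wavelength", "pixel_count_x",
                                    "pixel_count_y", "fov_x", "fov_y",
                                    "carrier_frequency",
                                    "refractive_increment_alpha",
                                    "frames_per_stack")],
    rolling_ball_radius = report$config$rolling_ball_radius)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
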