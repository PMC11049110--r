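#' Noise specification for hologram synthesis
#'
#' @param speckle_sd Standard deviation (radians) of the per-frame smooth
#'   coherence-noise phase field. Each frame of a stack gets an independent
#'   realization, which is what makes stack averaging effective.
#' @param speckle_corr_px Correlation length of the coherence noise in
#'   pixels.
#' @param detector_sd Additive detector noise, as a fraction of the mean
#'   intensity.
#' @param scatter_sd_per_dose Dose-dependent background scatter: standard
#'   deviation (radians) of a smooth static phase background added per unit
#'   log2(1 + dose/scatter_dose_scale). Emulates the loss of optical quality
#'   at high particle concentrations.
#' @param scatter_dose_scale Dose scale (ug/mL) of the scatter term.
#' @param dose Dose (ug/mL) the imaged well received, used only by the
#'   scatter term.
#' @param off If `TRUE`, all noise terms are zeroed.
#' @return A list of class `hologram_noise`.
#' @export
hologram_noise <- function(speckle_sd = 0.08, speckle_corr_px = 8,
                           detector_sd = 0.01,
                           scatter_sd_per_dose = 0.02,
                           scatter_dose_scale = 32,
                           dose = 0, off = FALSE) {
  if (off) {
    speckle_sd <- 0; detector_sd <- 0; scatter_sd_per_dose <- 0
  }
  structure(list(speckle_sd = speckle_sd,
                 speckle_corr_px = speckle_corr_px,
                 detector_sd = detector_sd,
                 scatter_sd_per_dose = scatter_sd_per_dose,
                 scatter_dose_scale = scatter_dose_scale,
                 dose = dose),
            class = "hologram_noise")
}

#' Synthesize an off-axis hologram stack from a phase scene
#'
#' Forward model of off-axis digital holographic microscopy: the object wave
#' `O = exp(i phi)` interferes with a tilted plane reference at the
#' configured carrier frequency, giving intensity frames
#' `I = |O + R|^2`. Each of `config$frames_per_stack` frames carries an
#' independent smooth coherence-noise phase realization plus additive
#' detector noise; an optional dose-dependent static scatter background
#' emulates degraded optical quality at high particle concentrations.
#' Frames are quantized to 16-bit counts.
#'
#' @param scene A `phase_scene` whose dimensions match `config`.
#' @param config An [optical_config()].
#' @param noise A [hologram_noise()] specification.
#' @param defocus_um Optional numeric: propagate the object wave by this
#'   signed distance (micrometres, toward the detector) before interference,
#'   to emulate a defocused acquisition.
#' @param seed Integer seed.
#' @return An object of class `hologram_stack`: list of integer-count
#'   frames plus metadata (`config`, `noise`, `defocus_um`,
#'   `n_saturated_px`).
#' @export
synthesize_hologram_stack <- function(scene, config = scene$config,
                                      noise = hologram_noise(),
                                      defocus_um = 0, seed = NULL) {
  stopifnot(inherits(scene, "phase_scene"), inherits(config, "optical_config"))
  if (!all(dim(scene$phase_map) == c(config$pixel_count_y,
                                     config$pixel_count_x))) {
    abort("scene dimensions do not match the optical configuration.")
  }
  fc <- config$carrier_frequency
  n_min <- min(config$pixel_count_x, config$pixel_count_y)
  if (sqrt(sum(fc^2)) <= 2 / n_min) {
    abort("carrier frequency too close to DC: sidebands would overlap.",
          class = "holotox_carrier_error")
  }

  nr <- config$pixel_count_y
  nc <- config$pixel_count_x
  ramp <- outer((seq_len(nr) - 1) * fc[2], (seq_len(nc) - 1) * fc[1], `+`)
  Rwave <- exp(2i * pi * ramp)

  with_seed(seed, {
    scatter_sd <- noise$scatter_sd_per_dose *
      log2(1 + noise$dose / noise$scatter_dose_scale)
    scatter <- if (scatter_sd > 0) {
      smooth_noise_field(nr, nc, noise$speckle_corr_px) * scatter_sd
    } else 0

    frames <- vector("list", config$frames_per_stack)
    n_sat <- 0L
    for (k in seq_len(config$frames_per_stack)) {
      psi <- if (noise$speckle_sd > 0) {
        smooth_noise_field(nr, nc, noise$speckle_corr_px) * noise$speckle_sd
      } else 0
      O <- exp(1i * (scene$phase_map + scatter + psi))
      if (defocus_um != 0) {
        O <- propagate_angular_spectrum(O, defocus_um, config$wavelength_um,
                                        config$pixel_pitch_x,
                                        config$pixel_pitch_y)
      }
      I <- Mod(O + Rwave)^2
      if (noise$detector_sd > 0) {
        I <- I + rnorm(length(I), sd = noise$detector_sd * mean(I))
      }
      counts <- round(I / 4.2 * 65535)
      n_sat <- n_sat + sum(counts > 65535 | counts < 0)
      counts <- pmin(pmax(counts, 0), 65535)
      frames[[k]] <- matrix(counts, nr, nc)
    }
    structure(list(frames = frames, config = config, noise = noise,
                   defocus_um = defocus_um, n_saturated_px = n_sat,
                   scene_true_dry_mass = scene$true_total_dry_mass),
              class = "hologram_stack")
  })
}

#' @export
print.hologram_stack <- function(x, ...) {
  cat("<hologram_stack>", length(x$frames), "frames,",
      nrow(x$frames[[1]]), "x", ncol(x$frames[[1]]), "px\n")
  invisible(x)
}
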