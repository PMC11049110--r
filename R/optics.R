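#' Optical configuration for the DHM imaging model
#'
#' Bundles the physical constants that relate off-axis holograms, phase maps
#' and dry mass: laser wavelength, field-of-view geometry, the spatial
#' carrier frequency of the off-axis reference wave, the refractive index
#' increment relating phase to protein content, and the number of hologram
#' frames recorded per field of view.
#'
#' @param wavelength Laser wavelength in metres (default 532 nm).
#' @param pixel_count_x,pixel_count_y Sensor size in pixels.
#' @param fov_x,fov_y Field of view in micrometres. The defaults correspond
#'   to a 405 um x 538 um field imaged with a 20x objective; pixel pitch may
#'   therefore be anisotropic.
#' @param carrier_frequency Length-2 numeric, carrier frequency of the
#'   off-axis fringes in cycles/pixel along (x, y); each component must lie
#'   strictly inside (-0.5, 0.5) and the magnitude must be positive.
#' @param refractive_increment_alpha Refractive index increment alpha in
#'   mL/g (numerically equal to um^3/pg). Default 0.19 mL/g, the standard
#'   value for cellular protein.
#' @param frames_per_stack Hologram frames recorded per field of view and
#'   time point; frames are averaged after reconstruction to suppress
#'   coherence noise. Default 10.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(pixel_count_x = 256, pixel_count_y = 256)
#' cfg$pixel_area # um^2 per pixel
#' @export
optical_config <- function(wavelength = 532e-9,
                           pixel_count_x = 512L,
                           pixel_count_y = 512L,
                           fov_x = 405,
                           fov_y = 538,
                           carrier_frequency = c(0.30, 0.20),
                           refractive_increment_alpha = 0.19,
                           frames_per_stack = 10L) {
  stopifnot_scalar_number(wavelength, "wavelength", positive = TRUE)
  stopifnot_scalar_number(fov_x, "fov_x", positive = TRUE)
  stopifnot_scalar_number(fov_y, "fov_y", positive = TRUE)
  stopifnot_scalar_number(refractive_increment_alpha,
                          "refractive_increment_alpha", positive = TRUE)
  if (length(carrier_frequency) != 2L || !all(is.finite(carrier_frequency))) {
    abort("`carrier_frequency` must be two finite numbers (cycles/pixel).")
  }
  if (any(abs(carrier_frequency) >= 0.5) || all(carrier_frequency == 0)) {
    abort("`carrier_frequency` components must lie in (-0.5, 0.5) and not both be zero.")
  }
  pixel_count_x <- as.integer(pixel_count_x)
  pixel_count_y <- as.integer(pixel_count_y)
  if (pixel_count_x < 8L || pixel_count_y < 8L) {
    abort("pixel counts must be at least 8.")
  }
  frames_per_stack <- as.integer(frames_per_stack)
  if (frames_per_stack < 1L) abort("`frames_per_stack` must be >= 1.")

  pitch_x <- fov_x / pixel_count_x
  pitch_y <- fov_y / pixel_count_y
  structure(
    list(
      wavelength = wavelength,
      wavelength_um = wavelength * 1e6,
      pixel_count_x = pixel_count_x,
      pixel_count_y = pixel_count_y,
      fov_x = fov_x,
      fov_y = fov_y,
      pixel_pitch_x = pitch_x,
      pixel_pitch_y = pitch_y,
      pixel_area = pitch_x * pitch_y,
      carrier_frequency = as.numeric(carrier_frequency),
      refractive_increment_alpha = refractive_increment_alpha,
      frames_per_stack = frames_per_stack
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength      : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  grid            : %d x %d px over %.0f x %.0f um\n",
              x$pixel_count_x, x$pixel_count_y, x$fov_x, x$fov_y))
  cat(sprintf("  pixel pitch     : %.3f x %.3f um\n",
              x$pixel_pitch_x, x$pixel_pitch_y))
  cat(sprintf("  carrier         : (%.3f, %.3f) cycles/px\n",
              x$carrier_frequency[1], x$carrier_frequency[2]))
  cat(sprintf("  alpha           : %.3f mL/g\n", x$refractive_increment_alpha))
  cat(sprintf("  frames per stack: %d\n", x$frames_per_stack))
  invisible(x)
}
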