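#' Locate the off-axis carrier frequency in a hologram spectrum
#'
#' Finds the spectral peak of maximal magnitude outside a DC exclusion
#' disk, restricted to the positive-fx half-plane (the Hermitian spectrum
#' of a real hologram carries the conjugate sideband at -f), then refines
#' it to sub-bin precision by maximizing the continuous windowed-DTFT
#' magnitude around the peak (a 3x3 centroid alone leaves a few 1e-4
#' cycles/pixel of bias from spectral leakage, which downstream shows up
#' as an uncorrected phase tilt).
#'
#' @param hologram A real-valued matrix (one hologram frame) or a
#'   `hologram_stack` (its first frame is used).
#' @param dc_exclusion_radius Radius (cycles/pixel) of the excluded DC disk.
#' @param prominence Minimum ratio of the peak magnitude over the median
#'   magnitude of the searched region; below it a
#'   `holotox_no_sideband` error is raised.
#' @return Numeric length-2 vector `c(fx, fy)` in cycles/pixel.
#' @export
locate_carrier <- function(hologram, dc_exclusion_radius = 0.05,
                           prominence = 10) {
  h <- if (inherits(hologram, "hologram_stack")) hologram$frames[[1]] else hologram
  if (!is.matrix(h) || !is.numeric(h)) abort("hologram must be a numeric matrix.")
  nr <- nrow(h); nc <- ncol(h)
  Fm <- Mod(fft(h - mean(h)))
  fx <- fft_freq(nc)   # per column
  fy <- fft_freq(nr)   # per row
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  sel <- (FX^2 + FY^2) > dc_exclusion_radius^2 &
    (FX > 0 | (FX == 0 & FY > 0))
  vals <- Fm[sel]
  if (!length(vals) || max(vals) < prominence * (median(vals) + 1e-300)) {
    abort("no sideband found: no spectral peak with sufficient prominence outside DC.",
          class = "holotox_no_sideband")
  }
  Fsearch <- Fm
  Fsearch[!sel] <- 0
  k <- arrayInd(which.max(Fsearch), dim(Fm))
  i0 <- k[1]; j0 <- k[2]
  wrap_half <- function(f) ifelse(f >= 0.5, f - 1, ifelse(f < -0.5, f + 1, f))
  f0 <- c(wrap_half((j0 - 1) / nc), wrap_half((i0 - 1) / nr))
  # refine on the continuous spectrum: Hann window suppresses leakage from
  # the DC term and the conjugate sideband
  win <- outer(0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / nr),
               0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / nc))
  hw <- (h - mean(h)) * win
  xs <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr) - 1, nr, nc)
  dtft_mag <- function(f) {
    -Mod(sum(hw * exp(-2i * pi * (f[1] * xs + f[2] * ys))))
  }
  opt <- stats::optim(f0, dtft_mag, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 200))
  est <- opt$par
  if (sqrt(sum((est - f0)^2)) > 2 / min(nr, nc)) est <- f0  # stay local
  est
}

# raised-cosine low-pass mask centred on DC, radius in cycles/pixel
soft_circular_mask <- function(nr, nc, radius, taper_frac = 0.3) {
  fx <- fft_freq(nc); fy <- fft_freq(nr)
  rho <- sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
  r0 <- radius * (1 - taper_frac)
  m <- matrix(0, nr, nc)
  m[rho <= r0] <- 1
  tz <- rho > r0 & rho < radius
  m[tz] <- 0.5 * (1 + cos(pi * (rho[tz] - r0) / (radius - r0)))
  m
}

#' Demodulate an off-axis hologram to a complex object field
#'
#' Shifts the sideband at the given carrier to DC by multiplying the
#' hologram with the conjugate reference wave, isolates it with a
#' soft-edged (raised-cosine) circular spectral mask, and inverse
#' transforms to the complex object field. Residual tilt and the piston
#' offset are removed using cell-free pixels.
#'
#' @param hologram Real-valued hologram matrix.
#' @param carrier Length-2 carrier frequency `c(fx, fy)` (cycles/pixel).
#' @param config An [optical_config()] supplying wavelength and pixel pitch
#'   for the returned field.
#' @param filter_radius Spectral mask radius in cycles/pixel; default
#'   `0.45 * |carrier|`. Must be smaller than `|carrier|` so the mask
#'   cannot overlap the DC term.
#' @param flatten Remove residual tilt/offset estimated from cell-free
#'   pixels (default `TRUE`).
#' @return A list of class `complex_field`: `values` (complex matrix),
#'   `wrapped_phase` (radians in (-pi, pi]), `pixel_pitch`, `wavelength_um`,
#'   `focus_offset_um`.
#' @export
demodulate_to_phase <- function(hologram, carrier, config,
                                filter_radius = NULL, flatten = TRUE) {
  h <- if (inherits(hologram, "hologram_stack")) hologram$frames[[1]] else hologram
  stopifnot(is.matrix(h), inherits(config, "optical_config"))
  cmag <- sqrt(sum(carrier^2))
  if (is.null(filter_radius)) filter_radius <- 0.45 * cmag
  if (filter_radius >= cmag) {
    abort("filter_radius must be smaller than |carrier|: the mask would overlap DC.",
          class = "holotox_filter_overlap")
  }
  nr <- nrow(h); nc <- ncol(h)
  # the object term O * conj(R) of |O + R|^2 sits at -carrier for a
  # reference tilted to +carrier; shifting the spectrum by +carrier brings
  # it to DC (the mirror sideband at +carrier holds conj(O))
  ramp <- outer((seq_len(nr) - 1) * carrier[2], (seq_len(nc) - 1) * carrier[1], `+`)
  demod <- (h - mean(h)) * exp(2i * pi * ramp)
  Fd <- fft(demod) * soft_circular_mask(nr, nc, filter_radius)
  U <- fft(Fd, inverse = TRUE) / (nr * nc)
  if (flatten) U <- flatten_field(U)
  structure(
    list(values = U,
         wrapped_phase = Arg(U),
         pixel_pitch = c(config$pixel_pitch_x, config$pixel_pitch_y),
         wavelength_um = config$wavelength_um,
         focus_offset_um = 0),
    class = "complex_field"
  )
}

# remove residual linear tilt (phase-gradient average) and piston offset
# (circular mean over cell-free pixels) from a complex field
flatten_field <- function(U) {
  nr <- nrow(U); nc <- ncol(U)
  gx <- Arg(sum(U[, -1] * Conj(U[, -nc])))
  gy <- Arg(sum(U[-1, ] * Conj(U[-nr, ])))
  ramp <- outer((seq_len(nr) - 1) * gy, (seq_len(nc) - 1) * gx, `+`)
  U <- U * exp(-1i * ramp)
  mask <- background_mask(Arg(U))
  off <- Arg(sum(U[mask]))
  U * exp(-1i * off)
}

#' Unwrap a 2D wrapped phase map
#'
#' Quality-guided (reliability-sorted) two-dimensional phase unwrapping:
#' pixels are joined across the most reliable gradients first, so noisy
#' regions cannot propagate 2*pi errors into clean ones. On wrap-free input
#' the map is returned unchanged (up to a global multiple of 2*pi).
#'
#' @param wrapped Matrix of wrapped phase values in (-pi, pi].
#' @return Matrix of unwrapped phase (radians).
#' @export
unwrap_phase <- function(wrapped) {
  if (!is.matrix(wrapped) || !is.numeric(wrapped)) {
    abort("`wrapped` must be a numeric matrix.")
  }
  if (any(!is.finite(wrapped))) abort("`wrapped` must be finite.")
  .unwrap2d(wrapped)
}

# angular-spectrum (convolution) propagation of a sampled complex field
propagate_angular_spectrum <- function(values, dz_um, wavelength_um,
                                       pitch_x, pitch_y) {
  if (dz_um == 0) return(values)
  nr <- nrow(values); nc <- ncol(values)
  fx <- fft_freq(nc) / pitch_x    # cycles/um
  fy <- fft_freq(nr) / pitch_y
  arg <- 1 / wavelength_um^2 - outer(rep(1, nr), fx^2) - outer(fy^2, rep(1, nc))
  H <- matrix(0i, nr, nc)
  prop <- arg > 0
  H[prop] <- exp(2i * pi * dz_um * sqrt(arg[prop]))
  fft(fft(values) * H, inverse = TRUE) / (nr * nc)
}

#' Propagate a complex field by a signed distance
#'
#' @param field A `complex_field`.
#' @param dz_um Signed propagation distance in micrometres (positive toward
#'   the detector). `dz_um = 0` is the identity.
#' @return The propagated `complex_field` with `focus_offset_um` updated.
#' @export
propagate_field <- function(field, dz_um) {
  stopifnot(inherits(field, "complex_field"))
  out <- field
  out$values <- propagate_angular_spectrum(field$values, dz_um,
                                           field$wavelength_um,
                                           field$pixel_pitch[1],
                                           field$pixel_pitch[2])
  out$wrapped_phase <- Arg(out$values)
  out$focus_offset_um <- field$focus_offset_um + dz_um
  out
}

# Tamura coefficient of the amplitude: sd/mean, optionally over a mask
tamura_coefficient <- function(amplitude, mask = NULL) {
  a <- if (is.null(mask)) amplitude else amplitude[mask]
  m <- mean(a)
  if (m <= 0) return(Inf)
  stats::sd(a) / m
}

#' Autofocus a complex field by angular-spectrum refocusing
#'
#' Propagates the field over a grid of candidate distances and scores each
#' candidate on the amplitude image. The default criterion is the negative
#' Tamura coefficient (normalized amplitude standard deviation) evaluated
#' over cell-free pixels: for phase-dominant specimens such as adherent
#' cells, amplitude contrast is minimal in focus, so the score is maximal
#' at the focal plane; restricting the statistic to the background
#' suppresses the bias that spectral-truncation ringing at cell edges
#' otherwise introduces.
#'
#' @param field A `complex_field`.
#' @param search_range Length-2 numeric, distance interval in micrometres.
#' @param steps Number of equally spaced candidate distances (>= 3).
#' @param criterion `"neg_tamura"` (default, minimal amplitude contrast
#'   over cell-free pixels), `"neg_tamura_full"` (minimal full-field
#'   amplitude contrast) or `"tamura"` (maximal full-field amplitude
#'   contrast, for amplitude specimens).
#' @return A list: `field` (refocused `complex_field`), `distance_um`
#'   (chosen distance), `scores` (tibble of distance and score), and
#'   `tie_flag` (`TRUE` when several maxima tied and the smallest
#'   `|distance|` was returned).
#' @export
refocus_autofocus <- function(field, search_range = c(-100, 100),
                              steps = 41L,
                              criterion = c("neg_tamura", "neg_tamura_full",
                                            "tamura")) {
  stopifnot(inherits(field, "complex_field"))
  criterion <- match.arg(criterion)
  steps <- as.integer(steps)
  if (steps < 3L) abort("`steps` must be >= 3.")
  if (length(search_range) != 2L || !all(is.finite(search_range))) {
    abort("`search_range` must be a finite length-2 interval.")
  }
  zs <- seq(search_range[1], search_range[2], length.out = steps)
  score <- vapply(zs, function(z) {
    U <- propagate_angular_spectrum(field$values, z,
                                    field$wavelength_um,
                                    field$pixel_pitch[1],
                                    field$pixel_pitch[2])
    amp <- Mod(U)
    switch(criterion,
           neg_tamura = -tamura_coefficient(
             amp, background_mask(Arg(U), frac = 0.4)),
           neg_tamura_full = -tamura_coefficient(amp),
           tamura = tamura_coefficient(amp))
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)
  tie_flag <- length(best) > 1L
  pick <- best[which.min(abs(zs[best]))]
  out_field <- propagate_field(field, zs[pick])
  list(field = out_field, distance_um = zs[pick],
       scores = tibble::tibble(distance_um = zs, score = score),
       tie_flag = tie_flag)
}

#' Average a stack of unwrapped phase maps into a QPI image
#'
#' Removes a per-frame piston offset (median over cell-free pixels, which
#' absorbs both ETL-induced phase drift and global 2*pi ambiguities of the
#' unwrapping) and averages pixel-wise.
#'
#' @param phases A list of unwrapped phase matrices with common geometry.
#' @param pixel_area Pixel area in um^2 recorded in the result.
#' @param mask Optional logical matrix of cell-free pixels; estimated from
#'   the first frame when `NULL`.
#' @param provenance Optional list stored in the result.
#' @return An object of class `qpi_image` with elements `phase`,
#'   `pixel_area`, `n_frames_averaged`, `provenance`.
#' @export
average_phase_stack <- function(phases, pixel_area = NA_real_, mask = NULL,
                                provenance = list()) {
  if (!is.list(phases) || length(phases) == 0L) {
    abort("`phases` must be a non-empty list of phase matrices.")
  }
  d <- dim(phases[[1]])
  if (!all(vapply(phases, function(p) identical(dim(p), d), logical(1)))) {
    abort("all frames must share the same geometry.")
  }
  if (is.null(mask)) mask <- background_mask(phases[[1]])
  acc <- matrix(0, d[1], d[2])
  for (p in phases) acc <- acc + (p - median(p[mask]))
  qpi_image(acc / length(phases), pixel_area,
            n_frames_averaged = length(phases), provenance = provenance)
}

#' Construct a QPI image object
#'
#' @param phase Unwrapped, averaged phase matrix (radians).
#' @param pixel_area Pixel area (um^2).
#' @param n_frames_averaged Number of hologram frames behind the image.
#' @param provenance Free-form list of reconstruction parameters.
#' @return Object of class `qpi_image`.
#' @export
qpi_image <- function(phase, pixel_area = NA_real_,
                      n_frames_averaged = 1L, provenance = list()) {
  stopifnot(is.matrix(phase))
  if (any(!is.finite(phase))) abort("phase must be finite.")
  structure(list(phase = phase, pixel_area = pixel_area,
                 n_frames_averaged = as.integer(n_frames_averaged),
                 provenance = provenance),
            class = "qpi_image")
}

#' @export
print.qpi_image <- function(x, ...) {
  cat("<qpi_image>", nrow(x$phase), "x", ncol(x$phase), "px,",
      x$n_frames_averaged, "frames averaged, mean phase",
      sprintf("%.4f rad\n", mean(x$phase)))
  invisible(x)
}

#' Reconstruct a QPI image from an off-axis hologram stack
#'
#' Full reconstruction chain: carrier location on the first frame, sideband
#' demodulation and quality-guided unwrapping of every frame, optional
#' autofocus (distance estimated once and applied to all frames), and
#' offset-corrected stack averaging.
#'
#' @param stack A `hologram_stack`.
#' @param config Optical configuration; defaults to the stack's.
#' @param carrier Known carrier frequency, or `NULL` to estimate it.
#' @param filter_radius Passed to [demodulate_to_phase()].
#' @param autofocus If `TRUE`, run [refocus_autofocus()] on the first frame
#'   and propagate all frames by the chosen distance.
#' @param search_range,steps Autofocus parameters.
#' @return A `qpi_image`.
#' @export
reconstruct_stack <- function(stack, config = stack$config, carrier = NULL,
                              filter_radius = NULL, autofocus = FALSE,
                              search_range = c(-100, 100), steps = 41L) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (is.null(carrier)) carrier <- locate_carrier(stack$frames[[1]])
  dz <- 0
  if (autofocus) {
    f1 <- demodulate_to_phase(stack$frames[[1]], carrier, config,
                              filter_radius = filter_radius)
    af <- refocus_autofocus(f1, search_range = search_range, steps = steps)
    dz <- af$distance_um
  }
  phases <- lapply(stack$frames, function(h) {
    fld <- demodulate_to_phase(h, carrier, config,
                               filter_radius = filter_radius)
    if (dz != 0) fld <- propagate_field(fld, dz)
    unwrap_phase(fld$wrapped_phase)
  })
  average_phase_stack(phases, pixel_area = config$pixel_area,
                      provenance = list(carrier = carrier,
                                        filter_radius = filter_radius,
                                        refocus_um = dz,
                                        n_frames = length(stack$frames)))
}
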