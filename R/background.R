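#' Spherical-cap (rolling ball) structuring element
#'
#' Builds the non-flat structuring element used by
#' [subtract_rolling_ball()]: the cap of a sphere whose 3D radius is chosen
#' so the cap spans a patch of the given pixel radius with the given height
#' in image units (radians for phase maps). Samples outside the patch are
#' `NA`.
#'
#' @param radius Patch radius in pixels (>= 1).
#' @param height Cap height in image units; default `radius / 100`.
#' @return A `(2*floor(radius)+1)` square matrix of heights with `NA`
#'   outside the circular support; the centre has the maximal height.
#' @export
ball_element <- function(radius, height = radius / 100) {
  stopifnot_scalar_number(radius, "radius", positive = TRUE)
  if (radius < 1) abort("`radius` must be >= 1.")
  stopifnot_scalar_number(height, "height", positive = TRUE)
  r <- radius
  Rb <- (r^2 + height^2) / (2 * height)   # 3D ball radius from cap geometry
  k <- floor(r)
  off <- -k:k
  rho2 <- outer(off^2, off^2, `+`)
  se <- sqrt(pmax(Rb^2 - rho2, 0)) - sqrt(Rb^2 - r^2)
  se[rho2 > r^2] <- NA_real_
  se
}

#' Rolling-ball background subtraction of a phase image
#'
#' Estimates the slowly varying phase background as the grayscale opening
#' (non-flat erosion followed by dilation) of the image with a ball
#' (spherical cap) structuring element, and subtracts it. Narrow, tall
#' features such as cells cannot be entered by the ball and survive;
#' smooth background tilt and curvature are removed. The opening is exact
#' (no shrink/scale approximation) and idempotent.
#'
#' @param phase A `qpi_image` or a numeric phase matrix.
#' @param radius Ball patch radius in pixels.
#' @param height Ball cap height in radians; default `radius / 100`.
#' @return A list with elements `image` (corrected, same type as the
#'   input) and `background` (a list of class `background_model` with the
#'   `method`, `radius` and `background_map`).
#' @examples
#' img <- matrix(0.01 * row(matrix(0, 32, 32)), 32, 32)
#' out <- subtract_rolling_ball(img, radius = 5)
#' max(abs(out$image)) < 1e-10 # a plane is background
#' @export
subtract_rolling_ball <- function(phase, radius = 50, height = radius / 100) {
  is_qpi <- inherits(phase, "qpi_image")
  img <- if (is_qpi) phase$phase else phase
  stopifnot(is.matrix(img), is.numeric(img))
  k <- 2 * floor(radius) + 1
  if (k > min(dim(img))) {
    abort("`radius` is larger than the image allows.",
          class = "holotox_radius_error")
  }
  se <- ball_element(radius, height)
  bg <- .nf_dilate(.nf_erode(img, se), se)
  corrected <- img - bg
  model <- structure(list(method = "rolling_ball", radius = radius,
                          height = height, background_map = bg),
                     class = "background_model")
  out <- if (is_qpi) {
    q <- phase
    q$phase <- corrected
    q$provenance$background <- list(method = "rolling_ball", radius = radius,
                                    height = height)
    q
  } else corrected
  list(image = out, background = model)
}

#' Mean phase shift of a corrected QPI image
#'
#' The population mean phase shift is the arithmetic mean of the corrected
#' phase over the full field of view (cells and background alike), which is
#' the quantity the dry-mass relation multiplies by the field-of-view area.
#'
#' @param corrected A `qpi_image` or numeric phase matrix.
#' @return Mean phase shift in radians.
#' @export
mean_phase_shift <- function(corrected) {
  img <- if (inherits(corrected, "qpi_image")) corrected$phase else corrected
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(!is.finite(img))) abort("phase image must be finite.")
  mean(img)
}
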