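#' Write a hologram stack as multi-page 16-bit TIFF with JSON sidecar
#'
#' @param stack A `hologram_stack`.
#' @param path Path of the `.tif` file; the sidecar metadata is written
#'   next to it as `<path>.json`.
#' @return `path`, invisibly. A warning reports any saturated pixels.
#' @export
write_hologram_stack <- function(stack, path) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (stack$n_saturated_px > 0) {
    warn(sprintf("hologram stack contains %d saturated pixel value(s).",
                 stack$n_saturated_px))
  }
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 65535),
                  path, bits.per.sample = 16L)
  cfg <- stack$config
  meta <- list(
    wavelength = cfg$wavelength,
    pixel_count_x = cfg$pixel_count_x, pixel_count_y = cfg$pixel_count_y,
    fov_x = cfg$fov_x, fov_y = cfg$fov_y,
    carrier_frequency = cfg$carrier_frequency,
    refractive_increment_alpha = cfg$refractive_increment_alpha,
    frames_per_stack = length(stack$frames),
    defocus_um = stack$defocus_um,
    n_saturated_px = stack$n_saturated_px,
    scene_true_dry_mass = stack$scene_true_dry_mass)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a hologram stack written by [write_hologram_stack()]
#'
#' @param path Path of the `.tif` file (sidecar `<path>.json` must exist).
#' @return A `hologram_stack`.
#' @export
read_hologram_stack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    abort("hologram stack or its sidecar metadata not found.",
          class = "holotox_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) round(p * 65535))
  cfg <- optical_config(
    wavelength = meta$wavelength,
    pixel_count_x = meta$pixel_count_x, pixel_count_y = meta$pixel_count_y,
    fov_x = meta$fov_x, fov_y = meta$fov_y,
    carrier_frequency = meta$carrier_frequency,
    refractive_increment_alpha = meta$refractive_increment_alpha,
    frames_per_stack = meta$frames_per_stack)
  structure(list(frames = frames, config = cfg,
                 noise = NULL, defocus_um = meta$defocus_um %||% 0,
                 n_saturated_px = meta$n_saturated_px %||% 0L,
                 scene_true_dry_mass = meta$scene_true_dry_mass),
            class = "hologram_stack")
}

#' Write a QPI phase image as 32-bit float TIFF plus provenance JSON
#'
#' @param qpi A `qpi_image`.
#' @param path Path of the `.tif` file.
#' @return `path`, invisibly.
#' @export
write_phase_tiff <- function(qpi, path) {
  stopifnot(inherits(qpi, "qpi_image"))
  # TIFF samples live in [0, 1]; an affine map recorded in the sidecar
  # makes the radian values recoverable (32-bit float keeps full precision)
  lo <- min(qpi$phase)
  span <- max(qpi$phase) - lo
  if (span == 0) span <- 1
  tiff::writeTIFF((qpi$phase - lo) / span, path, bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(pixel_area = qpi$pixel_area,
               n_frames_averaged = qpi$n_frames_averaged,
               phase_offset = lo, phase_span = span,
               provenance = qpi$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a QPI phase image written by [write_phase_tiff()]
#'
#' @param path Path of the `.tif` file.
#' @return A `qpi_image`.
#' @export
read_phase_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    abort("phase image or its sidecar metadata not found.",
          class = "holotox_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  phase <- tiff::readTIFF(path)
  phase <- phase * (meta$phase_span %||% 1) + (meta$phase_offset %||% 0)
  qpi_image(phase, pixel_area = meta$pixel_area %||% NA_real_,
            n_frames_averaged = meta$n_frames_averaged %||% 1L,
            provenance = as.list(meta$provenance))
}

#' Write / read plate-reader tables
#'
#' WST-8 tables are wide (one row per well), LDH tables long (one row per
#' well and minute). Reading validates the schema and the control roles
#' and addresses errors to the offending column or rule.
#'
#' @param tbl Tibble to write.
#' @param path CSV path.
#' @return `path` (writers, invisibly) or the validated tibble (readers).
#' @name plate_io
NULL

#' @rdname plate_io
#' @export
write_wst8_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_wst8_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well_id", "role", "od450", "od620")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("WST-8 table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "holotox_io_error")
  }
  tbl
}

#' @rdname plate_io
#' @export
write_ldh_csv <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_ldh_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("well_id", "role", "minute", "od492")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("LDH table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "holotox_io_error")
  }
  # time stamps must be strictly increasing in file order within each well
  bad <- tbl |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(ok = all(diff(.data$minute) > 0), .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste0("non-monotone time stamps in well(s): ",
                 paste(bad$well_id[!bad$ok], collapse = ", ")),
          class = "holotox_io_error")
  }
  tbl
}

#' Read a plate layout from CSV or YAML
#'
#' The CSV dialect has columns `well_id, role, condition, concentration,
#' replicate`; the YAML dialect is a list of the same records. The layout
#' is validated (well-formed ids, required control roles, non-negative
#' concentrations).
#'
#' @param path File path ending in `.csv`, `.yml` or `.yaml`.
#' @param require_positive Require a positive control (LDH use).
#' @return A validated layout tibble.
#' @export
read_plate_layout <- function(path, require_positive = TRUE) {
  if (grepl("[.]csv$", path)) {
    layout <- readr::read_csv(path, show_col_types = FALSE)
  } else if (grepl("[.]ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
    layout <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    abort("layout file must be .csv or .yaml.", class = "holotox_io_error")
  }
  validate_plate_layout(layout, require_positive = require_positive)
  tibble::as_tibble(layout)
}
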