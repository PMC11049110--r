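#' Convert mean phase shift to population dry mass
#'
#' Applies the standard QPI dry-mass relation
#' `dm = lambda / (2 * pi * alpha) * mean_phase * S_FOV`,
#' with `lambda` the laser wavelength, `alpha` the refractive index
#' increment and `S_FOV` the field-of-view area, resolving units to
#' picograms (`lambda` in um, `alpha` in um^3/pg = mL/g, areas in um^2).
#'
#' @param mean_phase Mean phase shift(s) in radians; vectorized.
#' @param config An [optical_config()].
#' @return Dry mass in picograms (may be negative for negative phase).
#' @examples
#' cfg <- optical_config()
#' dry_mass_from_phase(1, cfg) # pg per 1 rad mean phase over the FOV
#' @export
dry_mass_from_phase <- function(mean_phase, config) {
  stopifnot(inherits(config, "optical_config"))
  if (!is.numeric(mean_phase) || any(!is.finite(mean_phase))) {
    abort("`mean_phase` must be finite.")
  }
  s_fov <- config$fov_x * config$fov_y
  config$wavelength_um / (2 * pi * config$refractive_increment_alpha) *
    mean_phase * s_fov
}

#' Dry mass increment over the observation interval
#'
#' @param dm_t0,dm_t24 Population dry mass (pg) at measurement start and
#'   after 24 h; vectorized. Negative increments (net mass loss through
#'   death and detachment) are permitted.
#' @return `dm_t24 - dm_t0` in pg.
#' @export
dry_mass_increment <- function(dm_t0, dm_t24) {
  if (any(!is.finite(dm_t0)) || any(!is.finite(dm_t24))) {
    abort("dry masses must be finite.")
  }
  dm_t24 - dm_t0
}

#' Normalize dry-mass increments to relative proliferation
#'
#' Within each group (by default each `cell_line` x `experiment`
#' combination present in the data), expresses each record's DMI as a
#' percentage of the group's reference DMI. The default reference is the
#' maximum per-condition mean DMI (in practice the medium control), so the
#' best-growing condition maps to 100%; negative DMIs give negative
#' percentages.
#'
#' @param records A tibble with at least a `dmi` column; typically also
#'   `condition`, `cell_line`, `experiment`.
#' @param group_vars Character vector of grouping columns; columns absent
#'   from the data are ignored.
#' @param reference `"max_mean"` (default; maximum of per-`condition` mean
#'   DMI, falling back to `"max"` when there is no condition column) or
#'   `"max"` (maximum single DMI in the group).
#' @return The records with columns `relative_proliferation` (percent) and
#'   `no_growth_reference` (TRUE when the group's reference was <= 0, in
#'   which case the percentage is `NA`).
#' @export
normalize_increments <- function(records,
                                 group_vars = c("cell_line", "experiment"),
                                 reference = c("max_mean", "max")) {
  reference <- match.arg(reference)
  if (!"dmi" %in% names(records)) abort("`records` needs a `dmi` column.")
  gv <- intersect(group_vars, names(records))
  use_mean <- reference == "max_mean" && "condition" %in% names(records)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gv))) |>
    dplyr::group_modify(function(df, key) {
      ref <- if (use_mean) {
        max(tapply(df$dmi, df$condition, mean))
      } else {
        max(df$dmi)
      }
      if (!is.finite(ref) || ref <= 0) {
        df$relative_proliferation <- NA_real_
        df$no_growth_reference <- TRUE
      } else {
        df$relative_proliferation <- 100 * df$dmi / ref
        df$no_growth_reference <- FALSE
      }
      df
    }) |>
    dplyr::ungroup()
}
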