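#' Construct a 96-well style plate layout
#'
#' Builds the well table used by the plate simulator and the assay
#' normalizations: per-dose sample wells plus background wells (medium
#' without cells), negative controls (untreated cells) and positive
#' controls (digitonin-lysed cells, required for LDH normalization).
#'
#' @param doses Numeric vector of sample doses (ug/mL), all > 0 (the
#'   untreated condition is the negative control, not a dose-0 sample).
#' @param condition Condition label for the sample wells (e.g. particle
#'   type and cell line).
#' @param n_replicates Technical replicates per dose (default 4).
#' @param n_background,n_negative,n_positive Numbers of control wells.
#' @param positive_dose Concentration recorded for the digitonin positive
#'   control (ug/mL, default 75).
#' @return A tibble with columns `well_id`, `role`, `condition`,
#'   `concentration`, `replicate`.
#' @export
plate_layout <- function(doses, condition = "sample",
                         n_replicates = 4L,
                         n_background = 4L, n_negative = 4L,
                         n_positive = 4L, positive_dose = 75) {
  if (length(doses) && any(doses <= 0)) {
    abort("`doses` must all be > 0; the untreated condition is the negative control.")
  }
  rows <- list(
    tibble::tibble(role = "background", condition = "background",
                   concentration = 0,
                   replicate = seq_len(n_background)),
    tibble::tibble(role = "negative_control", condition = "medium",
                   concentration = 0,
                   replicate = seq_len(n_negative)),
    tibble::tibble(role = "positive_control", condition = "digitonin",
                   concentration = positive_dose,
                   replicate = seq_len(n_positive))
  )
  if (length(doses)) {
    rows <- c(rows, list(
      tidyr::expand_grid(concentration = sort(unique(doses)),
                         replicate = seq_len(n_replicates)) |>
        dplyr::mutate(role = "sample", condition = condition)
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$well_id <- sprintf("W%03d", seq_len(nrow(out)))
  validate_plate_layout(out)
  out[, c("well_id", "role", "condition", "concentration", "replicate")]
}

#' Validate a plate layout table
#'
#' @param layout A layout tibble (see [plate_layout()]).
#' @param require_positive Require at least one positive-control well
#'   (needed for LDH normalization).
#' @return The layout, invisibly; aborts with a classed error describing
#'   the violated rule otherwise.
#' @export
validate_plate_layout <- function(layout, require_positive = TRUE) {
  need <- c("well_id", "role", "condition", "concentration", "replicate")
  miss <- setdiff(need, names(layout))
  if (length(miss)) {
    abort(paste0("layout is missing columns: ", paste(miss, collapse = ", ")),
          class = "holotox_layout_error")
  }
  if (anyDuplicated(layout$well_id)) {
    abort("layout has duplicated well ids.", class = "holotox_layout_error")
  }
  if (!grepl("^[A-Za-z]", layout$well_id[1]) ||
      any(!grepl("^[A-Za-z][A-Za-z0-9]*$", layout$well_id))) {
    abort("malformed well ids: must start with a letter and be alphanumeric.",
          class = "holotox_layout_error")
  }
  if (!any(layout$role == "negative_control")) {
    abort("layout needs at least one negative_control well.",
          class = "holotox_layout_error")
  }
  if (!any(layout$role == "background")) {
    abort("layout needs at least one background well.",
          class = "holotox_layout_error")
  }
  if (require_positive && !any(layout$role == "positive_control")) {
    abort("layout needs at least one positive_control (digitonin) well for LDH normalization.",
          class = "holotox_layout_error")
  }
  if (any(layout$concentration < 0)) {
    abort("concentrations must be >= 0.", class = "holotox_layout_error")
  }
  invisible(layout)
}

#' Noise specification for the plate simulator
#'
#' @param wst8_sd Multiplicative noise sd on the WST-8 signal term.
#' @param ldh_sd Multiplicative noise sd per LDH kinetic reading.
#' @param off Zero all noise.
#' @return A list of class `plate_noise`.
#' @export
plate_noise <- function(wst8_sd = 0.03, ldh_sd = 0.01, off = FALSE) {
  if (off) { wst8_sd <- 0; ldh_sd <- 0 }
  structure(list(wst8_sd = wst8_sd, ldh_sd = ldh_sd), class = "plate_noise")
}

#' Simulate WST-8 and LDH plate-reader tables for a layout
#'
#' WST-8: `OD450 = background + signal * viability * (1 + eps)`, with a
#' separate turbidity reference read at 620 nm; the viability of sample
#' wells follows `truth_viability` at the well's concentration, negative
#' controls have viability 1, positive controls (digitonin) 0, background
#' wells contain no cells. LDH: each well's true kinetic slope is
#' `s_neg + death * (s_pos - s_neg)` and OD492 is read every minute for
#' 30 minutes (31 points); an optional plateau caps the series after
#' `plateau_minute` to exercise linear-range detection.
#'
#' @param layout A validated [plate_layout()] tibble.
#' @param truth_viability,truth_death [dose_effect_truth()] objects for the
#'   viability (decreasing) and death (increasing) endpoints.
#' @param noise A [plate_noise()].
#' @param seed Integer seed.
#' @param wst8_background,wst8_signal Background offset and full-viability
#'   signal of the corrected OD450 channel.
#' @param od620 Turbidity reference level.
#' @param ldh_slope_neg,ldh_slope_pos True kinetic slopes (OD/min) of the
#'   negative and positive (full lysis) controls.
#' @param ldh_od0 LDH series intercept.
#' @param plateau_minute If finite, the LDH series stops rising at this
#'   minute (substrate depletion).
#' @return A list with elements `wst8` (tibble: well_id, role, condition,
#'   concentration, od450, od620) and `ldh` (long tibble: well_id, role,
#'   condition, concentration, minute, od492).
#' @export
simulate_absorbance_plate <- function(layout,
                                      truth_viability,
                                      truth_death,
                                      noise = plate_noise(),
                                      seed = NULL,
                                      wst8_background = 0.15,
                                      wst8_signal = 1.3,
                                      od620 = 0.05,
                                      ldh_slope_neg = 0.002,
                                      ldh_slope_pos = 0.020,
                                      ldh_od0 = 0.05,
                                      plateau_minute = Inf) {
  validate_plate_layout(layout)
  stopifnot(inherits(truth_viability, "dose_effect_truth"),
            inherits(truth_death, "dose_effect_truth"))

  viability <- dplyr::case_when(
    layout$role == "background" ~ 0,
    layout$role == "negative_control" ~ 1,
    layout$role == "positive_control" ~ 0,
    TRUE ~ true_response(truth_viability, layout$concentration)
  )
  has_cells <- layout$role != "background"
  death <- dplyr::case_when(
    layout$role == "background" ~ 0,
    layout$role == "negative_control" ~ 0,
    layout$role == "positive_control" ~ 1,
    TRUE ~ true_response(truth_death, layout$concentration)
  )

  with_seed(seed, {
    eps <- if (noise$wst8_sd > 0) rnorm(nrow(layout), sd = noise$wst8_sd) else 0
    od450 <- wst8_background +
      ifelse(has_cells, wst8_signal * viability * (1 + eps), 0)
    wst8 <- tibble::tibble(
      well_id = layout$well_id, role = layout$role,
      condition = layout$condition, concentration = layout$concentration,
      od450 = od450, od620 = od620
    )

    minutes <- 0:30
    slope_true <- ldh_slope_neg + death * (ldh_slope_pos - ldh_slope_neg)
    slope_true[layout$role == "background"] <- 0
    ldh <- tidyr::expand_grid(idx = seq_len(nrow(layout)), minute = minutes)
    t_eff <- pmin(ldh$minute, plateau_minute)
    base <- ldh_od0 + slope_true[ldh$idx] * t_eff
    if (noise$ldh_sd > 0) {
      base <- base * (1 + rnorm(length(base), sd = noise$ldh_sd))
    }
    ldh <- tibble::tibble(
      well_id = layout$well_id[ldh$idx], role = layout$role[ldh$idx],
      condition = layout$condition[ldh$idx],
      concentration = layout$concentration[ldh$idx],
      minute = ldh$minute, od492 = base
    )
    list(wst8 = wst8, ldh = ldh)
  })
}
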