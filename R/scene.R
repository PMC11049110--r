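#' Dose-effect ground truth for synthetic experiments
#'
#' Describes the true dose-response relationship used by the synthetic-data
#' generators: a four-parameter logistic evaluated on dose, with `top` the
#' response at zero dose and `bottom` the response at saturating dose. For
#' proliferation and viability endpoints the response decreases with dose
#' (`top >= bottom`); for the death endpoint it increases (`bottom > top`).
#' An optional log-normal "rebound" bump can be superimposed to emulate
#' non-monotonic dose-effect relationships such as those produced by
#' drug-loaded nanoparticles.
#'
#' @param ec50 True half-maximal effective concentration (ug/mL), > 0.
#' @param hill Hill slope (> 0); the direction of the curve is carried by
#'   `top` and `bottom`, not by the sign of `hill`.
#' @param top,bottom Response fractions at zero and saturating dose.
#' @param endpoint One of `"proliferation"`, `"viability"`, `"death"`.
#' @param rebound_amplitude,rebound_dose,rebound_width Optional non-monotone
#'   bump: amplitude (response fraction), centre dose (ug/mL) and width in
#'   log10-dose decades. `rebound_amplitude = 0` (default) keeps the curve
#'   monotone.
#' @return An object of class `dose_effect_truth`; calling it is not needed,
#'   use [true_response()] to evaluate it.
#' @export
dose_effect_truth <- function(ec50, hill = 2, top = 1, bottom = 0,
                              endpoint = c("proliferation", "viability", "death"),
                              rebound_amplitude = 0, rebound_dose = 1,
                              rebound_width = 0.35) {
  endpoint <- match.arg(endpoint)
  stopifnot_scalar_number(ec50, "ec50", positive = TRUE)
  stopifnot_scalar_number(hill, "hill", positive = TRUE)
  if (endpoint %in% c("proliferation", "viability") && top < bottom) {
    abort("proliferation/viability truths must have top >= bottom.")
  }
  if (endpoint == "death" && bottom <= top) {
    abort("death truths must be monotone increasing (bottom > top).")
  }
  structure(
    list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
         endpoint = endpoint,
         rebound_amplitude = rebound_amplitude,
         rebound_dose = rebound_dose,
         rebound_width = rebound_width),
    class = "dose_effect_truth"
  )
}

#' Evaluate a dose-effect truth at given doses
#'
#' @param truth A [dose_effect_truth()].
#' @param dose Numeric vector of doses (ug/mL), >= 0. At dose 0 the response
#'   equals `top` exactly.
#' @return Numeric vector of true response fractions.
#' @export
true_response <- function(truth, dose) {
  stopifnot(inherits(truth, "dose_effect_truth"), all(dose >= 0))
  p <- ifelse(dose == 0, truth$top,
              truth$bottom + (truth$top - truth$bottom) /
                (1 + (dose / truth$ec50)^truth$hill))
  if (truth$rebound_amplitude != 0) {
    bump <- ifelse(dose > 0,
                   truth$rebound_amplitude *
                     exp(-(log10(dose / truth$rebound_dose))^2 /
                           (2 * truth$rebound_width^2)),
                   0)
    sgn <- if (truth$endpoint == "death") -1 else 1
    p <- p + sgn * bump
  }
  p
}

# integrated phase (sum(phase) * pixel_area, um^2 rad) per pg of dry mass
phase_integral_per_pg <- function(config) {
  2 * pi * config$refractive_increment_alpha / config$wavelength_um
}

#' Generate a ground-truth phase scene of an adherent cell population
#'
#' Renders `n_cells` smooth, compact phase "cells" (tapered quartic radial
#' profiles) on a zero background over the configured field of view. Each
#' cell's integrated phase is normalized so that its dry mass (via the
#' standard QPI relation dm = lambda/(2 pi alpha) * mean-phase * S_FOV)
#' equals a mass drawn around `mean_cell_mass`; the scene records its exact
#' total dry mass evaluated from the rendered map.
#'
#' @param config An [optical_config()].
#' @param n_cells Number of cells to place (>= 0).
#' @param mean_cell_mass Mean single-cell dry mass in picograms.
#' @param mass_cv Coefficient of variation of per-cell mass (0 = identical).
#' @param cell_radius_um Mean cell radius in micrometres.
#' @param radius_cv Coefficient of variation of the radius.
#' @param max_attempts_per_cell Placement attempts per cell before the
#'   packing is declared infeasible.
#' @param min_separation_frac Minimum centre separation as a fraction of the
#'   two cells' summed radii (overlap budget; 1 = no overlap allowed).
#' @param seed Integer seed; identical seeds and parameters give bitwise
#'   identical scenes.
#' @return An object of class `phase_scene` with elements `phase_map`
#'   (radians, rows = y, cols = x), `pixel_area` (um^2),
#'   `true_total_dry_mass` (pg), `cell_count`, `timestamp` (hours) and a
#'   `cells` tibble of centre/radius/mass.
#' @examples
#' cfg <- optical_config(pixel_count_x = 128, pixel_count_y = 128)
#' sc <- generate_phase_scene(cfg, n_cells = 10, seed = 1)
#' sc$true_total_dry_mass
#' @export
generate_phase_scene <- function(config, n_cells,
                                 mean_cell_mass = 300,
                                 mass_cv = 0.25,
                                 cell_radius_um = 15,
                                 radius_cv = 0.15,
                                 max_attempts_per_cell = 200L,
                                 min_separation_frac = 0.85,
                                 seed = NULL) {
  stopifnot(inherits(config, "optical_config"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  stopifnot_scalar_number(mean_cell_mass, "mean_cell_mass", positive = TRUE)

  nr <- config$pixel_count_y
  nc <- config$pixel_count_x
  map <- matrix(0, nr, nc)
  cells <- tibble::tibble(x = numeric(), y = numeric(),
                          radius = numeric(), mass = numeric())
  if (n_cells > 0) {
    cells <- with_seed(seed, {
      masses <- if (mass_cv > 0) {
        sdl <- sqrt(log(1 + mass_cv^2))
        rlnorm(n_cells, log(mean_cell_mass) - sdl^2 / 2, sdl)
      } else rep(mean_cell_mass, n_cells)
      radii <- if (radius_cv > 0) {
        sdl <- sqrt(log(1 + radius_cv^2))
        rlnorm(n_cells, log(cell_radius_um) - sdl^2 / 2, sdl)
      } else rep(cell_radius_um, n_cells)
      xs <- ys <- numeric(n_cells)
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (a in seq_len(max_attempts_per_cell)) {
          cx <- runif(1, radii[i], config$fov_x - radii[i])
          cy <- runif(1, radii[i], config$fov_y - radii[i])
          if (i == 1L || all(sqrt((xs[seq_len(i - 1)] - cx)^2 +
                                  (ys[seq_len(i - 1)] - cy)^2) >=
                             min_separation_frac *
                               (radii[seq_len(i - 1)] + radii[i]) / 2)) {
            xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break
          }
        }
        if (!placed) {
          abort(paste0("cell density too high: could not place cell ", i,
                       " of ", n_cells, " within the overlap budget."),
                class = "holotox_packing_error")
        }
      }
      tibble::tibble(x = xs, y = ys, radius = radii, mass = masses)
    })
    map <- render_cells(cells, config)
  }

  scene_from_map(map, config, cell_count = n_cells, cells = cells)
}

# render a table of cells (x, y in um; radius um; mass pg) to a phase map,
# normalizing each cell's rendered integrated phase to its target mass;
# cells whose peak phase would exceed `peak_cap` radians are widened
# (mass-preserving) so single cells never force unwrapping ambiguity
render_cells <- function(cells, config, peak_cap = 3) {
  nr <- config$pixel_count_y
  nc <- config$pixel_count_x
  xg <- (seq_len(nc) - 0.5) * config$pixel_pitch_x
  yg <- (seq_len(nr) - 0.5) * config$pixel_pitch_y
  map <- matrix(0, nr, nc)
  kpp <- phase_integral_per_pg(config)
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]; R <- cells$radius[i]
    target_integral <- cells$mass[i] * kpp     # um^2 rad
    # continuous integral of the quartic bump is peak * pi R^2 / 3
    peak_cont <- 3 * target_integral / (pi * R^2)
    if (peak_cont > peak_cap) R <- R * sqrt(peak_cont / peak_cap)
    repeat {
      jx <- which(abs(xg - cx) <= R)
      jy <- which(abs(yg - cy) <= R)
      if (!length(jx) || !length(jy)) break
      r2 <- outer((yg[jy] - cy)^2, (xg[jx] - cx)^2, `+`) / R^2
      prof <- ifelse(r2 < 1, (1 - r2)^2, 0)
      s <- sum(prof) * config$pixel_area
      if (s <= 0) break
      scale <- target_integral / s
      if (scale <= peak_cap * 1.02) {
        map[jy, jx] <- map[jy, jx] + prof * scale
        break
      }
      R <- R * sqrt(scale / peak_cap)  # discrete grid made it too tall
    }
  }
  map
}

scene_from_map <- function(map, config, cell_count, cells,
                           timestamp = 0) {
  structure(
    list(
      phase_map = map,
      pixel_area = config$pixel_area,
      true_total_dry_mass = dry_mass_from_phase(mean(map), config),
      cell_count = as.integer(cell_count),
      timestamp = timestamp,
      cells = cells,
      config = config
    ),
    class = "phase_scene"
  )
}

#' @export
print.phase_scene <- function(x, ...) {
  cat("<phase_scene>", dim(x$phase_map)[1], "x", dim(x$phase_map)[2], "px,",
      x$cell_count, "cells,",
      sprintf("%.1f pg dry mass, t = %g h\n", x$true_total_dry_mass,
              x$timestamp))
  invisible(x)
}

#' Evolve a phase scene under a dose-dependent growth law
#'
#' Produces the scene after `duration` hours of incubation at the given
#' dose. The population dry-mass multiplier interpolates between the
#' control growth factor (dose -> 0) and a net-loss floor (dose -> inf)
#' through the four-parameter logistic truth:
#' `m(d) = floor + (control - floor) * p(d)` with `p` the truth response
#' rescaled to `[0, 1]`. Surviving cells are re-rendered (grown or thinned)
#' and, when the effect is strong, low-mass debris fragments are added; the
#' rendered map is finally rescaled so the total dry mass matches the growth
#' law exactly.
#'
#' @param scene_t0 A `phase_scene` at t = 0.
#' @param dose Dose in ug/mL (>= 0).
#' @param truth A [dose_effect_truth()] for the proliferation endpoint.
#' @param duration Duration in hours (> 0); the growth factors are defined
#'   per 24 h and scaled as `m^(duration/24)`.
#' @param control_growth Population dry-mass multiplier of the untreated
#'   control over 24 h (default 2.0).
#' @param floor_growth Multiplier at saturating dose (default 0.4, net mass
#'   loss through death and detachment).
#' @param seed Integer seed for the re-rendering.
#' @return The t = `duration` `phase_scene`.
#' @export
apply_dose_response_truth <- function(scene_t0, dose, truth,
                                      duration = 24,
                                      control_growth = 2.0,
                                      floor_growth = 0.4,
                                      seed = NULL) {
  stopifnot(inherits(scene_t0, "phase_scene"),
            inherits(truth, "dose_effect_truth"))
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (dose < 0) abort("`dose` must be >= 0.")

  span <- truth$top - truth$bottom
  p01 <- if (span == 0) 1 else (true_response(truth, dose) - truth$bottom) / span
  m24 <- floor_growth + (control_growth - floor_growth) * p01
  m <- if (m24 > 0) m24^(duration / 24) else 0
  config <- scene_t0$config
  target_mass <- m * scene_t0$true_total_dry_mass

  n0 <- scene_t0$cell_count
  if (n0 == 0L || target_mass <= 0) {
    map <- matrix(0, config$pixel_count_y, config$pixel_count_x)
    return(scene_from_map(map, config, 0L,
                          scene_t0$cells[0, ],
                          timestamp = scene_t0$timestamp + duration))
  }

  n24 <- max(if (m < 1) 0L else 1L, as.integer(round(n0 * min(m, 4))))
  n_debris <- if (m < 1) as.integer(round((n0 - min(n24, n0)) * 1.5)) else 0L

  out <- with_seed(seed, {
    mean_mass <- mean(scene_t0$cells$mass)
    mean_rad <- mean(scene_t0$cells$radius)
    cells <- generate_cell_table(config, n24, mean_mass, 0.25,
                                 mean_rad, 0.15)
    if (n_debris > 0L) {
      debris <- generate_cell_table(config, n_debris, mean_mass * 0.08, 0.5,
                                    mean_rad * 0.3, 0.3,
                                    min_separation_frac = 0)
      cells <- dplyr::bind_rows(cells, debris)
    }
    cells
  })
  map <- render_cells(out, config)
  tot <- dry_mass_from_phase(mean(map), config)
  if (tot > 0) map <- map * (target_mass / tot)
  scene_from_map(map, config, cell_count = n24, cells = out,
                 timestamp = scene_t0$timestamp + duration)
}

# internal: draw a cell table without rendering (placement as in
# generate_phase_scene, but overlap allowed to relax for debris)
generate_cell_table <- function(config, n, mean_mass, mass_cv,
                                mean_radius, radius_cv,
                                min_separation_frac = 0.85,
                                max_attempts_per_cell = 200L) {
  if (n <= 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(),
                          radius = numeric(), mass = numeric()))
  }
  sdl_m <- sqrt(log(1 + mass_cv^2))
  masses <- if (mass_cv > 0) rlnorm(n, log(mean_mass) - sdl_m^2 / 2, sdl_m) else rep(mean_mass, n)
  sdl_r <- sqrt(log(1 + radius_cv^2))
  radii <- if (radius_cv > 0) rlnorm(n, log(mean_radius) - sdl_r^2 / 2, sdl_r) else rep(mean_radius, n)
  radii <- pmin(radii, min(config$fov_x, config$fov_y) / 2.5)
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      cx <- runif(1, radii[i], config$fov_x - radii[i])
      cy <- runif(1, radii[i], config$fov_y - radii[i])
      ok <- i == 1L || min_separation_frac == 0 ||
        all(sqrt((xs[seq_len(i - 1)] - cx)^2 + (ys[seq_len(i - 1)] - cy)^2) >=
              min_separation_frac * (radii[seq_len(i - 1)] + radii[i]) / 2)
      if (ok) { xs[i] <- cx; ys[i] <- cy; placed <- TRUE; break }
    }
    if (!placed) {
      # relax: accept the last attempted position rather than fail mid-growth
      xs[i] <- cx; ys[i] <- cy
    }
  }
  tibble::tibble(x = xs, y = ys, radius = radii, mass = masses)
}
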