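#' WST-8 relative cell viability
#'
#' Corrects each well's OD450 by its OD620 turbidity reference, subtracts
#' the mean background (wells without cells) and normalizes to the mean
#' negative (medium) control, which is set to exactly 100%:
#' `viability% = 100 * (OD450-620,well - OD450-620,bg) /
#'  (OD450-620,neg - OD450-620,bg)`.
#'
#' @param plate Tibble with columns `well_id`, `role`, `od450`, `od620`
#'   (and typically `condition`, `concentration`).
#' @return The plate with columns `od_corrected`, `viability_percent` and
#'   `plate_valid`. When the negative-control signal does not exceed the
#'   background the plate is flagged invalid (`plate_valid = FALSE`,
#'   viability `NA`) with a warning.
#' @examples
#' p <- tibble::tibble(
#'   well_id = c("B1", "N1", "S1"),
#'   role = c("background", "negative_control", "sample"),
#'   od450 = c(0.15, 1.5, 0.8), od620 = c(0.05, 0.1, 0.1))
#' wst8_viability(p)$viability_percent
#' @export
wst8_viability <- function(plate) {
  need <- c("role", "od450", "od620")
  if (!all(need %in% names(plate))) {
    abort("plate needs columns role, od450, od620.")
  }
  if (any(!is.finite(plate$od450)) || any(!is.finite(plate$od620))) {
    abort("absorbances must be finite.")
  }
  if (!any(plate$role == "background") ||
      !any(plate$role == "negative_control")) {
    abort("plate needs >= 1 background and >= 1 negative_control well.",
          class = "holotox_layout_error")
  }
  od <- plate$od450 - plate$od620
  bg <- mean(od[plate$role == "background"])
  neg <- mean(od[plate$role == "negative_control"])
  denom <- neg - bg
  out <- dplyr::mutate(plate, od_corrected = od)
  if (denom <= 0) {
    warn("plate invalid: negative-control signal does not exceed background.")
    out$viability_percent <- NA_real_
    out$plate_valid <- FALSE
  } else {
    out$viability_percent <- 100 * ((od - bg) / denom)
    out$plate_valid <- TRUE
  }
  out
}

# closed-form OLS slope and r^2 for a window
ols_slope_r2 <- function(t, y) {
  n <- length(t)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  syy <- sum((y - ym)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= .Machine$double.eps * n * max(1, ym^2)) 1 else (sxy^2 / (sxx * syy))
  c(slope = slope, r2 = r2, intercept = ym - slope * tm)
}

#' Kinetic slope of an LDH absorbance series over its linear range
#'
#' Searches the contiguous time window of maximal length whose ordinary
#' least-squares fit reaches `r2 >= r2_threshold`; among equal-length
#' windows the highest r2 wins, then the earliest start. The chosen window
#' is then refined by greedy end-trimming: an endpoint is dropped whenever
#' doing so at least halves the residual misfit `1 - r2` (so a stray
#' plateau point that dominates the residuals is excluded, while random
#' noise - which no single point dominates - leaves the window intact).
#' When no window qualifies, the full-series slope is returned with a
#' `nonlinear_kinetics` flag. A constant series counts as perfectly linear
#' (slope 0 over the full series).
#'
#' @param minutes Sampling times in minutes (strictly increasing).
#' @param od492 Absorbance readings, same length as `minutes` (>= 5).
#' @param min_window Minimum number of points in the window (>= 5).
#' @param r2_threshold Linearity requirement (default 0.99).
#' @return A one-row tibble: `slope` (OD/min), `t_start`, `t_end`, `r2`,
#'   `n_points`, `nonlinear_kinetics`.
#' @export
ldh_kinetic_slope <- function(minutes, od492, min_window = 5L,
                              r2_threshold = 0.99) {
  if (length(minutes) != length(od492)) abort("lengths differ.")
  if (length(minutes) < 5L) abort("need at least 5 time points.")
  if (any(diff(minutes) <= 0)) abort("sampling times must be strictly increasing.")
  if (any(!is.finite(od492))) abort("absorbances must be finite.")
  min_window <- max(5L, as.integer(min_window))
  n <- length(minutes)
  for (L in seq(n, min_window)) {
    best <- NULL
    for (s in seq_len(n - L + 1L)) {
      idx <- s:(s + L - 1L)
      f <- ols_slope_r2(minutes[idx], od492[idx])
      if (f[["r2"]] >= r2_threshold &&
          (is.null(best) || f[["r2"]] > best$r2 + 1e-12)) {
        best <- list(slope = f[["slope"]], r2 = f[["r2"]],
                     t_start = minutes[s], t_end = minutes[s + L - 1L],
                     n_points = L)
      }
    }
    if (!is.null(best)) {
      s <- match(best$t_start, minutes)
      e <- match(best$t_end, minutes)
      repeat {
        if (e - s + 1L <= min_window) break
        cur <- ols_slope_r2(minutes[s:e], od492[s:e])
        miss <- 1 - cur[["r2"]]
        if (miss <= 1e-12) break
        drop_first <- ols_slope_r2(minutes[(s + 1L):e], od492[(s + 1L):e])
        drop_last <- ols_slope_r2(minutes[s:(e - 1L)], od492[s:(e - 1L)])
        if ((1 - drop_last[["r2"]]) <= (1 - drop_first[["r2"]])) {
          if ((1 - drop_last[["r2"]]) <= 0.5 * miss) e <- e - 1L else break
        } else {
          if ((1 - drop_first[["r2"]]) <= 0.5 * miss) s <- s + 1L else break
        }
      }
      f <- ols_slope_r2(minutes[s:e], od492[s:e])
      return(tibble::tibble(slope = f[["slope"]], t_start = minutes[s],
                            t_end = minutes[e], r2 = f[["r2"]],
                            n_points = e - s + 1L,
                            nonlinear_kinetics = FALSE))
    }
  }
  f <- ols_slope_r2(minutes, od492)
  tibble::tibble(slope = f[["slope"]], t_start = minutes[1],
                 t_end = minutes[n], r2 = f[["r2"]], n_points = n,
                 nonlinear_kinetics = TRUE)
}

#' Per-well LDH kinetic slopes from a long kinetic table
#'
#' @param ldh Long tibble with columns `well_id`, `minute`, `od492` and any
#'   per-well metadata (`role`, `condition`, `concentration`), constant
#'   within a well.
#' @inheritParams ldh_kinetic_slope
#' @return One row per well: metadata plus the [ldh_kinetic_slope()]
#'   columns.
#' @export
ldh_slopes <- function(ldh, min_window = 5L, r2_threshold = 0.99) {
  need <- c("well_id", "minute", "od492")
  if (!all(need %in% names(ldh))) {
    abort("ldh table needs columns well_id, minute, od492.")
  }
  meta_cols <- setdiff(names(ldh), c("minute", "od492"))
  ldh |>
    dplyr::arrange(.data$well_id, .data$minute) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(function(df, key) {
      ldh_kinetic_slope(df$minute, df$od492, min_window = min_window,
                        r2_threshold = r2_threshold)
    }) |>
    dplyr::ungroup()
}

#' LDH release percentage from per-well kinetic slopes
#'
#' Normalizes each well's kinetic slope between the mean negative (medium)
#' control slope (0% release) and the mean positive (digitonin, full
#' lysis) control slope (100% release):
#' `release% = 100 * (m_well - m_neg) / (m_pos - m_neg)`.
#' Values are reported unclamped; noisy wells may fall below 0% or above
#' 100%.
#'
#' @param slopes Tibble with columns `role` and `slope` (see
#'   [ldh_slopes()]).
#' @return `slopes` with columns `release_percent` and `plate_valid`. When
#'   the positive-control slope does not exceed the negative control the
#'   plate is flagged invalid with a warning.
#' @export
ldh_release_percent <- function(slopes) {
  if (!all(c("role", "slope") %in% names(slopes))) {
    abort("`slopes` needs columns role and slope.")
  }
  if (!any(slopes$role == "negative_control") ||
      !any(slopes$role == "positive_control")) {
    abort("LDH normalization needs negative and positive (digitonin) control wells.",
          class = "holotox_layout_error")
  }
  m_neg <- mean(slopes$slope[slopes$role == "negative_control"])
  m_pos <- mean(slopes$slope[slopes$role == "positive_control"])
  out <- slopes
  if (m_pos <= m_neg) {
    warn("plate invalid: positive-control slope does not exceed negative control.")
    out$release_percent <- NA_real_
    out$plate_valid <- FALSE
  } else {
    out$release_percent <- 100 * ((slopes$slope - m_neg) / (m_pos - m_neg))
    out$plate_valid <- TRUE
  }
  out
}
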