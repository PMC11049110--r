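#' Tidy a four-parameter logistic fit
#'
#' @param x A `holotox_drfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`bottom`, `top`, `ec50`,
#'   `hill`) and its estimate.
#' @exportS3Method generics::tidy
tidy.holotox_drfit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill)
  )
}

#' One-row summary of a four-parameter logistic fit
#'
#' @param x A `holotox_drfit`.
#' @param ... Unused.
#' @return A one-row tibble: `ec50`, `hill`, `r2`, `accepted`,
#'   `rejection_reason`, `n_points`, `n_doses`.
#' @exportS3Method generics::glance
glance.holotox_drfit <- function(x, ...) {
  tibble::tibble(
    ec50 = x$ec50, hill = x$hill, r2 = x$r2,
    accepted = x$accepted, rejection_reason = x$rejection_reason,
    n_points = nrow(x$data), n_doses = length(unique(x$data$dose))
  )
}

#' Plot a dose-response fit
#'
#' Replicate responses and per-dose means on a log10 dose axis with the
#' fitted four-parameter logistic curve and the EC50 marked.
#'
#' @param object A `holotox_drfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.holotox_drfit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µg/mL)", y = "response (%)")
  if (object$converged) {
    grid <- tibble::tibble(
      dose = 10^seq(log10(min(dat$dose)), log10(max(dat$dose)),
                    length.out = 200))
    grid$response <- object$bottom + (object$top - object$bottom) /
      (1 + 10^(object$hill * (log10(grid$dose) - log10(object$ec50))))
    p <- p +
      ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = object$ec50, linetype = "dashed",
                          colour = "grey40")
  }
  p
}

#' Plot the comparative EC50 table of a pipeline report
#'
#' @param object A `holotox_report`.
#' @param ... Unused.
#' @return A ggplot object: EC50 (mean across experiments, SD error bars)
#'   per assay on a log scale; undetermined assays are omitted.
#' @exportS3Method ggplot2::autoplot
autoplot.holotox_report <- function(object, ...) {
  tab <- dplyr::filter(object$ec50_table, .data$determined)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$assay, y = .data$ec50_mean)) +
    ggplot2::geom_col(fill = "#2166ac", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ec50_mean - .data$ec50_sd,
                   ymax = .data$ec50_mean + .data$ec50_sd),
      width = 0.2, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "EC50 (µg/mL)")
}

#' Plot a phase image
#'
#' @param object A `qpi_image`.
#' @param ... Unused.
#' @return A ggplot raster of the phase map in radians.
#' @exportS3Method ggplot2::autoplot
autoplot.qpi_image <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(ncol(object$phase)),
                           y = seq_len(nrow(object$phase)))
  df$phase <- as.vector(object$phase) # column-major: y fastest within x
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "phase (rad)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
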