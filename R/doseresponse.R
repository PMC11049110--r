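#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - log10(ec50))))`
#' on log10 dose, with multi-start initialization (EC50 at the 25/50/75%
#' quantiles of the tested doses, Hill slope in {+-1, +-3}) to avoid local
#' minima; the Hill sign is unconstrained, so the direction of the curve is
#' inferred from the data. The zero-dose control is excluded (its logarithm
#' is undefined); it enters only through the upstream normalization of the
#' responses.
#'
#' @param doses Concentrations (same unit throughout, e.g. ug/mL); at least
#'   4 distinct positive values after dropping any zeros.
#' @param responses Percent responses, same length as `doses`.
#' @return An object of class `holotox_drfit` with elements `bottom`,
#'   `top`, `ec50`, `hill`, `r2`, `accepted` (`NA` until
#'   [assess_fit_acceptance()] is applied), `rejection_reason`, `data`,
#'   `converged`. When no start converges (or the responses are constant)
#'   the fit is returned with `rejection_reason = "fit_failed"` and `NA`
#'   parameters.
#' @examples
#' d <- rep(c(1, 3, 10, 30, 100), each = 2)
#' y <- 100 / (1 + (d / 10)^2)
#' fit <- fit_four_parameter_logistic(d, y)
#' fit$ec50
#' @export
fit_four_parameter_logistic <- function(doses, responses) {
  if (length(doses) != length(responses)) abort("lengths differ.")
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  d <- doses[keep]; y <- responses[keep]
  if (length(unique(d)) < 4L) {
    abort("need at least 4 distinct positive doses.")
  }
  dat <- tibble::tibble(dose = d, response = y, log_dose = log10(d))
  sstot <- sum((y - mean(y))^2)
  failed <- function(reason) {
    structure(list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
                   hill = NA_real_, r2 = NA_real_, accepted = FALSE,
                   rejection_reason = reason, data = dat,
                   converged = FALSE),
              class = "holotox_drfit")
  }
  if (sstot < 1e-10 * max(1, mean(y)^2)) return(failed("fit_failed"))

  le_grid <- unname(quantile(dat$log_dose, c(0.25, 0.5, 0.75)))
  starts <- tidyr::expand_grid(le = le_grid, hill = c(-3, -1, 1, 3))
  top0 <- max(y); bot0 <- min(y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) /
          (1 + 10^(hill * (log_dose - le))),
        data = dat,
        start = list(bottom = bot0, top = top0,
                     hill = starts$hill[i], le = starts$le[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss - 1e-12) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) return(failed("fit_failed"))
  cf <- coef(best$fit)
  # hill < 0 with swapped asymptotes describes the same curve; the sign is
  # left as fitted so `top` is always the response as dose -> 0
  if (cf[["hill"]] < 0) {
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    cf[["hill"]] <- -cf[["hill"]]
  }
  structure(list(bottom = cf[["bottom"]], top = cf[["top"]],
                 ec50 = 10^cf[["le"]], hill = cf[["hill"]],
                 r2 = 1 - best$ss / sstot, accepted = NA,
                 rejection_reason = "none", data = dat, converged = TRUE),
            class = "holotox_drfit")
}

#' Tidy-first wrapper for the four-parameter logistic fit
#'
#' @param data A data frame with dose and response columns.
#' @param dose,response Column names (tidy-eval).
#' @return A `holotox_drfit` (see [fit_four_parameter_logistic()]).
#' @export
fit_dose_response <- function(data, dose = dose, response = response) {
  d <- dplyr::pull(data, {{ dose }})
  y <- dplyr::pull(data, {{ response }})
  fit_four_parameter_logistic(d, y)
}

#' @export
print.holotox_drfit <- function(x, ...) {
  cat("<4PL dose-response fit>\n")
  if (x$converged) {
    cat(sprintf("  EC50 = %.4g, hill = %.3g, top = %.4g, bottom = %.4g, R2 = %.4f\n",
                x$ec50, x$hill, x$top, x$bottom, x$r2))
  } else {
    cat("  fit failed\n")
  }
  cat("  accepted:", x$accepted, "| reason:", x$rejection_reason, "\n")
  invisible(x)
}

#' Fit-acceptance rules
#'
#' @param k_sem Rebound allowance in per-dose SEM units (default 3).
#' @param abs_allowance Fallback rebound allowance (response units) when a
#'   per-dose SEM cannot be estimated (single replicates).
#' @param r2_min Minimum r2 for acceptance (default 0.8).
#' @return A list of class `acceptance_rules`.
#' @export
acceptance_rules <- function(k_sem = 3, abs_allowance = 5, r2_min = 0.8) {
  structure(list(k_sem = k_sem, abs_allowance = abs_allowance,
                 r2_min = r2_min), class = "acceptance_rules")
}

#' Apply acceptance rules to a dose-response fit
#'
#' A fit is rejected when (a) the per-dose mean responses are non-monotone
#' beyond a noise allowance: in the inferred direction of the curve, a
#' rebound against the running extreme exceeding `k_sem` pooled standard
#' errors of a per-dose mean (`non_monotonic`); (b) `r2` is below the
#' threshold (`poor_fit`); or (c) the EC50 falls outside the tested dose
#' range (`ec50_out_of_range`). Otherwise `accepted` is set.
#'
#' @param fit A `holotox_drfit`.
#' @param rules An [acceptance_rules()].
#' @return The fit with `accepted`/`rejection_reason` set.
#' @export
assess_fit_acceptance <- function(fit, rules = acceptance_rules()) {
  stopifnot(inherits(fit, "holotox_drfit"))
  if (!fit$converged) {
    fit$accepted <- FALSE
    fit$rejection_reason <- "fit_failed"
    return(fit)
  }
  agg <- fit$data |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(mean = mean(.data$response),
                     sem = if (dplyr::n() > 1)
                       stats::sd(.data$response) / sqrt(dplyr::n())
                     else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$dose)
  decreasing <- agg$mean[1] >= agg$mean[nrow(agg)]
  m <- if (decreasing) agg$mean else -agg$mean
  # pooled SEM across doses is a stabler noise scale than each dose's own
  pooled_sem <- if (all(is.na(agg$sem))) NA_real_ else
    sqrt(mean(agg$sem[!is.na(agg$sem)]^2))
  allow <- if (is.na(pooled_sem) || pooled_sem == 0)
    rules$abs_allowance else rules$k_sem * pooled_sem
  run_min <- cummin(m)
  rebound <- FALSE
  for (i in seq(2, nrow(agg))) {
    if (m[i] - run_min[i - 1L] > allow) { rebound <- TRUE; break }
  }
  if (rebound) {
    fit$accepted <- FALSE
    fit$rejection_reason <- "non_monotonic"
  } else if (!is.na(fit$r2) && fit$r2 < rules$r2_min) {
    fit$accepted <- FALSE
    fit$rejection_reason <- "poor_fit"
  } else if (fit$ec50 < min(fit$data$dose) || fit$ec50 > max(fit$data$dose)) {
    fit$accepted <- FALSE
    fit$rejection_reason <- "ec50_out_of_range"
  } else {
    fit$accepted <- TRUE
    fit$rejection_reason <- "none"
  }
  fit
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Per-dose comparison against the medium control
#'
#' One-way ANOVA across all groups (control plus doses) gates the
#' procedure: when the global test is not significant at `alpha`, no dose
#' is starred. Otherwise each dose group is compared with the control by a
#' Welch two-sample t-test, p-values are adjusted by Holm's step-down
#' method (family-wise error control over the dose family), and stars are
#' assigned at p < 0.05 (*), < 0.01 (**), < 0.001 (***).
#'
#' @param data Tibble with columns `dose` and `response` (replicates as
#'   rows); the control rows are `dose == control_dose`.
#' @param control_dose Dose value identifying the control group
#'   (default 0).
#' @param alpha Gate level for the ANOVA (default 0.05).
#' @return A tibble with one row per non-control dose: `dose`, `n`,
#'   `mean`, `diff` (vs control mean), `p_raw`, `p_adj`, `stars`,
#'   `exact_tie`. The ANOVA p-value is in attribute `anova_p`.
#' @export
compare_to_control <- function(data, control_dose = 0, alpha = 0.05) {
  if (!all(c("dose", "response") %in% names(data))) {
    abort("`data` needs columns dose and response.")
  }
  ctrl <- data$response[data$dose == control_dose]
  if (length(ctrl) < 2L) abort("need >= 2 control replicates.")
  grp <- data[data$dose != control_dose, ]
  if (!nrow(grp)) abort("no dose groups to compare.")
  if (any(table(grp$dose) < 2L)) abort("need >= 2 replicates per dose group.")

  all_tie <- stats::var(data$response) == 0
  an_p <- if (all_tie) 1 else {
    a <- stats::aov(response ~ factor(dose), data = data)
    summary(a)[[1]][["Pr(>F)"]][1]
  }
  if (!is.finite(an_p)) an_p <- 1

  welch_p <- function(y) {
    if (stats::var(y) == 0 && stats::var(ctrl) == 0) {
      if (isTRUE(all.equal(mean(y), mean(ctrl)))) return(c(p = 1, tie = 1))
      return(c(p = 1e-300, tie = 0))
    }
    c(p = tryCatch(stats::t.test(y, ctrl)$p.value,
                   error = function(e) NA_real_), tie = 0)
  }
  res <- grp |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$response),
                     p_raw = welch_p(.data$response)[["p"]],
                     exact_tie = welch_p(.data$response)[["tie"]] == 1,
                     .groups = "drop") |>
    dplyr::mutate(diff = .data$mean - mean(ctrl)) |>
    dplyr::arrange(.data$dose)
  res$p_adj <- p.adjust(res$p_raw, method = "holm")
  res$stars <- if (an_p < alpha) significance_stars(res$p_adj) else
    rep("", nrow(res))
  res <- res[, c("dose", "n", "mean", "diff", "p_raw", "p_adj", "stars",
                 "exact_tie")]
  attr(res, "anova_p") <- an_p
  res
}

#' Summarize EC50 values across independent experiments
#'
#' Arithmetic mean and standard deviation of per-experiment EC50s for each
#' condition/assay combination; conditions without any accepted fit are
#' reported as "not determined". One experiment gives a mean without an SD.
#'
#' @param fits Tibble with one row per fitted experiment and columns
#'   `ec50`, `accepted` plus any grouping columns named in `by`.
#' @param by Character vector of grouping columns present in `fits`
#'   (default `c("assay", "condition")`, intersected with the data).
#' @return A tibble with `ec50_mean`, `ec50_sd`, `n_fits`, `determined`
#'   and a formatted `label` (e.g. `"9 +/- 1"` or `"not determined"`).
#' @export
summarize_ec50_across_experiments <- function(fits,
                                              by = c("assay", "condition",
                                                     "cell_line")) {
  gv <- intersect(by, names(fits))
  if (!all(c("ec50", "accepted") %in% names(fits))) {
    abort("`fits` needs columns ec50 and accepted.")
  }
  fits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(gv))) |>
    dplyr::summarise(
      n_fits = sum(.data$accepted, na.rm = TRUE),
      ec50_mean = if (any(.data$accepted %in% TRUE))
        mean(.data$ec50[.data$accepted %in% TRUE]) else NA_real_,
      ec50_sd = if (sum(.data$accepted %in% TRUE) > 1L)
        stats::sd(.data$ec50[.data$accepted %in% TRUE]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      determined = .data$n_fits > 0L,
      label = dplyr::case_when(
        !.data$determined ~ "not determined",
        is.na(.data$ec50_sd) ~ sprintf("%.3g", .data$ec50_mean),
        TRUE ~ sprintf("%.3g +/- %.2g", .data$ec50_mean, .data$ec50_sd))
    )
}
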