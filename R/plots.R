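#' Plot a beta (or PPI coefficient) time course
#'
#' One line per predictor across the event-locked epoch, with the event
#' onset marked.
#'
#' @param object A `beta_timecourse`.
#' @param predictors Optional subset of predictor names (default: all
#'   but the intercept).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_timecourse <- function(object, predictors = NULL, ...) {
  df <- tibble::as_tibble(t(unclass(object)))
  df$time <- attr(object, "time_rel")
  df <- tidyr::pivot_longer(df, -"time",
    names_to = "predictor", values_to = "beta"
  )
  if (is.null(predictors)) {
    df <- dplyr::filter(df, .data$predictor != "(Intercept)")
  } else {
    df <- dplyr::filter(df, .data$predictor %in% predictors)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    .data$time, .data$beta,
    colour = .data$predictor
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from event onset (s)", y = "Beta (a.u.)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot left-out peak betas from a leave-one-out test
#'
#' @param object A `loo_peak_result`.
#' @param ... Unused.
#' @return A ggplot object: one point per participant with the group
#'   mean.
#' @export
autoplot.loo_peak_result <- function(object, ...) {
  df <- object$values
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3, shape = 18) +
    ggplot2::labs(
      x = object$predictor, y = "Left-out beta at group peak",
      subtitle = sprintf(
        "W = %.0f, p = %.3g",
        object$test$statistic, object$test$p.value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted revision mixed model
#'
#' Fixed-effect estimates with 95% confidence intervals.
#'
#' @param object A `conformity_lmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conformity_lmm <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::labs(
      x = "Estimate (95% CI)", y = NULL,
      title = paste(object$model, object$condition)
    ) +
    ggplot2::theme_minimal()
}

#' Mean revision by confidence and influence category
#'
#' Splits normalised confidence and previous-trial influence into low
#' `[0, 0.33]`, medium `(0.33, 0.66]` and high `(0.66, 1]` categories
#' and plots mean revision per cell: revision is expected to be maximal
#' at low confidence combined with high influence.
#'
#' @param annotated Annotated trial table.
#' @param condition Optional condition filter (`"human"`/`"computer"`).
#' @return A ggplot object (tile map).
#' @export
plot_revision_cells <- function(annotated, condition = NULL) {
  data <- revision_data(annotated)
  if (!is.null(condition)) {
    data <- dplyr::filter(data, .data$cover_story == condition)
  }
  cells <- data |>
    dplyr::mutate(
      conf_cat = cut(.data$conf_norm, c(0, 0.33, 0.66, 1),
        labels = c("low", "medium", "high"), include.lowest = TRUE
      ),
      inf_cat = cut(.data$prev_influence, c(0, 0.33, 0.66, 1),
        labels = c("low", "medium", "high"), include.lowest = TRUE
      )
    ) |>
    dplyr::group_by(.data$conf_cat, .data$inf_cat) |>
    dplyr::summarise(
      mean_revision = mean(.data$revision_stat),
      .groups = "drop"
    )
  ggplot2::ggplot(cells, ggplot2::aes(
    .data$inf_cat, .data$conf_cat,
    fill = .data$mean_revision
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Mean revision") +
    ggplot2::labs(x = "Influence (t-1)", y = "Confidence") +
    ggplot2::theme_minimal()
}

#' Sliding-window revision trajectories
#'
#' Group-mean revision per window, by partner susceptibility, separately
#' for human and computer conditions.
#'
#' @param windows Output of [sliding_window_revision()].
#' @return A ggplot object.
#' @export
plot_sliding_window <- function(windows) {
  df <- windows |>
    dplyr::group_by(
      .data$cover_story, .data$susceptibility, .data$window
    ) |>
    dplyr::summarise(
      mean_revision = mean(.data$mean_revision),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$window, .data$mean_revision,
    colour = .data$susceptibility
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cover_story) +
    ggplot2::labs(
      x = "Window (5 revision trials, step 1)",
      y = "Mean revision", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a connectivity surface
#'
#' Heat map of modulator-dependent seed-target coupling over confidence
#' and influence z-scores.
#'
#' @param grid Output of [connectivity_grid()].
#' @return A ggplot object.
#' @export
plot_connectivity_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(
    .data$inf_z, .data$conf_z,
    fill = .data$coupling
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Coupling") +
    ggplot2::labs(x = "Influence (z)", y = "Confidence (z)") +
    ggplot2::theme_minimal()
}
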