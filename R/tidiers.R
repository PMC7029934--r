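#' Tidy a passage result into the per-agent tibble
#'
#' @param x An `eel_passage_result`.
#' @param ... Unused.
#' @return The per-agent tibble (id, outcome, moves, spawn/final positions,
#'   and for the IBM burst speed, elapsed time, ascent time and L_max).
#' @export
tidy.eel_passage_result <- function(x, ...) {
  x$agents
}

#' One-row summary of a passage result
#'
#' @param x An `eel_passage_result`.
#' @param ... Unused.
#' @return One-row tibble: model, agents, passes, efficiency (%), median
#'   moves, and for the IBM the median ascent time of passed agents.
#' @export
glance.eel_passage_result <- function(x, ...) {
  passed <- x$agents$outcome == "passed"
  tibble::tibble(
    model = x$model,
    n_agents = x$n_agents,
    n_passed = x$n_passed,
    efficiency = x$efficiency,
    median_moves = stats::median(x$agents$moves),
    median_ascent_s = if ("ascent_s" %in% names(x$agents) && any(passed)) {
      stats::median(x$agents$ascent_s[passed])
    } else {
      NA_real_
    },
    seed = x$config$seed
  )
}

field_plot_df <- function(m, cell) {
  tibble::tibble(
    x = rep((seq_len(nrow(m)) - 0.5) * cell, times = ncol(m)),
    z = rep((seq_len(ncol(m)) - 0.5) * cell, each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a velocity field as a raster map
#'
#' @param object An [velocity_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eel_velocity_field <- function(object, ...) {
  df <- field_plot_df(object$speed, object$grid$cell_size)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$x,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "speed (m/s)", na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "spanwise (m)", y = "streamwise (m, upstream at top)") +
    ggplot2::theme_minimal()
}

#' Plot a classified field (passable / impassable / boundary map)
#'
#' White passable, red impassable, black boundary, matching the
#' conventional rendering of classified eel-tile maps.
#'
#' @param object An `eel_classified_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eel_classified_field <- function(object, ...) {
  df <- field_plot_df(object$class, object$grid$cell_size)
  df$class <- factor(df$value, levels = 0:2,
                     labels = c("passable", "impassable", "boundary"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$x,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(passable = "white", impassable = "firebrick",
                 boundary = "black"),
      name = NULL, drop = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "spanwise (m)", y = "streamwise (m, upstream at top)") +
    ggplot2::theme_minimal()
}

#' Plot a design chart (pass length against installation angle)
#'
#' One panel per elver length; lines join angles at each discharge, one
#' linetype per target efficiency.
#'
#' @param object An `eel_design_chart` from [design_chart()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eel_design_chart <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$angle_deg, y = .data$pass_length_m,
    colour = factor(.data$q_m2s), linetype = factor(.data$target_pct)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~elver_length, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "installation angle (deg)", y = "pass length (m)",
                  colour = expression(q ~ (m^2 ~ s^-1)),
                  linetype = "target efficiency (%)") +
    ggplot2::theme_minimal()
}
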