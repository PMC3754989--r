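#' Learning curves by block and trial type
#'
#' Mean percent-optimal responding per block, split by trial type and,
#' when a `group` column or manifest is supplied, by group.
#'
#' @param sessions A stacked session log tibble.
#' @param manifest Optional manifest tibble with `participant_id` and
#'   `group` columns used to facet by group.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(sessions, manifest = NULL) {
  df <- sessions |>
    dplyr::group_by(.data$participant_id, .data$block, .data$trial_type) |>
    dplyr::summarise(pct = 100 * mean(.data$optimal), .groups = "drop")
  if (!is.null(manifest)) {
    df <- dplyr::left_join(df,
                           manifest[c("participant_id", "group")],
                           by = "participant_id")
  } else {
    df$group <- "all"
  }
  df |>
    dplyr::group_by(.data$group, .data$block, .data$trial_type) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$block, y = .data$pct,
                                 color = .data$trial_type,
                                 linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::labs(x = "Block", y = "% optimal responses",
                  color = "Trial type", linetype = "Group") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Reward versus punishment performance scatter
#'
#' One point per participant: percent optimal on reward trials against
#' percent optimal on punishment trials, with chance (50%) and the
#' below-chance boundary (35% on reward trials) marked.
#'
#' @param summaries A tibble from [score_cohort()], optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_reward_punishment <- function(summaries) {
  aes <- if ("group" %in% names(summaries)) {
    ggplot2::aes(x = .data$pct_optimal_reward,
                 y = .data$pct_optimal_punishment, color = .data$group)
  } else {
    ggplot2::aes(x = .data$pct_optimal_reward,
                 y = .data$pct_optimal_punishment)
  }
  ggplot2::ggplot(summaries, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 50, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 35, linetype = "dashed") +
    ggplot2::labs(x = "% optimal, reward trials",
                  y = "% optimal, punishment trials") +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' @describeIn recovery_experiment True versus recovered parameter values,
#'   faceted by parameter, with the identity line.
#' @param object A `gl_recovery` object.
#' @export
autoplot.gl_recovery <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Recovered value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
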