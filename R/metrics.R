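#' Score a session the way the task is analyzed
#'
#' Computes percent-optimal responding separately over the reward trials and
#' the punishment trials (80 of each under the default configuration), the
#' same percentages per block, the final point total, solver flags, and a
#' below-chance flag. A participant is a *solver* on a trial type when the
#' optimal-response count reaches the exact-binomial criterion — at least
#' 65% optimal (52 of 80 under the defaults, the smallest count that beats
#' chance at two-tailed p < 0.01; see [criterion_count()]). The solver
#' threshold is inclusive (>= 52 of 80); the below-chance flag is strict
#' (< 35% optimal on reward trials, i.e. <= 27 of 80). Comparisons are made
#' on exact counts, not on rounded percentages.
#'
#' @param session A completed session tibble for one participant.
#' @param config The [task_config()] used to build the session.
#' @param alpha Significance level of the solver criterion (default 0.01,
#'   two-tailed).
#' @return A one-row tibble: `participant_id`, `pct_optimal_reward`,
#'   `pct_optimal_punishment`, per-block percentages in wide columns
#'   (`pct_reward_block1` ...), `total_points`, `solver_reward`,
#'   `solver_punishment`, `solver_any`, `below_chance_reward`.
#' @examples
#' sched <- build_session(task_config(), seed = 1)
#' sess <- simulate_agent(sched, agent_params(0.3, 0.3, 0.1, 0), seed = 2)
#' summarize_behavior(sess)
#' @export
summarize_behavior <- function(session, config = task_config(),
                               alpha = 0.01) {
  check_complete_session(session)
  if (!"optimal" %in% names(session) || anyNA(session$optimal)) {
    stop("session has no scored `optimal` column", call. = FALSE)
  }

  by_type <- session |>
    dplyr::group_by(.data$trial_type) |>
    dplyr::summarise(n = dplyr::n(), n_optimal = sum(.data$optimal),
                     .groups = "drop")
  get_type <- function(type, col) {
    v <- by_type[[col]][by_type$trial_type == type]
    if (length(v) == 0) 0L else v
  }
  n_rew <- get_type("reward", "n")
  n_pun <- get_type("punishment", "n")
  k_rew <- get_type("reward", "n_optimal")
  k_pun <- get_type("punishment", "n_optimal")
  if (n_rew == 0 || n_pun == 0) {
    stop("session must contain both reward and punishment trials",
         call. = FALSE)
  }
  crit_rew <- criterion_count(n_rew, alpha)
  crit_pun <- criterion_count(n_pun, alpha)

  per_block <- session |>
    dplyr::group_by(.data$block, .data$trial_type) |>
    dplyr::summarise(pct = 100 * mean(.data$optimal), .groups = "drop") |>
    dplyr::mutate(name = sprintf("pct_%s_block%d", .data$trial_type,
                                 .data$block)) |>
    dplyr::select("name", "pct") |>
    tidyr::pivot_wider(names_from = "name", values_from = "pct")

  dplyr::bind_cols(
    tibble::tibble(
      participant_id = session$participant_id[1],
      pct_optimal_reward = 100 * k_rew / n_rew,
      pct_optimal_punishment = 100 * k_pun / n_pun,
      total_points = config$initial_points + sum(session$points_delta),
      solver_reward = k_rew >= crit_rew,
      solver_punishment = k_pun >= crit_pun,
      below_chance_reward = k_rew < 0.35 * n_rew
    ),
    per_block
  ) |>
    dplyr::mutate(solver_any = .data$solver_reward | .data$solver_punishment,
                  .after = "solver_punishment")
}

#' Score every participant in a table of sessions
#'
#' @param sessions A stacked session log tibble.
#' @inheritParams summarize_behavior
#' @return A tibble with one [summarize_behavior()] row per participant.
#' @export
score_cohort <- function(sessions, config = task_config(), alpha = 0.01) {
  sessions |>
    dplyr::group_split(.data$participant_id) |>
    purrr::map_dfr(summarize_behavior, config = config, alpha = alpha)
}

#' Smallest optimal-response count that beats chance
#'
#' Returns the smallest count `k` of optimal responses out of `n_trials`
#' whose exact two-tailed binomial test against chance (p = 0.5) is
#' significant at level `alpha`. With 80 trials and alpha = 0.01 this is 52,
#' i.e. 65% optimal — the solver criterion.
#'
#' @param n_trials Number of trials of the given type.
#' @param alpha Two-tailed significance level.
#' @return The minimal above-chance count (integer).
#' @examples
#' criterion_count(80, 0.01) # 52
#' @export
criterion_count <- function(n_trials, alpha = 0.01) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  for (k in seq(ceiling(n_trials / 2), n_trials)) {
    if (exact_binomial_two_tailed(k, n_trials, 0.5) < alpha) {
      return(as.integer(k))
    }
  }
  as.integer(n_trials) + 1L
}
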