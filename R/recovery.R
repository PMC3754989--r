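#' Uniform sampler over grid nodes
#'
#' Returns a sampler function drawing each parameter independently and
#' uniformly from the candidate values of a [grid_spec()], for use as the
#' `sampler` of [recovery_experiment()]. Sampling true values on grid nodes
#' makes exact recovery possible in principle.
#'
#' @param grid A [grid_spec()].
#' @return A `function(n)` returning an n-row tibble of parameter draws.
#' @export
grid_node_sampler <- function(grid = grid_spec()) {
  stopifnot(inherits(grid, "gl_grid"))
  function(n) {
    tibble::tibble(
      alpha_gain = sample(grid$alpha_gain, n, replace = TRUE),
      alpha_loss = sample(grid$alpha_loss, n, replace = TRUE),
      beta = sample(grid$beta, n, replace = TRUE),
      r0 = sample(grid$r0, n, replace = TRUE)
    )
  }
}

# undefined (rather than a warning) when either margin is constant
rank_cor_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Parameter-recovery experiment
#'
#' Validates the estimation pipeline on ground truth: for each of
#' `n_agents` simulated agents, true parameters are sampled, a fresh
#' schedule is built, the agent plays it, and the session is refit by
#' [grid_fit()]. The report pairs true with recovered values and
#' summarizes per-parameter bias (mean recovered minus true), mean absolute
#' error, and Spearman rank correlation. Deterministic for a fixed seed.
#'
#' @param n_agents Number of simulated agents (>= 1).
#' @param sampler A `function(n)` returning a tibble of true parameter
#'   draws with columns `alpha_gain`, `alpha_loss`, `beta`, `r0`; defaults
#'   to [grid_node_sampler()] over `grid`.
#' @param config [task_config()] used for every schedule.
#' @param grid [grid_spec()] used for every fit.
#' @param seed Master integer seed.
#' @return An object of class `gl_recovery`: `pairs` (long tibble of
#'   participant, parameter, true, recovered) and `summary` (one row per
#'   parameter: bias, mae, spearman). [tidy()] returns the pairs,
#'   [glance()] the summary.
#' @examples
#' rec <- recovery_experiment(4, grid = grid_spec(r0 = seq(-1, 1, 0.5)),
#'                            seed = 7)
#' glance(rec)
#' @export
recovery_experiment <- function(n_agents,
                                sampler = grid_node_sampler(grid),
                                config = task_config(),
                                grid = grid_spec(),
                                seed) {
  stopifnot(n_agents >= 1)
  draws <- withr::with_seed(seed, {
    list(
      true = sampler(n_agents),
      schedule_seed = sample.int(.Machine$integer.max - 1L, n_agents),
      agent_seed = sample.int(.Machine$integer.max - 1L, n_agents)
    )
  })
  true <- dplyr::mutate(
    draws$true,
    participant_id = sprintf("agent_%03d", seq_len(n_agents)),
    .before = 1
  )

  recovered <- purrr::pmap_dfr(
    list(true$participant_id, true$alpha_gain, true$alpha_loss, true$beta,
         true$r0, draws$schedule_seed, draws$agent_seed),
    function(pid, ag, al, b, r0, s_seed, a_seed) {
      sched <- build_session(config, seed = s_seed, participant_id = pid)
      sess <- simulate_agent(sched, agent_params(ag, al, b, r0),
                             seed = a_seed, config = config)
      tidy(grid_fit(sess, grid))
    }
  )

  pairs <- dplyr::bind_rows(
    true = tidyr::pivot_longer(true,
                               c("alpha_gain", "alpha_loss", "beta", "r0"),
                               names_to = "parameter"),
    recovered = tidyr::pivot_longer(
      recovered[c("participant_id", "alpha_gain", "alpha_loss", "beta",
                  "r0")],
      c("alpha_gain", "alpha_loss", "beta", "r0"), names_to = "parameter"),
    .id = "role"
  ) |>
    tidyr::pivot_wider(names_from = "role", values_from = "value")

  summary <- pairs |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      bias = mean(.data$recovered - .data$true),
      mae = mean(abs(.data$recovered - .data$true)),
      spearman = rank_cor_or_na(.data$true, .data$recovered),
      .groups = "drop"
    )

  structure(
    list(pairs = pairs, summary = summary, fits = recovered,
         n_agents = n_agents, seed = seed, grid = grid),
    class = "gl_recovery"
  )
}

#' @export
print.gl_recovery <- function(x, ...) {
  cat(sprintf("<gl_recovery> %d agent(s), seed %s\n", x$n_agents,
              format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @rdname recovery_experiment
#' @param x A `gl_recovery` object.
#' @param ... Unused.
#' @export
tidy.gl_recovery <- function(x, ...) x$pairs

#' @rdname recovery_experiment
#' @export
glance.gl_recovery <- function(x, ...) x$summary
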