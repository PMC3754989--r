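#' Task configuration for the probabilistic reward/punishment learning task
#'
#' Defines the structure of a session of the probabilistic classification
#' task. Four abstract stimuli are each probabilistically associated with a
#' majority category (80% of appearances under the defaults) and assigned a
#' trial type: on *reward* trials a correct classification gains points and
#' an incorrect one yields no feedback; on *punishment* trials an incorrect
#' classification loses points and a correct one yields no feedback. The
#' no-feedback outcome is therefore ambiguous: it can signal either a missed
#' reward or a successfully avoided punishment.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param trials_per_stimulus Trials per stimulus per block (default 10).
#' @param common_per_stimulus How many of those trials sample the stimulus's
#'   majority category (default 8, i.e. an 80/20 split).
#' @param reward_points Points gained on a correct reward trial (default 25).
#' @param punishment_points Points lost (negative) on an incorrect punishment
#'   trial (default -25).
#' @param initial_points Starting point tally (default 500). The tally may go
#'   negative; no floor is applied.
#' @param stimulus_roles A data frame with columns `stimulus`,
#'   `majority_category` and `trial_type` mapping each of the four stimuli to
#'   its majority category and trial type. The default assigns S1 = (A,
#'   reward), S2 = (B, reward), S3 = (A, punishment), S4 = (B, punishment).
#'
#' @return A list of class `gl_task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_blocks
#' @export
task_config <- function(n_blocks = 4L,
                        trials_per_stimulus = 10L,
                        common_per_stimulus = 8L,
                        reward_points = 25L,
                        punishment_points = -25L,
                        initial_points = 500L,
                        stimulus_roles = default_stimulus_roles()) {
  stimulus_roles <- tibble::as_tibble(stimulus_roles)
  stopifnot(
    n_blocks >= 1, trials_per_stimulus >= 1,
    common_per_stimulus >= 0,
    all(c("stimulus", "majority_category", "trial_type") %in%
          names(stimulus_roles))
  )
  if (common_per_stimulus > trials_per_stimulus) {
    stop("`common_per_stimulus` must not exceed `trials_per_stimulus`",
         call. = FALSE)
  }
  if (nrow(stimulus_roles) != 4L ||
      anyDuplicated(stimulus_roles$stimulus) > 0L) {
    stop("`stimulus_roles` must define exactly 4 distinct stimuli",
         call. = FALSE)
  }
  if (!all(sort(table(stimulus_roles$trial_type)) == c(2L, 2L)) ||
      !setequal(stimulus_roles$trial_type, c("reward", "punishment"))) {
    stop("each trial type (reward, punishment) must cover exactly 2 stimuli",
         call. = FALSE)
  }
  if (!all(stimulus_roles$majority_category %in% c("A", "B"))) {
    stop("majority categories must be 'A' or 'B'", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_stimulus = as.integer(trials_per_stimulus),
      common_per_stimulus = as.integer(common_per_stimulus),
      reward_points = as.integer(reward_points),
      punishment_points = as.integer(punishment_points),
      initial_points = as.integer(initial_points),
      stimulus_roles = stimulus_roles
    ),
    class = "gl_task_config"
  )
}

default_stimulus_roles <- function() {
  tibble::tibble(
    stimulus = c("S1", "S2", "S3", "S4"),
    majority_category = c("A", "B", "A", "B"),
    trial_type = c("reward", "reward", "punishment", "punishment")
  )
}

#' Build a trial schedule for one session
#'
#' Generates the trial-by-trial schedule of a session: within each block,
#' every stimulus appears exactly `trials_per_stimulus` times, of which
#' exactly `common_per_stimulus` carry the stimulus's majority category and
#' the remainder its minority category (the per-block composition is exact,
#' not sampled independently per trial). Trial order is uniformly shuffled
#' within each block. The schedule carries no responses; see
#' [simulate_agent()] to play it with a model agent or [play_responses()] to
#' apply an observed response vector.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param participant_id Identifier recorded on every row.
#'
#' @return A tibble with one row per trial and columns `participant_id`,
#'   `trial` (1-based), `block` (1-based), `stimulus`, `trial_type`,
#'   `sampled_category` (the category the stimulus belongs to on this trial)
#'   and `optimal_category` (the majority category, the basis of optimal
#'   responding regardless of the trial's sampled category).
#' @examples
#' sched <- build_session(task_config(), seed = 1)
#' nrow(sched) # 160
#' @export
build_session <- function(config = task_config(), seed,
                          participant_id = "agent") {
  stopifnot(inherits(config, "gl_task_config"))
  roles <- config$stimulus_roles
  n_common <- config$common_per_stimulus
  n_rare <- config$trials_per_stimulus - n_common

  block_template <- purrr::pmap_dfr(
    roles,
    function(stimulus, majority_category, trial_type) {
      minority <- setdiff(c("A", "B"), majority_category)
      tibble::tibble(
        stimulus = stimulus,
        trial_type = trial_type,
        sampled_category = c(rep(majority_category, n_common),
                             rep(minority, n_rare)),
        optimal_category = majority_category
      )
    }
  )

  withr::with_seed(seed, {
    session <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
      dplyr::mutate(
        block_template[sample.int(nrow(block_template)), ],
        block = b, .before = 1
      )
    })
  })

  dplyr::mutate(session,
                participant_id = participant_id,
                trial = dplyr::row_number(),
                .before = 1)
}

#' Resolve the feedback and point change for a response
#'
#' Applies the task's feedback rule: a *correct* response (matching the
#' trial's sampled category) on a reward trial yields reward feedback and a
#' point gain; an *incorrect* response on a punishment trial yields
#' punishment feedback and a point loss; every other combination yields no
#' feedback and no point change. All arguments are vectorized over trials.
#'
#' @param trial_type `"reward"` or `"punishment"` per trial.
#' @param sampled_category The category the stimulus belongs to on the trial.
#' @param response The emitted response, `"A"` or `"B"`.
#' @param config A [task_config()] supplying the point values.
#'
#' @return A tibble with columns `feedback` (`"reward"`, `"punishment"` or
#'   `"none"`) and `points_delta`.
#' @examples
#' resolve_outcome("reward", "A", "A") # reward, +25
#' resolve_outcome("punishment", "A", "B") # punishment, -25
#' @export
resolve_outcome <- function(trial_type, sampled_category, response,
                            config = task_config()) {
  stopifnot(all(response %in% c("A", "B")),
            all(trial_type %in% c("reward", "punishment")))
  correct <- response == sampled_category
  feedback <- dplyr::case_when(
    trial_type == "reward" & correct ~ "reward",
    trial_type == "punishment" & !correct ~ "punishment",
    TRUE ~ "none"
  )
  points_delta <- dplyr::case_when(
    feedback == "reward" ~ as.integer(config$reward_points),
    feedback == "punishment" ~ as.integer(config$punishment_points),
    TRUE ~ 0L
  )
  tibble::tibble(feedback = feedback, points_delta = points_delta)
}

#' Is a response optimal?
#'
#' A response is optimal when it matches the stimulus's majority category,
#' regardless of the category the stimulus was sampled into on that
#' particular trial (and hence regardless of the feedback received).
#' Vectorized.
#'
#' @param response Response, `"A"` or `"B"`.
#' @param optimal_category The stimulus's majority category.
#' @return Logical vector.
#' @examples
#' is_optimal("A", "A")
#' @export
is_optimal <- function(response, optimal_category) {
  stopifnot(all(response %in% c("A", "B")))
  response == optimal_category
}

#' Apply a response vector to a schedule
#'
#' Fills a schedule with responses and resolves each trial: correctness,
#' optimality, feedback, point change, and the running point tally starting
#' from `initial_points`.
#'
#' @param schedule A schedule from [build_session()].
#' @param responses Character vector of `"A"`/`"B"`, one per trial.
#' @param config The [task_config()] used to build the schedule.
#' @return The schedule tibble with columns `response`, `correct`, `optimal`,
#'   `feedback`, `points_delta` and `cumulative_points` appended.
#' @export
play_responses <- function(schedule, responses, config = task_config()) {
  if (length(responses) != nrow(schedule)) {
    stop("`responses` must supply one response per trial", call. = FALSE)
  }
  out <- resolve_outcome(schedule$trial_type, schedule$sampled_category,
                         responses, config)
  dplyr::mutate(
    schedule,
    response = responses,
    correct = .data$response == .data$sampled_category,
    optimal = is_optimal(.data$response, .data$optimal_category),
    feedback = out$feedback,
    points_delta = out$points_delta,
    cumulative_points = config$initial_points + cumsum(out$points_delta)
  )
}
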