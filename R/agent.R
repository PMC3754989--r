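#' Parameters of the gain-loss reinforcement-learning model
#'
#' The model carries four free parameters. `alpha_gain` and `alpha_loss` are
#' learning rates applied when an outcome is better (positive prediction
#' error) or worse (negative prediction error) than expected. `beta` is the
#' softmax inverse-gain parameter in \[0, 1\]: low values make choice nearly
#' deterministic toward the higher expectancy, high values make it nearly
#' random; `beta = 0` is defined by its greedy limit. `r0` is the
#' reinforcement value attributed to the ambiguous no-feedback outcome and
#' may range from the punishment value (-1) to the reward value (+1): near 0
#' the outcome is treated as neutral, near +1 as akin to a successfully
#' avoided punishment, near -1 as akin to a missed reward. The reinforcement
#' values of explicit reward (`r_plus`) and punishment (`r_minus`) are fixed
#' at +1 and -1.
#'
#' @param alpha_gain Learning rate for positive prediction errors, in \[0, 1\].
#' @param alpha_loss Learning rate for negative prediction errors, in \[0, 1\].
#' @param beta Softmax inverse gain, in \[0, 1\].
#' @param r0 Reinforcement value of the no-feedback outcome, in
#'   \[`r_minus`, `r_plus`\].
#' @param r_plus,r_minus Fixed reinforcement values of reward and punishment.
#'
#' @return A list of class `gl_params`.
#' @examples
#' agent_params(0.27, 0.23, 0.34, 0.36)
#' @export
agent_params <- function(alpha_gain, alpha_loss, beta, r0,
                         r_plus = 1, r_minus = -1) {
  stopifnot(
    alpha_gain >= 0, alpha_gain <= 1,
    alpha_loss >= 0, alpha_loss <= 1,
    beta >= 0, beta <= 1,
    r0 >= r_minus, r0 <= r_plus
  )
  structure(
    list(alpha_gain = alpha_gain, alpha_loss = alpha_loss, beta = beta,
         r0 = r0, r_plus = r_plus, r_minus = r_minus),
    class = "gl_params"
  )
}

#' @export
print.gl_params <- function(x, ...) {
  cat(sprintf(
    "<gl_params> alpha_gain=%.3g alpha_loss=%.3g beta=%.3g r0=%.3g\n",
    x$alpha_gain, x$alpha_loss, x$beta, x$r0))
  invisible(x)
}

#' Softmax choice probabilities for a two-alternative choice
#'
#' Computes `Pr(A) = exp(Q_A / beta) / (exp(Q_A / beta) + exp(Q_B / beta))`
#' in a numerically stable form. At `beta = 0` the greedy limit is taken:
#' probability 1 for the larger expectancy, and 0.5 each on ties.
#' Vectorized over `q_a` and `q_b`.
#'
#' @param q_a,q_b Expectancy values of responses A and B.
#' @param beta Softmax inverse gain in \[0, 1\].
#' @return A tibble with columns `pr_a` and `pr_b` summing to 1.
#' @examples
#' choice_probabilities(1, 0, 0.5) # pr_a ~= 0.8808
#' @export
choice_probabilities <- function(q_a, q_b, beta) {
  stopifnot(beta >= 0, beta <= 1)
  if (beta == 0) {
    pr_a <- ifelse(q_a > q_b, 1, ifelse(q_a < q_b, 0, 0.5))
  } else {
    pr_a <- stats::plogis((q_a - q_b) / beta)
  }
  # new_tibble keeps this hot path cheap inside trial-by-trial replays
  tibble::new_tibble(list(pr_a = pr_a, pr_b = 1 - pr_a),
                     nrow = length(pr_a))
}

#' Reinforcement value of a feedback outcome
#'
#' Maps each feedback kind to its reinforcement value: reward to `r_plus`
#' (+1), punishment to `r_minus` (-1), and the ambiguous no-feedback outcome
#' to the free parameter `r0`. Vectorized over `feedback`.
#'
#' @param feedback `"reward"`, `"punishment"` or `"none"`.
#' @param params An [agent_params()] object.
#' @return Numeric vector of reinforcement values.
#' @export
reinforcement_value <- function(feedback, params) {
  if (!all(feedback %in% c("reward", "punishment", "none"))) {
    stop("unknown feedback kind", call. = FALSE)
  }
  unname(c(reward = params$r_plus, punishment = params$r_minus,
           none = params$r0)[feedback])
}

#' Prediction error
#'
#' `PE = R - Q[r, s]`: the difference between the reinforcement received and
#' the current expectancy of the emitted response; positive when the outcome
#' is better than expected.
#'
#' @param r Reinforcement value received.
#' @param q_current Current expectancy of the chosen (response, stimulus)
#'   pair.
#' @return Numeric prediction error.
#' @export
prediction_error <- function(r, q_current) {
  r - q_current
}

#' Initialize an expectancy table
#'
#' A 2 x 4 matrix of expectancy values `Q[response, stimulus]`, all zero at
#' the start of a session.
#'
#' @param stimuli Stimulus identifiers (columns).
#' @return A numeric matrix with rows `A`, `B`.
#' @export
init_qtable <- function(stimuli = c("S1", "S2", "S3", "S4")) {
  matrix(0, nrow = 2, ncol = length(stimuli),
         dimnames = list(c("A", "B"), stimuli))
}

#' Update an expectancy table after one trial
#'
#' Applies the asymmetric update to the chosen (response, stimulus) entry
#' only: the increment is `alpha_gain * PE` for positive prediction errors
#' and `alpha_loss * PE` for negative ones; a zero prediction error leaves
#' the table unchanged. Unchosen and unseen entries are never updated.
#'
#' @param qtable Matrix from [init_qtable()].
#' @param stimulus Stimulus id (column name).
#' @param response `"A"` or `"B"` (row name).
#' @param pe Prediction error for the trial.
#' @param params An [agent_params()] object.
#' @return The updated expectancy table.
#' @export
apply_update <- function(qtable, stimulus, response, pe, params) {
  stopifnot(is.finite(pe))
  rate <- if (pe > 0) params$alpha_gain else params$alpha_loss
  qtable[response, stimulus] <- qtable[response, stimulus] + rate * pe
  qtable
}

#' Simulate a model agent playing a session
#'
#' Plays a schedule generatively: on each trial the response is sampled from
#' the softmax over the current expectancies, the task resolves the outcome,
#' and the expectancy of the sampled response is updated from the prediction
#' error of the feedback actually received. Deterministic for a fixed seed.
#'
#' @param schedule A schedule from [build_session()].
#' @param params An [agent_params()] object.
#' @param seed Integer seed for the response sampling.
#' @param config The [task_config()] used to build the schedule.
#' @return A completed session tibble (see [play_responses()]).
#' @examples
#' sched <- build_session(task_config(), seed = 1)
#' sess <- simulate_agent(sched, agent_params(0.3, 0.3, 0.2, 0.5), seed = 2)
#' @export
simulate_agent <- function(schedule, params, seed, config = task_config()) {
  stopifnot(inherits(params, "gl_params"))
  n <- nrow(schedule)
  stimulus <- schedule$stimulus
  trial_type <- schedule$trial_type
  sampled <- schedule$sampled_category
  stimuli <- unique(config$stimulus_roles$stimulus)
  q <- init_qtable(stimuli)
  responses <- character(n)

  withr::with_seed(seed, {
    u <- stats::runif(n)
  })
  for (t in seq_len(n)) {
    s <- stimulus[t]
    pr_a <- choice_probabilities(q["A", s], q["B", s], params$beta)$pr_a
    resp <- if (u[t] < pr_a) "A" else "B"
    responses[t] <- resp
    out <- resolve_outcome(trial_type[t], sampled[t], resp, config)
    r <- reinforcement_value(out$feedback, params)
    pe <- prediction_error(r, q[resp, s])
    if (pe != 0) q <- apply_update(q, s, resp, pe, params)
  }
  play_responses(schedule, responses, config)
}
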