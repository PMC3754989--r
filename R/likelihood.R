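#' Parameter grid for maximum-likelihood estimation
#'
#' The estimator is an exhaustive search over a Cartesian grid. The default
#' grid steps the two learning rates and the inverse gain from 0 to 1 in
#' steps of 0.05 and the no-feedback value from -1 to +1 in steps of 0.1,
#' for 21^4 = 194,481 points.
#'
#' @param alpha_gain,alpha_loss,beta,r0 Numeric vectors of candidate values
#'   for each parameter; each is sorted ascending and must lie in the
#'   parameter's legal range.
#' @return A list of class `gl_grid` with a `size` attribute.
#' @examples
#' g <- grid_spec()
#' prod(lengths(g[c("alpha_gain", "alpha_loss", "beta", "r0")])) # 194481
#' @export
grid_spec <- function(alpha_gain = seq(0, 1, by = 0.05),
                      alpha_loss = seq(0, 1, by = 0.05),
                      beta = seq(0, 1, by = 0.05),
                      r0 = seq(-1, 1, by = 0.1)) {
  vals <- list(alpha_gain = sort(unique(alpha_gain)),
               alpha_loss = sort(unique(alpha_loss)),
               beta = sort(unique(beta)),
               r0 = sort(unique(r0)))
  if (any(lengths(vals) == 0L)) {
    stop("every grid dimension needs at least one value", call. = FALSE)
  }
  stopifnot(
    all(vals$alpha_gain >= 0 & vals$alpha_gain <= 1),
    all(vals$alpha_loss >= 0 & vals$alpha_loss <= 1),
    all(vals$beta >= 0 & vals$beta <= 1),
    all(vals$r0 >= -1 & vals$r0 <= 1)
  )
  structure(vals, class = "gl_grid", size = prod(lengths(vals)))
}

#' @export
print.gl_grid <- function(x, ...) {
  cat(sprintf("<gl_grid> %d points (%d x %d x %d x %d)\n", attr(x, "size"),
              length(x$alpha_gain), length(x$alpha_loss), length(x$beta),
              length(x$r0)))
  invisible(x)
}

check_complete_session <- function(session) {
  needed <- c("stimulus", "response", "feedback")
  missing_cols <- setdiff(needed, names(session))
  if (length(missing_cols) > 0) {
    stop("session is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(session$response) | is.na(session$feedback))
  if (length(bad) > 0) {
    stop("session has missing response/feedback at trial(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(session)
}

session_codes <- function(session) {
  stim_levels <- sort(unique(session$stimulus))
  list(
    stim = match(session$stimulus, stim_levels) - 1L,
    resp = match(session$response, c("A", "B")) - 1L,
    fb = c(reward = 1L, punishment = -1L, none = 0L)[session$feedback]
  )
}

#' Log-likelihood of an observed session under the gain-loss model
#'
#' Replays the session trial by trial: the probability of the participant's
#' actual response is computed from the current expectancy table, its log is
#' accumulated, and the table is then updated using the actual response and
#' the feedback actually received. The result is the sum of log
#' probabilities over all trials (the LLE), which is always <= 0; it is
#' `-Inf` only when some trial has probability exactly 0, which can occur
#' only in the greedy limit `beta = 0`.
#'
#' This is the plain reference implementation; [grid_fit()] uses an
#' optimized evaluation that is tested to agree with it.
#'
#' @param session A completed session tibble (every trial has a `response`
#'   and a `feedback`).
#' @param params An [agent_params()] object.
#' @return The log-likelihood (a single number <= 0).
#' @examples
#' sched <- build_session(task_config(), seed = 1)
#' sess <- simulate_agent(sched, agent_params(0.3, 0.3, 0.2, 0.5), seed = 2)
#' session_log_likelihood(sess, agent_params(0, 0, 0.5, 0)) # 160 * log(0.5)
#' @export
session_log_likelihood <- function(session, params) {
  stopifnot(inherits(params, "gl_params"))
  check_complete_session(session)
  q <- init_qtable(sort(unique(session$stimulus)))
  lle <- 0
  for (t in seq_len(nrow(session))) {
    s <- session$stimulus[t]
    resp <- session$response[t]
    pr <- choice_probabilities(q["A", s], q["B", s], params$beta)
    p <- if (resp == "A") pr$pr_a else pr$pr_b
    if (p == 0) return(-Inf)
    lle <- lle + log(p)
    r <- reinforcement_value(session$feedback[t], params)
    pe <- prediction_error(r, q[resp, s])
    if (pe != 0) q <- apply_update(q, s, resp, pe, params)
  }
  lle
}

#' Fit the gain-loss model to one session by exhaustive grid search
#'
#' Evaluates the session log-likelihood at every point of the grid and
#' returns the maximizer (the largest LLE, i.e. closest to 0). Ties are
#' broken deterministically: the first point in ascending lexicographic
#' order over (alpha_gain, alpha_loss, beta, r0) is returned and the number
#' of tied points is reported. No probability flooring is applied; grid
#' points with `beta = 0` get `-Inf` unless the session is perfectly
#' consistent with greedy choice, which removes them from contention without
#' special-casing.
#'
#' @param session A completed session tibble for a single participant.
#' @param grid A [grid_spec()].
#' @param tie_tol Absolute tolerance within which two log-likelihoods are
#'   treated as tied (guards floating-point noise in genuinely identical
#'   likelihoods).
#' @return An object of class `gl_fit` with elements `best_params`
#'   ([agent_params()]), `lle`, `n_ties`, `grid`, `participant_id` and
#'   `n_trials`. Use [tidy()] for a one-row tibble.
#' @examples
#' sched <- build_session(task_config(), seed = 1)
#' sess <- simulate_agent(sched, agent_params(0.3, 0.3, 0.2, 0.5), seed = 2)
#' fit <- grid_fit(sess, grid_spec(r0 = seq(-1, 1, 0.5)))
#' tidy(fit)
#' @export
grid_fit <- function(session, grid = grid_spec(), tie_tol = 1e-9) {
  stopifnot(inherits(grid, "gl_grid"))
  check_complete_session(session)
  if (length(unique(session$stimulus)) > 8) {
    stop("at most 8 distinct stimuli are supported", call. = FALSE)
  }
  codes <- session_codes(session)
  lle <- grid_loglik_cpp(codes$stim, codes$resp, codes$fb,
                         grid$alpha_gain, grid$alpha_loss, grid$beta,
                         grid$r0)
  best <- max(lle)
  tied <- which(lle >= best - tie_tol)
  idx <- tied[1] - 1L
  nR <- length(grid$r0); nB <- length(grid$beta); nL <- length(grid$alpha_loss)
  iR <- idx %% nR
  iB <- (idx %/% nR) %% nB
  iL <- (idx %/% (nR * nB)) %% nL
  iG <- idx %/% (nR * nB * nL)
  structure(
    list(
      best_params = agent_params(grid$alpha_gain[iG + 1],
                                 grid$alpha_loss[iL + 1],
                                 grid$beta[iB + 1],
                                 grid$r0[iR + 1]),
      lle = best,
      n_ties = length(tied),
      grid = grid,
      participant_id = session$participant_id[1],
      n_trials = nrow(session)
    ),
    class = "gl_fit"
  )
}

#' @export
print.gl_fit <- function(x, ...) {
  cat(sprintf("<gl_fit> %s: LLE = %.3f (%d trial(s), %d tie(s))\n",
              x$participant_id, x$lle, x$n_trials, x$n_ties))
  print(x$best_params)
  invisible(x)
}

#' @rdname grid_fit
#' @param x A `gl_fit` object.
#' @param ... Unused.
#' @export
tidy.gl_fit <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    alpha_gain = x$best_params$alpha_gain,
    alpha_loss = x$best_params$alpha_loss,
    beta = x$best_params$beta,
    r0 = x$best_params$r0,
    lle = x$lle,
    n_ties = x$n_ties
  )
}

#' @rdname grid_fit
#' @export
glance.gl_fit <- function(x, ...) {
  tibble::tibble(
    lle = x$lle,
    n_ties = x$n_ties,
    grid_size = attr(x$grid, "size"),
    n_trials = x$n_trials
  )
}

#' Fit every participant in a table of sessions
#'
#' Splits a stacked session log by `participant_id`, fits each participant
#' with [grid_fit()], and binds the tidied results into a fit table.
#'
#' @param sessions A session log tibble holding one or more participants.
#' @param grid A [grid_spec()].
#' @param .progress Print one line per participant as fitting proceeds.
#' @return A tibble with one row per participant: `participant_id`,
#'   `alpha_gain`, `alpha_loss`, `beta`, `r0`, `lle`, `n_ties`.
#' @export
fit_cohort <- function(sessions, grid = grid_spec(), .progress = FALSE) {
  if (nrow(sessions) == 0) stop("no sessions supplied", call. = FALSE)
  sessions |>
    dplyr::group_split(.data$participant_id) |>
    purrr::map_dfr(function(one) {
      if (isTRUE(.progress)) {
        message("fitting ", one$participant_id[1])
      }
      tidy(grid_fit(one, grid))
    })
}
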