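#' Read and write session logs
#'
#' Session logs are plain CSV, UTF-8, comma-separated, with a mandatory
#' header and one row per trial: `participant_id`, `trial` (1-based),
#' `block` (1-based), `stimulus`, `trial_type`, `sampled_category`,
#' `optimal_category`, `response`, `correct`, `optimal`, `feedback`,
#' `points_delta`, `cumulative_points`. The reader validates categorical
#' columns and reports the first offending row on failure.
#'
#' @param sessions A session tibble (possibly several participants).
#' @param path File path.
#' @return `write_session_log()` returns `sessions` invisibly;
#'   `read_session_log()` returns the session tibble.
#' @export
write_session_log <- function(sessions, path) {
  readr::write_csv(sessions, path)
  invisible(sessions)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    trial = readr::col_integer(),
    block = readr::col_integer(),
    stimulus = readr::col_character(),
    trial_type = readr::col_character(),
    sampled_category = readr::col_character(),
    optimal_category = readr::col_character(),
    response = readr::col_character(),
    correct = readr::col_logical(),
    optimal = readr::col_logical(),
    feedback = readr::col_character(),
    points_delta = readr::col_integer(),
    cumulative_points = readr::col_integer()
  ))
  if (nrow(x) == 0) stop("empty session log: ", path, call. = FALSE)
  checks <- list(
    trial_type = c("reward", "punishment"),
    sampled_category = c("A", "B"),
    optimal_category = c("A", "B"),
    response = c("A", "B"),
    feedback = c("reward", "punishment", "none")
  )
  for (col in names(checks)) {
    bad <- which(!x[[col]] %in% checks[[col]])
    if (length(bad) > 0) {
      stop(sprintf("invalid `%s` value %s at row %d of %s", col,
                   deparse(x[[col]][bad[1]]), bad[1], path),
           call. = FALSE)
    }
  }
  x
}

#' Read and write fit tables
#'
#' Fit tables hold one row per participant with the grid-search estimates:
#' `participant_id`, `alpha_gain`, `alpha_loss`, `beta`, `r0`, `lle`,
#' `n_ties`.
#'
#' @param fits A fit table from [fit_cohort()].
#' @param path File path.
#' @export
write_fit_table <- function(fits, path) {
  readr::write_csv(fits, path)
  invisible(fits)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    alpha_gain = readr::col_double(),
    alpha_loss = readr::col_double(),
    beta = readr::col_double(),
    r0 = readr::col_double(),
    lle = readr::col_double(),
    n_ties = readr::col_integer()
  ))
}

#' Read and write cohort manifests
#'
#' The manifest records, per synthetic participant, the group label, true
#' generating parameters, covariate labels, and the per-agent seeds.
#'
#' @param manifest A manifest tibble from [generate_cohort()].
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_guess()
  ))
}

#' Write a behavioral summary table
#'
#' @param summaries A tibble from [score_cohort()].
#' @param path File path.
#' @export
write_summary_table <- function(summaries, path) {
  readr::write_csv(summaries, path)
  invisible(summaries)
}
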