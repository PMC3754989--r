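#' Truncated-normal distribution specification
#'
#' Parameter values for synthetic agents are drawn from normal distributions
#' truncated to the parameter's legal range, so sampled values are always
#' valid. Sampling uses inverse-CDF transformation, which is exact and
#' reproducible.
#'
#' @param mean,sd Center and spread of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @return A list of class `gl_dist`.
#' @export
trunc_normal <- function(mean, sd, lower, upper) {
  stopifnot(sd > 0, lower < upper)
  structure(list(family = "truncnorm", mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "gl_dist")
}

sample_dist <- function(dist, n) {
  stopifnot(inherits(dist, "gl_dist"))
  p_lo <- stats::pnorm(dist$lower, dist$mean, dist$sd)
  p_hi <- stats::pnorm(dist$upper, dist$mean, dist$sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), dist$mean, dist$sd)
}

#' Specification of one synthetic group
#'
#' Describes a group of simulated participants: its size and the
#' distributions its agents' model parameters are drawn from, plus optional
#' categorical covariate proportions (labels only — covariates have no
#' behavioral effect) used to exercise contingency-table statistics.
#'
#' @param label Group label (e.g. `"control"`, `"ptss"`).
#' @param n Number of participants.
#' @param alpha_gain,alpha_loss,beta,r0 [trunc_normal()] specifications for
#'   each model parameter, truncated to the parameter's legal range.
#' @param covariates Named list of named numeric vectors of category
#'   proportions (each summing to 1), e.g.
#'   `list(combat = c(yes = 0.33, no = 0.67))`.
#' @return A list of class `gl_group_spec`.
#' @export
group_spec <- function(label, n,
                       alpha_gain = trunc_normal(0.27, 0.32, 0, 1),
                       alpha_loss = trunc_normal(0.23, 0.34, 0, 1),
                       beta = trunc_normal(0.34, 0.27, 0, 1),
                       r0 = trunc_normal(0, 0.2, -1, 1),
                       covariates = list()) {
  stopifnot(n >= 1)
  for (d in list(alpha_gain, alpha_loss, beta, r0)) {
    stopifnot(inherits(d, "gl_dist"))
  }
  stopifnot(alpha_gain$lower >= 0, alpha_gain$upper <= 1,
            alpha_loss$lower >= 0, alpha_loss$upper <= 1,
            beta$lower >= 0, beta$upper <= 1,
            r0$lower >= -1, r0$upper <= 1)
  structure(
    list(label = label, n = as.integer(n),
         param_distributions = list(alpha_gain = alpha_gain,
                                    alpha_loss = alpha_loss,
                                    beta = beta, r0 = r0),
         covariates = covariates),
    class = "gl_group_spec"
  )
}

#' Specification of a synthetic cohort
#'
#' @param groups List of [group_spec()] objects.
#' @param config A [task_config()] shared by all groups.
#' @return A list of class `gl_cohort_spec`.
#' @export
cohort_spec <- function(groups, config = task_config()) {
  stopifnot(length(groups) >= 1,
            all(purrr::map_lgl(groups, inherits, "gl_group_spec")),
            inherits(config, "gl_task_config"))
  structure(list(groups = groups, config = config),
            class = "gl_cohort_spec")
}

#' Default two-group cohort presets
#'
#' A control group of 39 and a PTSS group of 48 participants, the reference
#' cohort design this pipeline targets. Both groups share the same
#' learning-rate and inverse-gain distributions (truncated normals around
#' the cohort-wide estimates: alpha_gain 0.27 (SD 0.32), alpha_loss 0.23
#' (SD 0.34), beta 0.34 (SD 0.27)); they differ only in the no-feedback
#' value `r0`, centered at 0.5 for the control group and at 0 for the PTSS
#' group (spread 0.2), the configuration under which control agents treat
#' no-feedback as partially rewarding and are thereby selectively impaired
#' on reward trials. Covariate label proportions follow the reference
#' cohort's demographic counts.
#'
#' @param config A [task_config()].
#' @return A [cohort_spec()] with two groups.
#' @examples
#' spec <- default_presets()
#' purrr::map_int(spec$groups, "n") # 39, 48
#' @export
default_presets <- function(config = task_config()) {
  cohort_spec(
    groups = list(
      group_spec(
        "control", 39,
        r0 = trunc_normal(0.5, 0.2, -1, 1),
        covariates = list(
          combat = c(yes = 13 / 39, no = 26 / 39),
          medication = c(yes = 11 / 39, no = 28 / 39),
          bi = c(inhibited = 12 / 39, uninhibited = 14 / 39,
                 inconsistent = 13 / 39)
        )
      ),
      group_spec(
        "ptss", 48,
        r0 = trunc_normal(0, 0.2, -1, 1),
        covariates = list(
          combat = c(yes = 22 / 48, no = 26 / 48),
          medication = c(yes = 37 / 48, no = 11 / 48),
          bi = c(inhibited = 28 / 48, uninhibited = 6 / 48,
                 inconsistent = 14 / 48)
        )
      )
    ),
    config = config
  )
}

# exact label counts by largest remainder, then a uniform shuffle
assign_labels <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  sample(rep(names(props), times = base))
}

#' Generate a synthetic cohort of simulated participants
#'
#' For each agent: draw true model parameters from the group's
#' distributions, build a fresh trial schedule, and simulate the agent
#' playing it. All randomness is funneled through the single master seed,
#' so outputs (sessions and manifest) are fully reproducible.
#'
#' @param spec A [cohort_spec()], e.g. [default_presets()].
#' @param seed Master integer seed.
#' @return A list of class `gl_cohort` with `sessions` (stacked session log
#'   tibble, one row per trial) and `manifest` (one row per agent:
#'   `participant_id`, `group`, true parameter values, covariate labels,
#'   per-agent seeds).
#' @examples
#' cohort <- generate_cohort(default_presets(), seed = 42)
#' nrow(cohort$manifest) # 87
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "gl_cohort_spec"))
  manifest <- withr::with_seed(seed, {
    purrr::map_dfr(spec$groups, function(g) {
      params <- purrr::map(g$param_distributions, sample_dist, n = g$n)
      covs <- purrr::map(g$covariates, assign_labels, n = g$n)
      tibble::tibble(
        participant_id = sprintf("%s_%02d", g$label, seq_len(g$n)),
        group = g$label,
        alpha_gain = params$alpha_gain,
        alpha_loss = params$alpha_loss,
        beta = params$beta,
        r0 = params$r0,
        !!!covs,
        schedule_seed = sample.int(.Machine$integer.max - 1L, g$n),
        agent_seed = sample.int(.Machine$integer.max - 1L, g$n)
      )
    })
  })

  sessions <- purrr::pmap_dfr(
    manifest[c("participant_id", "alpha_gain", "alpha_loss", "beta", "r0",
               "schedule_seed", "agent_seed")],
    function(participant_id, alpha_gain, alpha_loss, beta, r0,
             schedule_seed, agent_seed) {
      sched <- build_session(spec$config, seed = schedule_seed,
                             participant_id = participant_id)
      simulate_agent(sched,
                     agent_params(alpha_gain, alpha_loss, beta, r0),
                     seed = agent_seed, config = spec$config)
    }
  )

  structure(list(sessions = sessions, manifest = manifest, seed = seed),
            class = "gl_cohort")
}

#' @export
print.gl_cohort <- function(x, ...) {
  cat(sprintf("<gl_cohort> %d participant(s), %d trial rows (seed %s)\n",
              nrow(x$manifest), nrow(x$sessions), format(x$seed)))
  print(dplyr::count(x$manifest, .data$group))
  invisible(x)
}
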