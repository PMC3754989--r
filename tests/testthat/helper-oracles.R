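# Independent reference implementations used as oracles. These deliberately
# take the slowest, most literal route so they share no code path with the
# optimized implementations they check.

# Exhaustive quadruple loop over the grid, evaluating the naive R replay at
# every point; first maximizer in ascending lexicographic order.
naive_grid_fit_oracle <- function(session, grid) {
  best_lle <- -Inf
  best <- NULL
  n_ties <- 0L
  for (ag in grid$alpha_gain) {
    for (al in grid$alpha_loss) {
      for (b in grid$beta) {
        for (r0 in grid$r0) {
          lle <- session_log_likelihood(session,
                                        agent_params(ag, al, b, r0))
          if (lle > best_lle + 1e-9) {
            best_lle <- lle
            best <- c(alpha_gain = ag, alpha_loss = al, beta = b, r0 = r0)
            n_ties <- 1L
          } else if (abs(lle - best_lle) <= 1e-9) {
            n_ties <- n_ties + 1L
          }
        }
      }
    }
  }
  list(params = best, lle = best_lle, n_ties = n_ties)
}

# Exact two-tailed binomial p-value at p0 = 0.5 by enumeration of all n + 1
# outcomes: the total probability of outcomes at least as far from n/2 as k.
enum_binom_two_tailed_half <- function(k, n) {
  i <- 0:n
  sum(stats::dbinom(i[abs(i - n / 2) >= abs(k - n / 2)], n, 0.5))
}

# A complete simulated session in one call.
make_session <- function(alpha_gain = 0.3, alpha_loss = 0.3, beta = 0.2,
                         r0 = 0, schedule_seed = 1, agent_seed = 2,
                         config = task_config(),
                         participant_id = "p1") {
  sched <- build_session(config, seed = schedule_seed,
                         participant_id = participant_id)
  simulate_agent(sched, agent_params(alpha_gain, alpha_loss, beta, r0),
                 seed = agent_seed, config = config)
}
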