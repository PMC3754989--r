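test_that("non-learning parameters give the closed-form likelihood", {
  # alpha_gain = alpha_loss = 0 keeps Q at 0, so every trial has
  # probability 0.5 and the LLE is n * ln(0.5) regardless of beta and r0
  sess <- make_session()
  for (p in list(agent_params(0, 0, 0.5, 0),
                 agent_params(0, 0, 0.05, 0.9),
                 agent_params(0, 0, 1, -1))) {
    expect_equal(session_log_likelihood(sess, p), 160 * log(0.5),
                 tolerance = 1e-12)
  }
})

test_that("a trial predicted with certainty contributes zero log-likelihood", {
  # two trials of the same reward stimulus, both answered A and rewarded:
  # with alpha_gain = 1 the first update drives Q[A, S1] to 1, so a greedy
  # agent assigns probability 1 to the second response. Only the first
  # (all-zero Q, tie) trial contributes, at log(0.5).
  sched <- build_session(task_config(), seed = 1)
  two <- sched[sched$stimulus == "S1" & sched$sampled_category == "A", ][1:2, ]
  sess <- play_responses(two, c("A", "A"))
  expect_equal(session_log_likelihood(sess, agent_params(1, 1, 0, 0)),
               log(0.5), tolerance = 1e-12)
  # ...and a greedy-inconsistent response has probability 0: LLE = -Inf
  sess_bad <- play_responses(two, c("A", "B"))
  expect_identical(session_log_likelihood(sess_bad, agent_params(1, 1, 0, 0)),
                   -Inf)
})

test_that("log-likelihood is never positive", {
  withr::with_seed(21, {
    draws <- data.frame(ag = runif(5), al = runif(5), b = runif(5, 0.05, 1),
                        r0 = runif(5, -1, 1))
  })
  sess <- make_session(schedule_seed = 9, agent_seed = 10)
  for (i in seq_len(nrow(draws))) {
    p <- agent_params(draws$ag[i], draws$al[i], draws$b[i], draws$r0[i])
    expect_lte(session_log_likelihood(sess, p), 0)
  }
})

test_that("incomplete sessions are rejected", {
  sched <- build_session(task_config(), seed = 1)
  expect_error(session_log_likelihood(sched, agent_params(0, 0, 0.5, 0)),
               "missing column")
  sess <- make_session()
  sess$response[10] <- NA
  expect_error(session_log_likelihood(sess, agent_params(0, 0, 0.5, 0)),
               "trial\\(s\\) 10")
  expect_error(grid_fit(sess), "trial\\(s\\) 10")
})

test_that("the default grid has 21^4 points on the stated lattice", {
  g <- grid_spec()
  expect_equal(attr(g, "size"), 21^4)
  expect_equal(g$alpha_gain, seq(0, 1, by = 0.05))
  expect_equal(g$r0, seq(-1, 1, by = 0.1))
  expect_error(grid_spec(beta = numeric(0)), "at least one value")
})

test_that("optimized grid evaluation matches the naive replay everywhere", {
  reduced <- grid_spec(alpha_gain = seq(0, 1, 0.25),
                       alpha_loss = seq(0, 1, 0.25),
                       beta = seq(0, 1, 0.25),
                       r0 = seq(-1, 1, 0.5))
  sess <- make_session(0.5, 0.25, 0.25, 0.5, schedule_seed = 3,
                       agent_seed = 4)
  codes <- gainloss:::session_codes(sess)
  fast <- gainloss:::grid_loglik_cpp(codes$stim, codes$resp, codes$fb,
                                     reduced$alpha_gain, reduced$alpha_loss,
                                     reduced$beta, reduced$r0)
  i <- 0L
  for (ag in reduced$alpha_gain) {
    for (al in reduced$alpha_loss) {
      for (b in reduced$beta) {
        for (r0 in reduced$r0) {
          i <- i + 1L
          slow <- session_log_likelihood(sess,
                                         agent_params(ag, al, b, r0))
          if (is.finite(slow)) {
            expect_equal(fast[i], slow, tolerance = 1e-9)
          } else {
            expect_identical(fast[i], slow)
          }
        }
      }
    }
  }
})

test_that("grid_fit agrees with the quadruple-loop oracle", {
  reduced <- grid_spec(alpha_gain = seq(0, 1, 0.25),
                       alpha_loss = seq(0, 1, 0.25),
                       beta = seq(0.25, 1, 0.25),
                       r0 = seq(-1, 1, 0.5))
  withr::with_seed(31, {
    draws <- data.frame(ag = runif(5), al = runif(5), b = runif(5, 0.1, 1),
                        r0 = runif(5, -1, 1))
  })
  for (i in seq_len(nrow(draws))) {
    sess <- make_session(draws$ag[i], draws$al[i], draws$b[i], draws$r0[i],
                         schedule_seed = 40 + i, agent_seed = 50 + i)
    fit <- grid_fit(sess, reduced)
    oracle <- naive_grid_fit_oracle(sess, reduced)
    expect_equal(fit$lle, oracle$lle, tolerance = 1e-9)
    expect_equal(unlist(tidy(fit)[c("alpha_gain", "alpha_loss", "beta",
                                    "r0")]),
                 oracle$params, tolerance = 1e-12)
    expect_equal(fit$n_ties, oracle$n_ties)
  }
})

test_that("the fitted maximum dominates the generating parameters", {
  gen <- agent_params(0.3, 0.2, 0.25, 0.5) # all on default grid nodes
  sess <- make_session(0.3, 0.2, 0.25, 0.5, schedule_seed = 6,
                       agent_seed = 7)
  fit <- grid_fit(sess)
  expect_gte(fit$lle, session_log_likelihood(sess, gen) - 1e-9)
})

test_that("ties are counted and broken lexicographically", {
  # a non-learning grid makes the likelihood flat: every (beta, r0) point
  # ties at 160 ln(0.5) and the first lexicographic point is returned
  sess <- make_session(schedule_seed = 8, agent_seed = 9)
  flat_grid <- grid_spec(alpha_gain = 0, alpha_loss = 0,
                         beta = seq(0, 1, 0.05), r0 = seq(-1, 1, 0.1))
  fit <- grid_fit(sess, flat_grid)
  expect_equal(fit$n_ties, 21 * 21)
  expect_equal(fit$lle, 160 * log(0.5), tolerance = 1e-9)
  expect_equal(tidy(fit)$beta, 0)
  expect_equal(tidy(fit)$r0, -1)

  # a feedback-insensitive (random) responder ties on the full grid too
  sched <- build_session(task_config(), seed = 3)
  withr::with_seed(9, {
    resp <- sample(c("A", "B"), 160, replace = TRUE)
  })
  rand_fit <- grid_fit(play_responses(sched, resp))
  expect_gt(rand_fit$n_ties, 1)
  expect_gte(rand_fit$lle, 160 * log(0.5))
})

test_that("trial order matters exactly when learning is on", {
  sess <- make_session(0.4, 0.3, 0.2, 0.3, schedule_seed = 12,
                       agent_seed = 13)
  perm <- withr::with_seed(14, sample.int(nrow(sess)))
  shuffled <- sess[perm, ]
  flat <- agent_params(0, 0, 0.5, 0)
  expect_equal(session_log_likelihood(shuffled, flat),
               session_log_likelihood(sess, flat), tolerance = 1e-12)
  learning <- agent_params(0.4, 0.3, 0.2, 0.3)
  expect_false(isTRUE(all.equal(
    session_log_likelihood(shuffled, learning),
    session_log_likelihood(sess, learning), tolerance = 1e-6
  )))
})

test_that("fit_cohort returns one tidy row per participant", {
  cfg <- task_config(n_blocks = 1)
  reduced <- grid_spec(alpha_gain = seq(0, 1, 0.5),
                       alpha_loss = seq(0, 1, 0.5),
                       beta = seq(0.25, 1, 0.25), r0 = seq(-1, 1, 0.5))
  sessions <- dplyr::bind_rows(
    make_session(config = cfg, schedule_seed = 1, agent_seed = 2,
                 participant_id = "p1"),
    make_session(config = cfg, schedule_seed = 3, agent_seed = 4,
                 participant_id = "p2")
  )
  fits <- fit_cohort(sessions, reduced)
  expect_equal(fits$participant_id, c("p1", "p2"))
  one <- grid_fit(sessions[sessions$participant_id == "p2", ], reduced)
  expect_equal(fits[2, ], tidy(one))
  expect_error(fit_cohort(sessions[0, ]), "no sessions")
})
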