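
test_that("state initialisation sets both value matrices to 1/n_a", {
  st <- init_state(3L, 3L)
  expect_equal(st$q_rl, matrix(1 / 3, 3, 3))
  expect_equal(st$q_wm, matrix(1 / 3, 3, 3))
  st5 <- init_state(5L, 3L)
  expect_equal(dim(st5$q_rl), c(5L, 3L))
  expect_true(all(st5$q_wm == 1 / 3))
  expect_error(init_state(3L, 1L), "n_a")
})

test_that("value updates match direct substitution in the update rules", {
  p <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 0.05)
  st <- init_state(3L, 3L)
  # positive feedback: 1/3 + 0.1*(1 - 1/3) = 0.4
  st1 <- update_rl(st, 1L, 2L, 1L, p)
  expect_equal(st1$q_rl[1, 2], 0.4, tolerance = 1e-12)
  expect_equal(st1$q_rl[-1, ], st$q_rl[-1, ])
  # negative feedback from 0.4: 0.4 + 0.1*0.5*(0 - 0.4) = 0.38
  st2 <- update_rl(st1, 1L, 2L, 0L, p)
  expect_equal(st2$q_rl[1, 2], 0.38, tolerance = 1e-12)
  # alpha = 0 leaves the state unchanged
  p0 <- rlwm_params(1e-9, 0.5, 0.25, 0.8, 3, 0.05)
  expect_equal(update_rl(st, 1L, 1L, 1L, p0)$q_rl, st$q_rl,
               tolerance = 1e-8)

  # WM: positive feedback is one-shot to exactly 1
  w1 <- update_wm(st, 2L, 3L, 1L, p)
  expect_identical(w1$q_wm[2, 3], 1)
  # negative feedback shrinks by (1 - gamma): 1 * (1 - 0.5)... with gamma 0.2
  p2 <- rlwm_params(0.1, 0.2, 0.25, 0.8, 3, 0.05)
  w2 <- update_wm(w1, 2L, 3L, 0L, p2)
  expect_equal(w2$q_wm[2, 3], 0.8, tolerance = 1e-12)

  expect_error(update_rl(st, 9L, 1L, 1L, p), "stimulus")
  expect_error(update_rl(st, 1L, 1L, 2, p), "r")
})

test_that("WM decay relaxes toward 1/n_a and is exactly geometric", {
  p <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 0.05)
  st <- init_state(2L, 3L)
  st$q_wm[1, 1] <- 1
  d1 <- decay_wm(st, p)
  expect_equal(d1$q_wm[1, 1], 1 + 0.25 * (1 / 3 - 1), tolerance = 1e-12)
  expect_equal(d1$q_rl, st$q_rl)
  # phi = 1: full decay in one step
  p1 <- rlwm_params(0.1, 0.5, 1 - 1e-12, 0.8, 3, 0.05)
  expect_equal(decay_wm(st, p1)$q_wm, matrix(1 / 3, 2, 3), tolerance = 1e-9)
  # after m decays from v: 1/n_a + (1-phi)^m * (v - 1/n_a), exactly
  v <- 0.9
  st$q_wm[2, 2] <- v
  cur <- st
  for (m in 1:7) cur <- decay_wm(cur, p)
  expect_equal(cur$q_wm[2, 2], 1 / 3 + 0.75^7 * (v - 1 / 3),
               tolerance = 1e-12)
})

test_that("softmax is symmetric, saturating and overflow-safe at beta 100", {
  expect_equal(softmax_policy(rep(1 / 3, 3), 100), rep(1 / 3, 3))
  p <- softmax_policy(c(0.9, 0.1, 0.1), 100)
  expect_equal(p[1], 1 / (1 + 2 * exp(-80)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(softmax_policy(c(5, -3, 2), 0), rep(1 / 3, 3))
  expect_false(any(is.nan(softmax_policy(c(1e4, 0), 100))))
  expect_error(softmax_policy(numeric(0)), "empty")
})

test_that("mixture weight implements rho * min(1, C/ss)", {
  p <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 0.05)
  expect_equal(mixture_weight(p, 5L), 0.48, tolerance = 1e-12)
  expect_equal(mixture_weight(p, 2L), 0.8)
  expect_equal(mixture_weight(p, 3L), 0.8)
  p0 <- rlwm_params(0.1, 0.5, 0.25, 1e-12, 3, 0.05)
  expect_equal(mixture_weight(p0, 4L), 1e-12 * 3 / 4)
})

test_that("policy mixing and lapse mixing match direct substitution", {
  # pol_mix = (1-omega)*pol_rl + omega*pol_wm with omega = 0.48
  pol_rl <- c(0.2, 0.5, 0.3); pol_wm <- c(1, 0, 0)
  expect_equal((1 - 0.48) * pol_rl + 0.48 * pol_wm,
               c(0.584, 0.26, 0.156), tolerance = 1e-12)
  # epsilon = 1 forces the uniform policy
  p_eps1 <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 1 - 1e-12)
  st <- init_state(3L, 3L)
  st$q_rl[1, 1] <- 0.99
  pol <- action_policy(st, 1L, p_eps1)
  expect_equal(pol$pol_final, rep(1 / 3, 3), tolerance = 1e-9)
  # epsilon = 0.1 on a degenerate mixture
  expect_equal((1 - 0.1) * c(1, 0, 0) + 0.1 / 3,
               c(0.9333333333, 0.0333333333, 0.0333333333),
               tolerance = 1e-9)
})

test_that("all four policies are valid distributions on fuzzed states", {
  set.seed(88)
  for (rep in 1:25) {
    ss <- sample(2:5, 1)
    p <- rlwm_params(runif(1, .01, .29), runif(1, .05, .95),
                     runif(1, .05, .95), runif(1, .05, .95),
                     sample(2:5, 1), runif(1, .01, .5))
    st <- init_state(ss, 3L)
    st$q_rl[] <- runif(ss * 3)
    st$q_wm[] <- runif(ss * 3)
    pol <- action_policy(st, sample(ss, 1), p)
    for (nm in c("pol_rl", "pol_wm", "pol_mix", "pol_final")) {
      expect_equal(sum(pol[[nm]]), 1, tolerance = 1e-12)
      expect_true(all(pol[[nm]] >= 0))
    }
    expect_equal(pol$omega, p$rho * min(1, p$capacity / ss))
  }
})

test_that("RPE uses the cooperative mixed expectation with a pure-RL switch", {
  p <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 0.05)
  st <- init_state(2L, 3L)
  st$q_wm[1, 1] <- 1; st$q_rl[1, 1] <- 0.4
  expect_equal(trial_rpe(st, 1L, 1L, 1L, omega = 0.5), 0.3,
               tolerance = 1e-12)
  expect_equal(trial_rpe(st, 1L, 1L, 1L, omega = 0), 0.6,
               tolerance = 1e-12)
  expect_equal(trial_rpe(st, 1L, 1L, 1L, omega = 0.5, form = "rl"), 0.6)
  # outcome equal to the expectation gives zero
  st$q_wm[1, 2] <- 0.5; st$q_rl[1, 2] <- 0.5
  expect_equal(trial_rpe(st, 1L, 2L, 0.5, omega = 0.3), 0)
})

test_that("trial step, latents and likelihood match the independent trace", {
  # 6-trial block, ss = 2: a mixed correct/incorrect sequence
  stim <- c(1L, 2L, 1L, 2L, 1L, 2L)
  action <- c(1L, 3L, 1L, 2L, 2L, 2L)
  reward <- c(1L, 0L, 1L, 1L, 0L, 1L)
  pars <- list(alpha = 0.2, gamma = 0.5, phi = 0.1, rho = 0.9,
               capacity = 2, epsilon = 0.05)
  oracle <- do.call(oracle_trace,
                    c(list(stim, action, reward, ss = 2L, n_a = 3L), pars))
  p <- with(pars, rlwm_params(alpha, gamma, phi, rho, capacity, epsilon))
  trials <- data.frame(block = 1L, trial = 1:6, set_size = 2L,
                       stimulus = stim, action = action, correct = reward)
  for (lat in list(compute_latents_r(p, trials), compute_latents(p, trials))) {
    expect_equal(lat$q_rl_chosen, oracle$q_rl_chosen, tolerance = 1e-10)
    expect_equal(lat$q_wm_chosen, oracle$q_wm_chosen, tolerance = 1e-10)
    expect_equal(lat$omega, oracle$omega, tolerance = 1e-10)
    expect_equal(lat$rpe, oracle$rpe, tolerance = 1e-10)
    expect_equal(lat$choice_prob, oracle$choice_prob, tolerance = 1e-10)
  }
  nll_oracle <- -sum(log(oracle$choice_prob))
  expect_equal(session_nll_r(p, trials), nll_oracle, tolerance = 1e-10)
  expect_equal(session_nll(p, trials), nll_oracle, tolerance = 1e-10)
})

test_that("compiled and reference likelihoods agree on fuzzed sessions", {
  set.seed(17)
  for (rep in 1:10) {
    p <- rlwm_params(runif(1, .01, .29), runif(1, .05, .95),
                     runif(1, .05, .95), runif(1, .05, .95),
                     sample(2:5, 1), runif(1, .01, .5))
    sim <- simulated_session(seed = 100L + rep, params = p)
    expect_equal(session_nll(p, sim$trials), session_nll_r(p, sim$trials),
                 tolerance = 1e-10)
    lr <- compute_latents_r(p, sim$trials)
    lc <- compute_latents(p, sim$trials)
    expect_equal(as.matrix(lr[3:8]), as.matrix(lc[3:8]), tolerance = 1e-10)
  }
})

test_that("likelihood limits: uniform policy, additivity, block resets", {
  p1 <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 1 - 1e-12)
  sim <- simulated_session(seed = 21L)
  # epsilon = 1: NLL = T log(3) for any action sequence
  expect_equal(session_nll(p1, sim$trials), nrow(sim$trials) * log(3),
               tolerance = 1e-6)
  # duplicating the session (as a new block pair) doubles the NLL
  p <- demo_params()
  t2 <- sim$trials
  t2$block <- t2$block + max(sim$trials$block)
  both <- rbind(sim$trials, t2)
  expect_equal(session_nll(p, both), 2 * session_nll(p, sim$trials),
               tolerance = 1e-10)
  expect_error(session_nll(p, sim$trials[rev(seq_len(nrow(sim$trials))), ]),
               "ordered")
})

test_that("Q values stay in [0,1] and follow the closed-form learning curve", {
  p <- rlwm_params(0.25, 0.6, 0.3, 0.8, 3, 0.05)
  st <- init_state(2L, 3L)
  # k consecutive rewards: Q_RL = 1 - (1-alpha)^k * (1 - 1/n_a)
  for (k in 1:10) {
    st <- update_rl(st, 1L, 1L, 1L, p)
    expect_equal(st$q_rl[1, 1], 1 - (1 - 0.25)^k * (1 - 1 / 3),
                 tolerance = 1e-12)
  }
  # fuzzed update sequences keep both matrices in [0,1]
  set.seed(4)
  st <- init_state(3L, 3L)
  for (i in 1:200) {
    s <- sample(3L, 1); a <- sample(3L, 1); r <- sample(0:1, 1)
    st <- decay_wm(st, p)
    st <- update_wm(st, s, a, r, p)
    st <- update_rl(st, s, a, r, p)
    expect_true(all(st$q_rl >= 0 & st$q_rl <= 1))
    expect_true(all(st$q_wm >= 0 & st$q_wm <= 1))
  }
})

test_that("agent simulation respects its limits and determinism", {
  cfg <- tiny_config()
  skel <- generate_session(cfg, seed = 3)
  # near-uniform lapse keeps accuracy near chance
  p_noise <- rlwm_params(0.1, 0.5, 0.25, 0.8, 3, 0.999)
  accs <- vapply(1:10, function(i) {
    mean(simulate_agent(p_noise, skel, seed = i)$trials$correct)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.06)
  # strong WM within capacity: near ceiling from iteration 2 onward
  p_wm <- rlwm_params(0.05, 0.6, 0.05, 0.95, 5, 0.01)
  skel2 <- generate_session(task_config(set_sizes = 2L,
                                        iterations_per_stimulus = 10L),
                            seed = 5)
  sim2 <- simulate_agent(p_wm, skel2, seed = 6)
  late <- sim2$trials$correct[sim2$trials$iteration >= 2]
  expect_gt(mean(late), 0.9)
  # determinism
  expect_identical(simulate_agent(demo_params(), skel, seed = 11),
                   simulate_agent(demo_params(), skel, seed = 11))
})

test_that("pure-RL accuracy tracks the 1-(1-alpha)^k value envelope", {
  # with rho ~ 0, learning is driven by Q_RL alone; after k rewards the
  # value gap implies near-argmax choice once it clears the soft window
  p <- rlwm_params(0.25, 0.6, 0.3, 1e-9, 3, 0.02)
  cfg <- task_config(set_sizes = 3L, iterations_per_stimulus = 10L)
  correct <- matrix(NA_real_, 40, 10)
  for (i in 1:40) {
    skel <- generate_session(cfg, seed = 800 + i)
    sim <- simulate_agent(p, skel, seed = 900 + i)
    correct[i, ] <- tapply(sim$trials$correct, sim$trials$iteration, mean)
  }
  curve <- colMeans(correct)
  # monotone-ish growth toward ceiling clearly above chance
  expect_gt(mean(curve[7:10]), 0.9)
  expect_lt(curve[1], 0.5)
  expect_gt(stats::cor(seq_len(9), curve[2:10]), 0.5)
})
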