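# Small shared fixtures built in code. Sizes are chosen so the whole
# non-acceptance suite stays fast while still exercising multi-block,
# multi-set-size structure.

tiny_config <- function() {
  task_config(set_sizes = c(2L, 3L), iterations_per_stimulus = 6L, seed = 1L)
}

demo_params <- function() {
  rlwm_params(alpha = 0.2, gamma = 0.5, phi = 0.1, rho = 0.9,
              capacity = 2, epsilon = 0.05)
}

simulated_session <- function(seed = 42L, config = tiny_config(),
                              params = demo_params()) {
  skel <- generate_session(config, seed = seed)
  simulate_agent(params, skel, seed = seed + 1L)
}

# one-subject epoch simulation on a reduced grid for fast GLM tests
small_montage <- function(n = 8L) scalp_montage()[seq_len(n), , drop = FALSE]

# Straight-line oracle for the model equations: an independently coded
# trace that composes the per-trial arithmetic directly, against which the
# package's step/latents/likelihood implementations are checked.
oracle_trace <- function(stim, action, reward, ss, n_a, alpha, gamma, phi,
                         rho, capacity, epsilon, beta = 100) {
  q_rl <- matrix(1 / n_a, ss, n_a)
  q_wm <- matrix(1 / n_a, ss, n_a)
  omega <- rho * min(1, capacity / ss)
  n <- length(stim)
  out <- data.frame(q_rl_chosen = numeric(n), q_wm_chosen = numeric(n),
                    omega = numeric(n), rpe = numeric(n),
                    choice_prob = numeric(n))
  soft <- function(q) { e <- exp(beta * (q - max(q))); e / sum(e) }
  for (t in seq_len(n)) {
    s <- stim[t]; a <- action[t]; r <- reward[t]
    q_wm <- q_wm + phi * (1 / n_a - q_wm)            # decay
    p_rl <- soft(q_rl[s, ]); p_wm <- soft(q_wm[s, ])
    p_mix <- (1 - omega) * p_rl + omega * p_wm
    p_fin <- (1 - epsilon) * p_mix + epsilon / n_a
    out$q_rl_chosen[t] <- q_rl[s, a]
    out$q_wm_chosen[t] <- q_wm[s, a]
    out$omega[t] <- omega
    out$rpe[t] <- r - (omega * q_wm[s, a] + (1 - omega) * q_rl[s, a])
    out$choice_prob[t] <- p_fin[a]
    if (r == 1) {
      q_wm[s, a] <- 1
      q_rl[s, a] <- q_rl[s, a] + alpha * (1 - q_rl[s, a])
    } else {
      q_wm[s, a] <- q_wm[s, a] + gamma * (0 - q_wm[s, a])
      q_rl[s, a] <- q_rl[s, a] + alpha * gamma * (0 - q_rl[s, a])
    }
  }
  out
}
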