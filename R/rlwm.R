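#' RL-WM model parameters
#'
#' Parameter vector of the mixture model of instrumental learning in which a
#' slow, incremental reinforcement-learning (RL) module and a fast,
#' capacity-limited, decaying working-memory (WM) module jointly drive
#' choice. The inverse temperature `beta` is fixed at 100 and the WM
#' learning rate `alpha_wm` at 1 (one-shot WM updating); neither is ever a
#' free parameter.
#'
#' @param alpha RL learning rate, constrained to (0, 0.3) to keep the RL
#'   module identifiable against the one-shot WM module.
#' @param gamma perseveration parameter in (0, 1): the weight on negative
#'   feedback in both modules' updates (lower = greater neglect of errors).
#' @param phi WM decay rate in (0, 1): per-trial relaxation of WM values
#'   toward their initial value 1/n_a.
#' @param rho baseline WM reliance in (0, 1).
#' @param capacity integer WM capacity C in \{2, 3, 4, 5\}.
#' @param epsilon lapse rate in (0, 1): probability of an undirected random
#'   choice.
#' @return An object of class `rlwm_params`.
#' @examples
#' p <- rlwm_params(alpha = 0.15, gamma = 0.6, phi = 0.2, rho = 0.8,
#'                  capacity = 3, epsilon = 0.05)
#' @export
rlwm_params <- function(alpha, gamma, phi, rho, capacity, epsilon) {
  capacity <- as.integer(capacity)
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= lo || x >= hi) {
      stop(sprintf("`%s` must be a scalar in (%g, %g)", nm, lo, hi))
    }
  }
  chk(alpha, 0, 0.3, "alpha")
  chk(gamma, 0, 1, "gamma")
  chk(phi, 0, 1, "phi")
  chk(rho, 0, 1, "rho")
  chk(epsilon, 0, 1, "epsilon")
  if (!capacity %in% 2:5) stop("`capacity` must be an integer in 2..5")
  structure(
    list(alpha = alpha, gamma = gamma, phi = phi, rho = rho,
         capacity = capacity, epsilon = epsilon,
         beta = 100, alpha_wm = 1),
    class = "rlwm_params")
}

#' @export
print.rlwm_params <- function(x, ...) {
  cat(sprintf(
    "RL-WM parameters: alpha=%.4f gamma=%.4f phi=%.4f rho=%.4f C=%d epsilon=%.4f (beta=100, alpha_wm=1 fixed)\n",
    x$alpha, x$gamma, x$phi, x$rho, x$capacity, x$epsilon))
  invisible(x)
}

#' Initialise learner state for one block
#'
#' Both Q matrices start at the uninformative value 1/n_a in every cell.
#'
#' @param ss block set size (number of stimuli).
#' @param n_a number of actions (>= 2).
#' @return A `learner_state` list with `q_rl` and `q_wm` (ss x n_a matrices).
#' @export
init_state <- function(ss, n_a) {
  if (ss < 1L) stop("`ss` must be >= 1")
  if (n_a < 2L) stop("`n_a` must be >= 2")
  q0 <- matrix(1 / n_a, nrow = ss, ncol = n_a)
  structure(list(q_rl = q0, q_wm = q0, ss = as.integer(ss),
                 n_a = as.integer(n_a)),
            class = "learner_state")
}

.check_sa <- function(state, s, a = 1L) {
  if (s < 1L || s > state$ss) stop("stimulus index out of range")
  if (a < 1L || a > state$n_a) stop("action index out of range")
}

#' RL value update
#'
#' Positive feedback moves Q_RL(s,a) toward 1 at rate `alpha`; negative
#' feedback moves it toward 0 at the discounted rate `alpha * gamma`.
#'
#' @param state a `learner_state`.
#' @param s,a 1-based stimulus and action indices of the current trial.
#' @param r binary reward (correctness), 0 or 1.
#' @param params an [rlwm_params()].
#' @return Updated state.
#' @export
update_rl <- function(state, s, a, r, params) {
  .check_sa(state, s, a)
  if (!r %in% c(0, 1)) stop("`r` must be 0 or 1")
  q <- state$q_rl[s, a]
  state$q_rl[s, a] <- if (r == 1) q + params$alpha * (1 - q)
                      else        q + params$alpha * params$gamma * (0 - q)
  state
}

#' WM value update
#'
#' With the WM learning rate fixed at 1, positive feedback sets Q_WM(s,a)
#' to exactly 1; negative feedback shrinks it by the factor (1 - gamma).
#'
#' @inheritParams update_rl
#' @return Updated state.
#' @export
update_wm <- function(state, s, a, r, params) {
  .check_sa(state, s, a)
  if (!r %in% c(0, 1)) stop("`r` must be 0 or 1")
  state$q_wm[s, a] <- if (r == 1) 1
                      else state$q_wm[s, a] + params$gamma * (0 - state$q_wm[s, a])
  state
}

#' WM decay
#'
#' Every WM entry relaxes toward its initial value 1/n_a at rate `phi`;
#' RL values are untouched.
#'
#' @inheritParams update_rl
#' @return Updated state.
#' @export
decay_wm <- function(state, params) {
  q0 <- 1 / state$n_a
  state$q_wm <- state$q_wm + params$phi * (q0 - state$q_wm)
  state
}

#' Softmax choice probabilities
#'
#' Computed with max-subtraction so the fixed inverse temperature beta = 100
#' never overflows; exactly equal values receive exactly equal
#' probabilities.
#'
#' @param q numeric vector of action values.
#' @param beta inverse temperature.
#' @return Probability vector summing to 1.
#' @export
softmax_policy <- function(q, beta = 100) {
  if (length(q) == 0L) stop("empty value vector")
  if (any(!is.finite(q))) stop("non-finite action values")
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Blockwise WM weight
#'
#' omega = rho * min(1, C / ss): WM reliance saturates at `rho` when the
#' block's set size fits within capacity and falls off proportionally
#' beyond it.
#'
#' @param params an [rlwm_params()].
#' @param ss block set size.
#' @return Scalar omega in \[0, 1\].
#' @export
mixture_weight <- function(params, ss) {
  if (ss < 1L) stop("`ss` must be >= 1")
  params$rho * min(1, params$capacity / ss)
}

#' Full action policy for the current stimulus
#'
#' Computes the RL and WM softmax policies, their omega-weighted mixture,
#' and the final policy after mixing in the uniform lapse component with
#' weight epsilon.
#'
#' @inheritParams update_rl
#' @return A list with `pol_rl`, `pol_wm`, `pol_mix`, `pol_final`, `omega`.
#' @export
action_policy <- function(state, s, params) {
  .check_sa(state, s)
  pol_rl <- softmax_policy(state$q_rl[s, ], params$beta)
  pol_wm <- softmax_policy(state$q_wm[s, ], params$beta)
  omega <- mixture_weight(params, state$ss)
  pol_mix <- (1 - omega) * pol_rl + omega * pol_wm
  pol_final <- (1 - params$epsilon) * pol_mix + params$epsilon / state$n_a
  list(pol_rl = pol_rl, pol_wm = pol_wm, pol_mix = pol_mix,
       pol_final = pol_final, omega = omega)
}

#' Trialwise reward prediction error
#'
#' The cooperative account: the expectation against which the outcome is
#' compared mixes WM and RL values by the block's WM weight omega, so that
#' outcomes already predicted by WM produce smaller RPEs. `form = "rl"`
#' gives the pure-RL expectation r - Q_RL(s,a) for sensitivity analysis.
#'
#' @param state the pre-update (post-decay) state of the trial.
#' @param s,a stimulus and chosen action.
#' @param r binary reward.
#' @param omega the block's WM mixture weight.
#' @param form `"cooperative"` (default) or `"rl"`.
#' @return Scalar RPE in \[-1, 1\].
#' @export
trial_rpe <- function(state, s, a, r, omega, form = c("cooperative", "rl")) {
  form <- match.arg(form)
  .check_sa(state, s, a)
  expectation <- if (form == "cooperative") {
    omega * state$q_wm[s, a] + (1 - omega) * state$q_rl[s, a]
  } else {
    state$q_rl[s, a]
  }
  r - expectation
}

#' Execute one trial of the model
#'
#' Per-trial order: WM decay, then policy computation and latent recording
#' for the observed (s, a, r), then the WM and RL updates. Decay precedes
#' the trial's retrieval so that the values entering the policy are the
#' decayed ones; `decay = "after"` switches to post-update decay for
#' sensitivity analysis.
#'
#' @inheritParams update_rl
#' @param rpe_form passed to [trial_rpe()].
#' @param decay `"before"` (default) or `"after"` the trial's updates.
#' @return list(policy = PolicyBundle, latents = one-row data.frame,
#'   state = updated state).
#' @export
rlwm_step <- function(state, s, a, r, params,
                      rpe_form = c("cooperative", "rl"),
                      decay = c("before", "after")) {
  rpe_form <- match.arg(rpe_form)
  decay <- match.arg(decay)
  if (decay == "before") state <- decay_wm(state, params)
  pol <- action_policy(state, s, params)
  latents <- data.frame(
    q_rl_chosen = state$q_rl[s, a],
    q_wm_chosen = state$q_wm[s, a],
    q_mix_chosen = pol$omega * state$q_wm[s, a] +
      (1 - pol$omega) * state$q_rl[s, a],
    omega = pol$omega,
    rpe = trial_rpe(state, s, a, r, pol$omega, rpe_form),
    choice_prob = pol$pol_final[a])
  state <- update_wm(state, s, a, r, params)
  state <- update_rl(state, s, a, r, params)
  if (decay == "after") state <- decay_wm(state, params)
  list(policy = pol, latents = latents, state = state)
}

# Within-block stimulus ids can be arbitrary labels; recode to 1..ss.
.block_stim_index <- function(stimulus) {
  match(stimulus, sort(unique(stimulus)))
}

#' Per-trial latent traces for an observed session (reference implementation)
#'
#' Runs the model over the observed choices, resetting state at every block
#' boundary (each block introduces new stimuli), and records the per-trial
#' latents: chosen-action RL/WM/mixed values, omega, RPE and the final-policy
#' probability of the taken action.
#'
#' @param params an [rlwm_params()].
#' @param trials trial data.frame with `block`, `trial`, `set_size`,
#'   `stimulus`, `action` (1-based), `correct`.
#' @param n_a number of actions.
#' @inheritParams rlwm_step
#' @return data.frame of latents aligned to `trials` rows, plus the keys
#'   `block` and `trial`.
#' @export
compute_latents_r <- function(params, trials, n_a = 3L,
                              rpe_form = c("cooperative", "rl"),
                              decay = c("before", "after")) {
  rpe_form <- match.arg(rpe_form)
  decay <- match.arg(decay)
  .check_session(trials)
  out <- vector("list", length(unique(trials$block)))
  k <- 0L
  for (b in unique(trials$block)) {
    k <- k + 1L
    idx <- which(trials$block == b)
    ss <- trials$set_size[idx[1L]]
    sidx <- .block_stim_index(trials$stimulus[idx])
    state <- init_state(ss, n_a)
    rows <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      st <- rlwm_step(state, sidx[j], trials$action[i], trials$correct[i],
                      params, rpe_form, decay)
      state <- st$state
      rows[[j]] <- cbind(block = b, trial = trials$trial[i], st$latents)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

.check_session <- function(trials) {
  req <- c("block", "trial", "set_size", "stimulus", "action", "correct")
  if (!all(req %in% names(trials))) {
    stop("trials must contain columns: ", paste(req, collapse = ", "))
  }
  ord <- order(trials$block, trials$trial)
  if (!identical(ord, seq_len(nrow(trials)))) {
    stop("trials must be ordered by block then trial")
  }
  if (anyNA(trials$action) || anyNA(trials$correct)) {
    stop("actions and correctness must be observed (no NA)")
  }
  invisible(TRUE)
}

#' Session negative log-likelihood (reference implementation)
#'
#' -sum over trials of log pol_final(a_t), with state reset at each block
#' boundary. The lapse component bounds every choice probability away from
#' zero, so the result is finite for any admissible parameter vector.
#'
#' @inheritParams compute_latents_r
#' @return Scalar negative log-likelihood.
#' @export
session_nll_r <- function(params, trials, n_a = 3L,
                          decay = c("before", "after")) {
  lat <- compute_latents_r(params, trials, n_a, decay = decay)
  -sum(log(lat$choice_prob))
}

#' Session negative log-likelihood (compiled fast path)
#'
#' Identical model to [session_nll_r()] (agreement to 1e-10 is asserted in
#' the test suite); used by the fitting routines where the likelihood is
#' evaluated tens of thousands of times.
#'
#' @inheritParams session_nll_r
#' @export
session_nll <- function(params, trials, n_a = 3L,
                        decay = c("before", "after")) {
  decay <- match.arg(decay)
  .check_session(trials)
  arr <- .session_arrays(trials)
  rlwm_nll_cpp(arr$block_id, arr$set_size, arr$stim, trials$action,
               trials$correct, as.integer(n_a),
               params$alpha, params$gamma, params$phi, params$rho,
               as.integer(params$capacity), params$epsilon, params$beta,
               decay == "before")
}

#' Per-trial latents (compiled fast path)
#'
#' @inheritParams compute_latents_r
#' @export
compute_latents <- function(params, trials, n_a = 3L,
                            rpe_form = c("cooperative", "rl"),
                            decay = c("before", "after")) {
  rpe_form <- match.arg(rpe_form)
  decay <- match.arg(decay)
  .check_session(trials)
  arr <- .session_arrays(trials)
  m <- rlwm_latents_cpp(arr$block_id, arr$set_size, arr$stim, trials$action,
                        trials$correct, as.integer(n_a),
                        params$alpha, params$gamma, params$phi, params$rho,
                        as.integer(params$capacity), params$epsilon,
                        params$beta, decay == "before",
                        rpe_form == "cooperative")
  out <- as.data.frame(m)
  names(out) <- c("q_rl_chosen", "q_wm_chosen", "q_mix_chosen", "omega",
                  "rpe", "choice_prob")
  cbind(block = trials$block, trial = trials$trial, out)
}

# blockwise integer recoding shared by the compiled entry points
.session_arrays <- function(trials) {
  ublock <- unique(trials$block)
  block_id <- match(trials$block, ublock)
  stim <- integer(nrow(trials))
  set_size <- integer(nrow(trials))
  for (b in seq_along(ublock)) {
    idx <- which(block_id == b)
    stim[idx] <- .block_stim_index(trials$stimulus[idx])
    set_size[idx] <- trials$set_size[idx[1L]]
  }
  list(block_id = block_id, set_size = set_size, stim = stim)
}

#' Simulate an agent through a session skeleton
#'
#' Samples actions from the model's final policy. The correct action for
#' each stimulus is drawn once per block (uniformly) unless supplied;
#' rewards follow the 1-or-2-point scheme via [assign_reward()]. Response
#' times are generated from a log-normal whose location decreases with
#' choice confidence (decision latents do not otherwise constrain RT).
#'
#' @param params an [rlwm_params()].
#' @param skeleton session skeleton from [generate_session()].
#' @param seed integer seed.
#' @param p_two_points probability a correct response earns 2 points.
#' @param correct_actions optional named list mapping block to an
#'   integer vector of designated correct actions per stimulus.
#' @inheritParams rlwm_step
#' @return list(trials = completed trial data.frame with covariates,
#'   latents = latent trace data.frame).
#' @export
simulate_agent <- function(params, skeleton, seed = 1L, p_two_points = 0.5,
                           correct_actions = NULL,
                           rpe_form = c("cooperative", "rl"),
                           decay = c("before", "after")) {
  rpe_form <- match.arg(rpe_form)
  decay <- match.arg(decay)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  trials <- skeleton
  n_a <- 3L
  if ("n_actions" %in% names(attributes(skeleton))) {
    n_a <- attr(skeleton, "n_actions")
  }
  arr <- .session_arrays(trials)
  # designated correct action per trial, drawn blockwise before the
  # compiled generative pass
  ca_trial <- integer(nrow(trials))
  for (b in unique(trials$block)) {
    idx <- which(trials$block == b)
    ss <- trials$set_size[idx[1L]]
    ca <- if (!is.null(correct_actions)) correct_actions[[as.character(b)]]
          else sample.int(n_a, ss, replace = TRUE)
    ca_trial[idx] <- ca[arr$stim[idx]]
  }
  sim <- rlwm_simulate_cpp(arr$block_id, arr$set_size, arr$stim, ca_trial,
                           as.integer(n_a), params$alpha, params$gamma,
                           params$phi, params$rho,
                           as.integer(params$capacity), params$epsilon,
                           params$beta, decay == "before")
  trials$action <- sim[, 1L]
  trials$correct <- sim[, 2L]
  trials$reward_points <- assign_reward(trials$correct, p_two_points)
  latents <- compute_latents(params, trials, n_a, rpe_form, decay)
  trials$rt_ms <- exp(stats::rnorm(
    nrow(trials), mean = log(550) + 0.35 * (1 - latents$choice_prob),
    sd = 0.2))
  trials <- compute_covariates(trials)
  list(trials = trials, latents = latents)
}
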