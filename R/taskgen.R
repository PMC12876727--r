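#' Task configuration for a blocked associative-learning (RL-WM) session
#'
#' The task presents `set_size` distinct stimuli per block, each
#' `iterations_per_stimulus` times, in a pseudo-random order with no
#' immediate stimulus repeats. Set size is manipulated between blocks and
#' is the working-memory load manipulation; delay (trials since the same
#' stimulus was last correctly answered) varies within blocks. Correct
#' responses earn 1 or 2 points probabilistically; errors earn 0.
#'
#' @param set_sizes integer vector of stimuli-per-block conditions, each >= 2.
#' @param n_actions number of response options (>= 2).
#' @param iterations_per_stimulus presentations of each stimulus per block.
#' @param n_blocks_per_set_size blocks per set-size condition.
#' @param p_two_points probability that a correct response earns 2 points
#'   rather than 1.
#' @param seed integer seed governing stimulus-order randomisation.
#' @return An object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config(set_sizes = c(2, 3), iterations_per_stimulus = 5)
#' @export
task_config <- function(set_sizes = c(2L, 3L, 4L, 5L),
                        n_actions = 3L,
                        iterations_per_stimulus = 13L,
                        n_blocks_per_set_size = 3L,
                        p_two_points = 0.5,
                        seed = 1L) {
  set_sizes <- as.integer(set_sizes)
  if (length(set_sizes) == 0L || anyNA(set_sizes) || any(set_sizes < 2L)) {
    stop("`set_sizes` must be a non-empty vector of integers >= 2")
  }
  if (n_actions < 2L) stop("`n_actions` must be >= 2")
  if (iterations_per_stimulus < 1L) stop("`iterations_per_stimulus` must be >= 1")
  if (n_blocks_per_set_size < 1L) stop("`n_blocks_per_set_size` must be >= 1")
  if (p_two_points < 0 || p_two_points > 1) stop("`p_two_points` must be in [0, 1]")
  structure(
    list(set_sizes = set_sizes,
         n_actions = as.integer(n_actions),
         iterations_per_stimulus = as.integer(iterations_per_stimulus),
         n_blocks_per_set_size = as.integer(n_blocks_per_set_size),
         p_two_points = p_two_points,
         seed = as.integer(seed)),
    class = "task_config")
}

# Constrained shuffle: a sequence with each of `ss` stimuli appearing
# `n_iter` times and no two consecutive trials sharing a stimulus.
# Sequential sampling weighted by remaining counts, with a forced pick
# whenever one stimulus holds at least half of the remaining trials
# (otherwise the no-repeat constraint would become unsatisfiable). With
# equal counts and ss >= 2 a valid order always exists; a restart guard
# covers numerical corner cases.
shuffle_no_repeat <- function(ss, n_iter) {
  if (ss == 1L) {
    if (n_iter > 1L) stop("no-repeat ordering impossible for set_size 1")
    return(1L)
  }
  n <- ss * n_iter
  repeat {
    remaining <- rep(n_iter, ss)
    out <- integer(n)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      total <- n - i + 1L
      forced <- which(remaining * 2L >= total + 1L)
      cand <- if (length(forced) && forced[1L] != prev) {
        forced[1L]
      } else {
        allowed <- which(remaining > 0L)
        allowed <- allowed[allowed != prev]
        if (!length(allowed)) { ok <- FALSE; break }
        if (length(allowed) == 1L) allowed
        else sample(allowed, 1L, prob = remaining[allowed])
      }
      out[i] <- cand
      remaining[cand] <- remaining[cand] - 1L
      prev <- cand
    }
    if (ok) return(out)
  }
}

#' Generate the trial skeleton of one task session
#'
#' Builds the block structure and pseudo-random stimulus sequences for one
#' subject. Actions, correctness, rewards and derived covariates are filled
#' in later (by an agent simulation or by observed data).
#'
#' @param config a [task_config()].
#' @param seed integer seed; the same config and seed always yield the same
#'   stimulus sequences.
#' @param subject_id subject identifier stored in every row.
#' @return A data.frame with one row per trial: `subject_id`, `block`,
#'   `set_size`, `trial`, `stimulus`, `iteration` (1-based count of
#'   presentations of that stimulus), and `NA` placeholders for `action`,
#'   `correct`, `reward_points`, `rt_ms`, `delay`, `pcor`.
#' @export
generate_session <- function(config, seed = config$seed, subject_id = "s01") {
  stopifnot(inherits(config, "task_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  blocks <- rep(config$set_sizes, times = config$n_blocks_per_set_size)
  # interleave conditions rather than running all blocks of one set size
  blocks <- blocks[order(rep(seq_len(config$n_blocks_per_set_size),
                             each = length(config$set_sizes)))]
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    ss <- blocks[b]
    stim <- shuffle_no_repeat(ss, config$iterations_per_stimulus)
    iter <- stats::ave(stim, stim, FUN = seq_along)
    out[[b]] <- data.frame(
      subject_id = subject_id,
      group = NA_character_,
      block = b,
      set_size = ss,
      trial = seq_along(stim),
      stimulus = stim,
      iteration = iter,
      action = NA_integer_,
      correct = NA_integer_,
      reward_points = NA_integer_,
      rt_ms = NA_real_,
      delay = NA_integer_,
      pcor = NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_actions") <- config$n_actions
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assign reward points for a response
#'
#' Errors earn 0 points; correct responses earn 2 points with probability
#' `p_two_points` and 1 point otherwise. The learning model conditions only
#' on binary correctness, so point magnitude is carried for completeness.
#'
#' @param correct 0/1 vector of correctness.
#' @param p_two_points probability of the 2-point reward given correct.
#' @return Integer vector of points in \{0, 1, 2\}.
#' @export
assign_reward <- function(correct, p_two_points = 0.5) {
  if (!all(correct %in% c(0L, 1L))) stop("`correct` must be 0/1")
  n <- length(correct)
  pts <- integer(n)
  idx <- correct == 1L
  pts[idx] <- 1L + stats::rbinom(sum(idx), 1L, p_two_points)
  pts
}

#' Compute delay and reward-history covariates
#'
#' For each trial t of stimulus s within a block, `pcor` counts earlier
#' presentations of s in the block answered correctly (reward history), and
#' `delay` is the number of intervening trials since the most recent earlier
#' correct presentation of s, `NA` if s has not yet been answered correctly.
#'
#' @param trials trial data.frame ordered by block then trial, with
#'   `correct` filled in.
#' @return The same data.frame with `delay` and `pcor` columns filled.
#' @export
compute_covariates <- function(trials) {
  req <- c("block", "trial", "stimulus", "correct")
  if (!all(req %in% names(trials))) {
    stop("trials must contain columns: ", paste(req, collapse = ", "))
  }
  ord <- order(trials$block, trials$trial)
  if (!identical(ord, seq_len(nrow(trials)))) {
    stop("trials must be ordered by block then trial")
  }
  trials$delay <- NA_integer_
  trials$pcor <- NA_integer_
  for (b in unique(trials$block)) {
    idx <- which(trials$block == b)
    last_correct_pos <- integer(0)   # by stimulus id
    n_correct <- integer(0)
    for (i in idx) {
      s <- as.character(trials$stimulus[i])
      pos <- trials$trial[i]
      nc <- if (s %in% names(n_correct)) n_correct[[s]] else 0L
      trials$pcor[i] <- nc
      if (s %in% names(last_correct_pos)) {
        trials$delay[i] <- pos - last_correct_pos[[s]] - 1L
      }
      if (isTRUE(trials$correct[i] == 1L)) {
        last_correct_pos[[s]] <- pos
        n_correct[[s]] <- nc + 1L
      }
    }
  }
  trials
}

#' Read / write trial tables
#'
#' Plain-CSV serialisation of trial tables; missing delays are written as
#' empty fields.
#'
#' @param trials trial data.frame.
#' @param path file path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("delay", "pcor", "action", "correct", "reward_points")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  out
}
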