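#' Cohort specification for the synthetic four-group study
#'
#' Defines, per diagnostic-analogue group (CTRL / MDD / BP / SCZ), the
#' sample size, the truncated-normal distributions of the RL-WM
#' parameters, the EEG template gains, and the reward-history coupling of
#' the set-size (WM) template. The planted structure mirrors the
#' qualitative group differences the analysis is designed to detect:
#' higher WM decay in the SCZ and BP analogues, greater neglect of
#' negative feedback (lower gamma) in the SCZ analogue, and a blunted
#' reward-history coupling of the WM template in the MDD analogue.
#'
#' @param n_per_group subjects per group.
#' @return Named list of per-group specs (class `cohort_spec`).
#' @export
default_cohort_spec <- function(n_per_group = 20L) {
  base <- list(
    n = as.integer(n_per_group),
    mean = c(alpha = 0.06, gamma = 0.55, phi = 0.30, rho = 0.85,
             epsilon = 0.08),
    sd = c(alpha = 0.03, gamma = 0.15, phi = 0.10, rho = 0.06,
           epsilon = 0.04),
    capacity_probs = c(`2` = 0.15, `3` = 0.35, `4` = 0.35, `5` = 0.15),
    gains = c(q_value = 0.8, set_size = 0.8, delay = 0.5, rpe = 0.8),
    pcor_coupling = 0.35)
  spec <- list(CTRL = base, MDD = base, BP = base, SCZ = base)
  spec$MDD$pcor_coupling <- 0          # blunted WM management
  spec$BP$mean["phi"] <- 0.42          # higher WM decay
  spec$SCZ$mean["phi"] <- 0.42         # higher WM decay
  spec$SCZ$mean["gamma"] <- 0.28       # greater neglect of negative feedback
  structure(spec, class = "cohort_spec")
}

# truncated-normal draw inside a hard interval by resampling
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Sample a subject table from a cohort specification
#'
#' @param spec a `cohort_spec`, see [default_cohort_spec()].
#' @param seed integer seed.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   true parameters, template gains and coupling.
#' @export
sample_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  if (any(vapply(spec, function(g) g$n < 1L, logical(1)))) {
    stop("every group needs at least 1 subject")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boxes <- .rlwm_boxes()
  rows <- list()
  for (grp in names(spec)) {
    g <- spec[[grp]]
    n <- g$n
    draw <- function(nm) {
      if (g$sd[nm] == 0) rep(g$mean[nm], n)
      else .rtruncnorm(n, g$mean[nm], g$sd[nm],
                       boxes[nm, 1] + 0.005 * diff(boxes[nm, ]),
                       boxes[nm, 2] - 0.005 * diff(boxes[nm, ]))
    }
    rows[[grp]] <- data.frame(
      subject_id = sprintf("%s%03d", grp, seq_len(n)),
      group = grp,
      alpha = draw("alpha"), gamma = draw("gamma"), phi = draw("phi"),
      rho = draw("rho"), epsilon = draw("epsilon"),
      capacity = sample(2:5, n, replace = TRUE, prob = g$capacity_probs),
      gain_q_value = unname(g$gains[["q_value"]]),
      gain_set_size = unname(g$gains[["set_size"]]),
      gain_delay = unname(g$gains[["delay"]]),
      gain_rpe = unname(g$gains[["rpe"]]),
      pcor_coupling = g$pcor_coupling,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate behavior for a whole cohort
#'
#' Forward-simulates every subject through the task with their true
#' parameters; returns the stacked trial table (with covariates) and
#' latent traces.
#'
#' @param subjects subject table from [sample_cohort()].
#' @param config a [task_config()].
#' @param seed integer master seed.
#' @return list(trials, latents), each with a `subject_id` column.
#' @export
simulate_behavior_cohort <- function(subjects, config = task_config(),
                                     seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subj_seeds <- sample.int(2^30, nrow(subjects))
  trials <- vector("list", nrow(subjects))
  latents <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    p <- rlwm_params(subjects$alpha[i], subjects$gamma[i], subjects$phi[i],
                     subjects$rho[i], subjects$capacity[i],
                     subjects$epsilon[i])
    skel <- generate_session(config, seed = subj_seeds[i],
                             subject_id = subjects$subject_id[i])
    skel$group <- subjects$group[i]
    sim <- simulate_agent(p, skel, seed = subj_seeds[i] + 1L,
                          p_two_points = config$p_two_points)
    trials[[i]] <- sim$trials
    latents[[i]] <- cbind(subject_id = subjects$subject_id[i], sim$latents)
  }
  list(trials = do.call(rbind, trials),
       latents = do.call(rbind, latents))
}

#' Canonical spatiotemporal template library
#'
#' Smooth, unit-norm channel x timepoint templates for each regressor:
#' an early frontal component for the RL value regressor, a late parietal
#' component for set size, a late frontal component for delay, and a
#' mid-latency frontocentral component for the feedback-locked RPE. The
#' shapes (Gaussian temporal kernels on smooth topographies) are
#' generator conventions; only their qualitative spatial layout is
#' meaningful.
#'
#' @param montage channel montage, see [scalp_montage()].
#' @param times_ms epoch time axis in ms.
#' @return Named list of channels x timepoints matrices, unit Frobenius
#'   norm each.
#' @export
template_library <- function(montage = scalp_montage(),
                             times_ms = default_times_ms()) {
  topo <- function(cx, cy, width = 0.45) {
    w <- exp(-((montage$x - cx)^2 + (montage$y - cy)^2) / (2 * width^2))
    w / max(w)
  }
  kern <- function(center_ms, width_ms) {
    k <- exp(-(times_ms - center_ms)^2 / (2 * width_ms^2))
    k[times_ms < 0] <- 0   # silent during the pre-event baseline
    k
  }
  mk <- function(tp, tk) {
    m <- outer(tp, tk)
    # compact support: truncate the Gaussian tails at 10% of peak so the
    # template has a well-defined spatiotemporal footprint
    m[m < 0.1 * max(m)] <- 0
    m / sqrt(sum(m^2))
  }
  out <- list(
    q_value = mk(topo(0, 0.55), kern(220, 70)),    # early frontal
    set_size = mk(topo(0, -0.60), kern(450, 90)),  # late parietal
    delay = mk(topo(0, 0.55), kern(500, 90)),      # late frontal
    rpe = mk(topo(0, 0.25), kern(300, 70)))        # mid frontocentral
  for (nm in names(out)) {
    dimnames(out[[nm]]) <- list(montage$channel, NULL)
  }
  out
}

#' Noise level for a target footprint signal-to-noise ratio
#'
#' SNR is defined as the template's RMS signal amplitude over its compact
#' footprint divided by the marginal noise SD; this returns the noise SD
#' achieving a requested SNR for a given template and gain.
#'
#' @param templates a [template_library()].
#' @param gain template gain (amplitude multiplier).
#' @param regressor which template defines the footprint.
#' @param snr target signal-to-noise ratio.
#' @return Scalar noise SD.
#' @export
snr_noise_sd <- function(templates, gain = 0.8, regressor = "q_value",
                         snr = 1) {
  B <- templates[[regressor]]
  gain * sqrt(sum(B^2) / sum(B > 0)) / snr
}

#' Default epoch time axis
#'
#' -100 to +700 ms at 125 Hz (8 ms steps, 101 samples).
#' @return Numeric vector of times in ms.
#' @export
default_times_ms <- function() seq(-100, 700, by = 8)

# z-score with NAs mapped to the mean (0); used only when painting
# generator signal, never in the analysis design
.zscore_na0 <- function(x) {
  z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  z[is.na(z)] <- 0
  z
}

#' Simulate multichannel epochs for one subject
#'
#' voltage(trial, ch, t) = sum_k gain_k(trial) * B_k(ch, t) * x_k(trial)
#' plus spatially correlated, temporally smoothed Gaussian noise. For
#' stimulus-locked epochs the painted regressors are the RL value, set
#' size and delay; for feedback-locked epochs the RPE. The set-size
#' (WM) template's trial gain grows with reward history at rate
#' `pcor_coupling` (the WM-management coupling), which is zero in the
#' blunted (MDD-analogue) group.
#'
#' @param trials one subject's completed trial table.
#' @param latents matching latent trace.
#' @param subject one row of the subject table (gains and coupling).
#' @param templates a [template_library()].
#' @param lock `"stimulus"` or `"feedback"`.
#' @param noise_sd marginal noise SD (0 for noiseless identity checks).
#' @param spatial_lambda spatial noise correlation length (montage units).
#' @param temporal_ma temporal moving-average smoothing width (samples).
#' @param seed integer seed.
#' @param montage channel montage.
#' @param times_ms epoch time axis.
#' @return An [epoch_set()].
#' @export
simulate_eeg <- function(trials, latents, subject, templates,
                         lock = c("stimulus", "feedback"),
                         noise_sd = 1, spatial_lambda = 0.5,
                         temporal_ma = 3L, seed = 1L,
                         montage = scalp_montage(),
                         times_ms = default_times_ms()) {
  lock <- match.arg(lock)
  nch <- nrow(montage)
  if (nrow(templates$q_value) != nch) stop("template/channel mismatch")
  if (ncol(templates$q_value) != length(times_ms)) {
    stop("template/time-axis mismatch")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(trials)
  nt <- length(times_ms)

  key_t <- paste(trials$block, trials$trial)
  key_l <- paste(latents$block, latents$trial)
  m <- match(key_t, key_l)
  pcor_z <- .zscore_na0(trials$pcor)
  v <- array(0, dim = c(n, nch, nt))
  add_component <- function(v, gain_per_trial, template) {
    amp <- gain_per_trial                       # length-n amplitudes
    tem <- as.vector(template)                  # nch*nt
    v + array(outer(amp, tem), dim = c(n, nch, nt))
  }
  if (lock == "stimulus") {
    v <- add_component(v, subject$gain_q_value *
                         .zscore_na0(latents$q_rl_chosen[m]),
                       templates$q_value)
    # the WM template expresses both objective demand (set size) and
    # reward history: recruitment grows with load, management with
    # accumulated success; the management term is the group coupling
    v <- add_component(v, subject$gain_set_size *
                         (.zscore_na0(trials$set_size) +
                            subject$pcor_coupling * pcor_z),
                       templates$set_size)
    v <- add_component(v, subject$gain_delay * .zscore_na0(trials$delay),
                       templates$delay)
  } else {
    v <- add_component(v, subject$gain_rpe * .zscore_na0(latents$rpe[m]),
                       templates$rpe)
  }
  if (noise_sd > 0) {
    d <- as.matrix(stats::dist(montage[, c("x", "y")]))
    L <- chol(exp(-d / spatial_lambda) + diag(1e-8, nch))
    # one draw for all trials: channels x (trials * timepoints), spatially
    # correlated through the Cholesky factor
    z <- crossprod(L, matrix(stats::rnorm(nch * n * nt), nch, n * nt))
    z <- aperm(array(z, dim = c(nch, n, nt)), c(2, 1, 3))
    if (temporal_ma > 1L) {
      sm <- array(0, dim = dim(z))
      half <- (temporal_ma - 1L) %/% 2L
      for (off in (-half):(temporal_ma - 1L - half)) {
        idx <- ((seq_len(nt) - 1L + off) %% nt) + 1L  # circular in time
        sm <- sm + z[, , idx, drop = FALSE]
      }
      z <- sm / sqrt(temporal_ma)               # unit marginal variance
    }
    v <- v + noise_sd * z
  }
  epoch_set(v, montage$channel, times_ms, lock,
            data.frame(subject_id = trials$subject_id,
                       block = trials$block, trial = trials$trial,
                       stringsAsFactors = FALSE))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Produces an internally consistent dataset (trials, latents, stimulus-
#' and feedback-locked epochs, and a ground-truth record) at one of three
#' size presets: `tiny` (4 subjects, 2 set sizes, smoke-test scale),
#' `ci` (20 subjects/group, full task, sized for the validation suite),
#' `full` (40 subjects/group).
#'
#' @param preset `"tiny"`, `"ci"` or `"full"`.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
make_fixture <- function(preset = c("tiny", "ci", "full"), seed = 1L,
                         out_dir = tempfile("rlwm_fixture_")) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
    tiny = list(n = 1L, config = task_config(set_sizes = c(2L, 3L),
                                             iterations_per_stimulus = 6L)),
    ci = list(n = 20L, config = task_config()),
    full = list(n = 40L, config = task_config()))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- default_cohort_spec(sizes$n)
  subjects <- sample_cohort(spec, seed = seed)
  beh <- simulate_behavior_cohort(subjects, sizes$config, seed = seed + 1L)
  templates <- template_library()
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    latents = file.path(out_dir, "latents.csv"),
    epochs_stim = file.path(out_dir, "epochs_stim.h5"),
    epochs_fb = file.path(out_dir, "epochs_fb.h5"),
    truth = file.path(out_dir, "truth.json"))
  write_trials(beh$trials, paths$trials)
  write_latents(beh$latents, paths$latents)
  noise_sd <- snr_noise_sd(templates,
                           gain = spec$CTRL$gains[["q_value"]])
  for (lk in c("stimulus", "feedback")) {
    eps <- cohort_epochs(subjects, beh, templates, lock = lk,
                         seed = seed + 2L, noise_sd = noise_sd)
    big <- .concat_epochs(eps)
    write_epochs(big, if (lk == "stimulus") paths$epochs_stim
                      else paths$epochs_fb)
  }
  jsonlite::write_json(
    list(preset = preset, seed = seed, subjects = subjects,
         task = unclass(sizes$config)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate epochs for every subject of a cohort
#'
#' @param subjects subject table.
#' @param beh output of [simulate_behavior_cohort()].
#' @param templates a [template_library()].
#' @param lock epoch lock.
#' @param seed master seed (per-subject seeds are derived from it).
#' @param ... passed to [simulate_eeg()].
#' @return Named list of per-subject [epoch_set()]s.
#' @export
cohort_epochs <- function(subjects, beh, templates = template_library(),
                          lock = "stimulus", seed = 1L, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subj_seeds <- sample.int(2^30, nrow(subjects))
  out <- vector("list", nrow(subjects))
  names(out) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    tr <- beh$trials[beh$trials$subject_id == sid, , drop = FALSE]
    la <- beh$latents[beh$latents$subject_id == sid, , drop = FALSE]
    out[[i]] <- simulate_eeg(tr, la, subjects[i, ], templates, lock = lock,
                             seed = subj_seeds[i], ...)
  }
  out
}

.concat_epochs <- function(eps) {
  n <- sum(vapply(eps, function(e) dim(e$voltages)[1], integer(1)))
  e1 <- eps[[1]]
  v <- array(0, dim = c(n, dim(e1$voltages)[2], dim(e1$voltages)[3]))
  keys <- vector("list", length(eps))
  at <- 0L
  for (i in seq_along(eps)) {
    ni <- dim(eps[[i]]$voltages)[1]
    v[at + seq_len(ni), , ] <- eps[[i]]$voltages
    keys[[i]] <- eps[[i]]$trial_keys
    at <- at + ni
  }
  epoch_set(v, e1$channels, e1$times_ms, e1$lock, do.call(rbind, keys))
}
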