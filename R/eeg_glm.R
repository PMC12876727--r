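#' Standard 29-channel scalp montage
#'
#' Approximate 2D head-projected coordinates for a 29-channel 10-20 style
#' scalp layout (electro-ocular channels are never part of analysis
#' arrays). Coordinates are only used to derive spatial adjacency for
#' cluster formation.
#'
#' @return data.frame with `channel`, `x` (left-right), `y` (back-front).
#' @export
scalp_montage <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FC2", "FC6",
                "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8",
                "POz", "O1", "Oz", "O2"),
    x = c(-0.31, 0.31, -0.80, -0.40, 0, 0.40, 0.80,
          -0.60, -0.20, 0.20, 0.60,
          -0.85, -0.40, 0, 0.40, 0.85,
          -0.60, -0.20, 0.20, 0.60,
          -0.80, -0.40, 0, 0.40, 0.80,
          0, -0.27, 0, 0.27),
    y = c(0.90, 0.90, 0.55, 0.60, 0.62, 0.60, 0.55,
          0.30, 0.30, 0.30, 0.30,
          0, 0, 0, 0, 0,
          -0.30, -0.30, -0.30, -0.30,
          -0.55, -0.60, -0.62, -0.60, -0.55,
          -0.78, -0.90, -0.93, -0.90),
    stringsAsFactors = FALSE)
}

#' Channel adjacency from montage distances
#'
#' Two channels are spatial neighbours when their projected distance is
#' below `threshold` (in montage units; the default connects each channel
#' to its immediate ring neighbours).
#'
#' @param montage data.frame as from [scalp_montage()].
#' @param threshold distance cutoff.
#' @return Logical symmetric matrix with channel dimnames.
#' @export
channel_adjacency <- function(montage = scalp_montage(), threshold = 0.46) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- d > 0 & d < threshold
  dimnames(adj) <- list(montage$channel, montage$channel)
  adj
}

#' Construct an epoch set
#'
#' Container for preprocessed, epoched EEG: a trials x channels x
#' timepoints voltage array with channel labels, a uniform time axis and
#' the lock event, plus trial keys that resolve rows against a trial
#' table.
#'
#' @param voltages numeric array, trials x channels x timepoints.
#' @param channels character channel labels.
#' @param times_ms strictly increasing, uniformly spaced time axis (ms).
#' @param lock `"stimulus"` or `"feedback"`.
#' @param trial_keys data.frame with `subject_id`, `block`, `trial`
#'   uniquely identifying each epoch row.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(voltages, channels, times_ms,
                      lock = c("stimulus", "feedback"), trial_keys) {
  lock <- match.arg(lock)
  if (length(dim(voltages)) != 3L) stop("`voltages` must be a 3-d array")
  if (dim(voltages)[2] != length(channels)) stop("channel count mismatch")
  if (dim(voltages)[3] != length(times_ms)) stop("timepoint count mismatch")
  steps <- diff(times_ms)
  if (any(steps <= 0) || (length(steps) > 1L &&
      max(abs(steps - steps[1])) > 1e-9)) {
    stop("`times_ms` must be strictly increasing and uniformly spaced")
  }
  if (nrow(trial_keys) != dim(voltages)[1]) stop("trial key count mismatch")
  key <- interaction(trial_keys$subject_id, trial_keys$block,
                     trial_keys$trial, drop = TRUE)
  if (anyDuplicated(key)) stop("trial keys must be unique")
  structure(list(voltages = voltages, channels = channels,
                 times_ms = times_ms, lock = lock, trial_keys = trial_keys),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set (%s-locked): %d trials x %d channels x %d timepoints (%g..%g ms)\n",
              x$lock, dim(x$voltages)[1], dim(x$voltages)[2],
              dim(x$voltages)[3], min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Z-score epochs across trials
#'
#' Standardises the voltage at every channel x timepoint cell to mean 0,
#' SD 1 across the included trials, absorbing per-subject amplitude scale
#' before the single-trial regressions.
#'
#' @param epochs an [epoch_set()].
#' @param trial_mask logical inclusion mask over trials (default: all).
#' @return The epoch set restricted to included trials, z-scored.
#' @export
zscore_epochs <- function(epochs, trial_mask = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  v <- epochs$voltages
  if (is.null(trial_mask)) trial_mask <- rep(TRUE, dim(v)[1])
  if (sum(trial_mask) < 10L) stop("need at least 10 included trials")
  v <- v[trial_mask, , , drop = FALSE]
  n <- dim(v)[1]
  vm <- matrix(v, nrow = n)                     # trials x (channel * time)
  mu <- colMeans(vm)
  sd <- sqrt(colSums(sweep(vm, 2, mu)^2) / (n - 1))
  if (any(sd < 1e-12)) {
    bad <- arrayInd(which(sd < 1e-12)[1], dim(v)[2:3])
    stop(sprintf("zero variance at channel %s, %g ms",
                 epochs$channels[bad[1]], epochs$times_ms[bad[2]]))
  }
  v <- array(scale(vm, center = mu, scale = sd), dim = dim(v))
  epoch_set(v, epochs$channels, epochs$times_ms, epochs$lock,
            epochs$trial_keys[trial_mask, , drop = FALSE])
}

.zscore <- function(x) (x - mean(x)) / stats::sd(x)

#' Build the trialwise design matrix for the mass-univariate regression
#'
#' Joins the model latents onto the trial table, restricts to correct
#' trials with a defined delay, and assembles the z-scored regressors:
#' set size, the model-derived value regressor (RL expected value `q` for
#' stimulus-locked epochs, the trialwise RPE for feedback-locked epochs),
#' delay, their pairwise and three-way interactions, log RT and trial
#' number within block. Interactions are products of z-scored main
#' effects, re-z-scored so every column shares a common scale.
#'
#' @param trials trial data.frame with covariates computed.
#' @param latents latent trace data.frame keyed by (block, trial).
#' @param lock `"stimulus"` or `"feedback"`.
#' @return list(X = design matrix (no intercept), included = logical mask
#'   over trial rows, trials = the included trial rows).
#' @export
build_design <- function(trials, latents, lock = c("stimulus", "feedback")) {
  lock <- match.arg(lock)
  key_t <- paste(trials$block, trials$trial)
  key_l <- paste(latents$block, latents$trial)
  m <- match(key_t, key_l)
  if (anyNA(m)) stop("latents missing for some trials")
  value <- if (lock == "stimulus") latents$q_rl_chosen[m] else latents$rpe[m]
  value_name <- if (lock == "stimulus") "q_value" else "rpe"

  included <- trials$correct == 1L & !is.na(trials$delay)
  if (!any(included)) stop("all trials excluded (no correct trials with defined delay)")
  if (mean(!included) > 0.5) {
    warning(sprintf("%.0f%% of trials excluded from the design",
                    100 * mean(!included)))
  }
  raw <- data.frame(
    set_size = trials$set_size[included],
    value = value[included],
    delay = trials$delay[included],
    log_rt = log(trials$rt_ms[included]),
    trial_in_block = trials$trial[included])
  for (nm in names(raw)) {
    if (stats::sd(raw[[nm]]) < 1e-12) {
      stop("degenerate (constant) design column: ",
           if (nm == "value") value_name else nm)
    }
  }
  z <- lapply(raw, .zscore)
  X <- cbind(
    set_size = z$set_size,
    value = z$value,
    delay = z$delay,
    set_size_x_value = .zscore(z$set_size * z$value),
    set_size_x_delay = .zscore(z$set_size * z$delay),
    value_x_delay = .zscore(z$value * z$delay),
    set_size_x_value_x_delay = .zscore(z$set_size * z$value * z$delay),
    log_rt = z$log_rt,
    trial_in_block = z$trial_in_block)
  colnames(X) <- sub("value", value_name, colnames(X), fixed = TRUE)
  list(X = X, included = included,
       trials = trials[included, , drop = FALSE])
}

#' Mass-univariate robust regression of single-trial EEG
#'
#' Fits, independently at every channel x timepoint, a robust linear model
#' of the z-scored voltage on the design columns plus an intercept, by
#' iteratively reweighted least squares with Huber weighting (tuning
#' constant 1.345, MAD scale). Cells that do not converge fall back to
#' ordinary least squares and are flagged.
#'
#' @param epochs a z-scored [epoch_set()] restricted to the design's
#'   included trials.
#' @param design output of [build_design()] (or any list with an `X`
#'   matrix whose rows align with the epochs).
#' @param tuning Huber tuning constant.
#' @param maxit maximum IRLS iterations per cell.
#' @param tol absolute coefficient tolerance for convergence.
#' @return An object of class `beta_map`: `beta` array (regressor x
#'   channel x timepoint, intercept included as `(Intercept)`),
#'   `channels`, `times_ms`, `lock`, `diagnostics`.
#' @export
robust_mass_univariate <- function(epochs, design, tuning = 1.345,
                                   maxit = 50L, tol = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"))
  X <- design$X
  n <- dim(epochs$voltages)[1]
  if (nrow(X) != n) stop("design rows do not align with epoch trials")
  nch <- dim(epochs$voltages)[2]
  nt <- dim(epochs$voltages)[3]
  Y <- matrix(epochs$voltages, nrow = n)  # cells indexed ch + nch*(t-1)
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- huber_irls_cpp(Xi, Y, tuning, as.integer(maxit), tol)
  beta <- array(t(fit$beta), dim = c(nch, nt, ncol(Xi)))
  beta <- aperm(beta, c(3, 1, 2))
  dimnames(beta) <- list(colnames(Xi), epochs$channels, NULL)
  structure(
    list(beta = beta, channels = epochs$channels,
         times_ms = epochs$times_ms, lock = epochs$lock,
         diagnostics = list(
           iterations = matrix(fit$iterations, nch, nt),
           converged = matrix(fit$converged, nch, nt))),
    class = "beta_map")
}

#' @export
print.beta_map <- function(x, ...) {
  cat(sprintf("beta_map (%s-locked): %d regressors x %d channels x %d timepoints; %d/%d cells converged\n",
              x$lock, dim(x$beta)[1], dim(x$beta)[2], dim(x$beta)[3],
              sum(x$diagnostics$converged), length(x$diagnostics$converged)))
  invisible(x)
}

#' Group-level cluster permutation test on regression coefficients
#'
#' One-sample t-test of one regressor's per-subject coefficients against
#' zero at every channel x timepoint; suprathreshold cells (two-sided
#' cluster-forming p < `cluster_alpha`) are clustered over consecutive
#' timepoints and spatially adjacent channels, and each observed cluster's
#' mass (sum of |t|) is compared with a sign-flip permutation null of the
#' maximum cluster mass.
#'
#' @param beta_maps list of per-subject `beta_map` objects.
#' @param regressor name of the regressor to test.
#' @param adjacency channel adjacency matrix, see [channel_adjacency()].
#' @param cluster_alpha two-sided cluster-forming threshold.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param alpha cluster-level significance threshold.
#' @return An object of class `cluster_mask`: `mask` (channels x
#'   timepoints logical), `sign` (+1/-1 within significant clusters, 0
#'   elsewhere), `clusters` (per-cluster mass, sign, permutation p),
#'   `tmap`, `null_max`.
#' @export
group_cluster_test <- function(beta_maps, regressor,
                               adjacency = channel_adjacency(),
                               cluster_alpha = 0.05, n_perm = 1000L,
                               alpha = 0.05) {
  if (length(beta_maps) < 8L) stop("need at least 8 subjects")
  if (n_perm < 100L) stop("need at least 100 permutations")
  b1 <- beta_maps[[1]]
  if (!regressor %in% dimnames(b1$beta)[[1]]) {
    stop("unknown regressor: ", regressor)
  }
  nch <- dim(b1$beta)[2]
  nt <- dim(b1$beta)[3]
  adjacency <- adjacency[b1$channels, b1$channels]
  B <- t(vapply(beta_maps, function(bm) {
    as.vector(bm$beta[regressor, , ])
  }, numeric(nch * nt)))
  ns <- nrow(B)
  t_thresh <- stats::qt(1 - cluster_alpha / 2, df = ns - 1)
  res <- cluster_perm_cpp(B, nch, nt, adjacency, t_thresh,
                          as.integer(n_perm))
  labels <- matrix(res$labels, nch, nt)
  ncl <- length(res$masses)
  pvals <- if (ncl) vapply(res$masses, function(mm) {
    (1 + sum(res$null_max >= mm)) / (n_perm + 1)
  }, numeric(1)) else numeric(0)
  keep <- which(pvals < alpha)
  mask <- matrix(FALSE, nch, nt)
  sign_map <- matrix(0L, nch, nt)
  for (k in keep) {
    cells <- labels == k
    mask[cells] <- TRUE
    sign_map[cells] <- res$signs[k]
  }
  dimnames(mask) <- dimnames(sign_map) <- list(b1$channels, NULL)
  structure(
    list(regressor = regressor, mask = mask, sign = sign_map,
         clusters = data.frame(cluster = seq_len(ncl),
                               mass = as.numeric(res$masses),
                               sign = as.integer(res$signs),
                               p = pvals)[order(pvals), , drop = FALSE],
         tmap = matrix(res$tmap, nch, nt,
                       dimnames = list(b1$channels, NULL)),
         null_max = res$null_max,
         channels = b1$channels, times_ms = b1$times_ms,
         alpha = alpha),
    class = "cluster_mask")
}

#' @export
print.cluster_mask <- function(x, ...) {
  cat(sprintf("cluster_mask for '%s': %d candidate clusters, %d significant (p < %g), %d cells in mask\n",
              x$regressor, nrow(x$clusters), sum(x$clusters$p < x$alpha),
              x$alpha, sum(x$mask)))
  invisible(x)
}

#' Extract a trialwise neural marker from a cluster mask
#'
#' marker(trial) = mean of sign-aligned z-scored voltage over the masked
#' channel x timepoint cells; cells in negative-effect clusters are
#' negated so that larger marker values always mean stronger expression
#' of the effect.
#'
#' @param epochs a z-scored [epoch_set()].
#' @param mask a `cluster_mask` (or any list with `mask` and `sign`
#'   matrices over channels x timepoints).
#' @return data.frame of the epoch trial keys plus a `marker` column.
#' @export
extract_trial_marker <- function(epochs, mask) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!any(mask$mask)) {
    stop("empty cluster mask: no significant cells; review the ",
         "cluster-forming threshold or statistical power")
  }
  cells <- which(mask$mask)
  sgn <- mask$sign[cells]
  n <- dim(epochs$voltages)[1]
  v <- matrix(epochs$voltages, nrow = n)
  marker <- as.vector(v[, cells, drop = FALSE] %*% sgn) / length(cells)
  cbind(epochs$trial_keys, marker = marker)
}

#' Asymptotic per-association marker summary
#'
#' Averages a trialwise marker over the final 4 iterations of each
#' stimulus within each block, per subject, capturing asymptotic
#' expression of the effect. Stimuli with fewer than 4 marker-bearing
#' iterations are summarised over what exists and flagged.
#'
#' @param markers data.frame with `subject_id`, `block`, `trial`,
#'   `marker`.
#' @param trials trial data.frame supplying `stimulus` and `iteration`
#'   for the same keys.
#' @param n_final number of final iterations to average (default 4).
#' @return data.frame per (subject_id, block, stimulus): `marker_asym`,
#'   `n_used`, `flagged`.
#' @export
asymptotic_marker <- function(markers, trials, n_final = 4L) {
  key_m <- paste(markers$subject_id, markers$block, markers$trial)
  key_t <- paste(trials$subject_id, trials$block, trials$trial)
  m <- match(key_m, key_t)
  if (anyNA(m)) stop("markers contain trials absent from the trial table")
  df <- data.frame(subject_id = markers$subject_id, block = markers$block,
                   stimulus = trials$stimulus[m],
                   iteration = trials$iteration[m],
                   marker = markers$marker)
  split_keys <- interaction(df$subject_id, df$block, df$stimulus, drop = TRUE)
  out <- lapply(split(df, split_keys), function(g) {
    g <- g[order(g$iteration), , drop = FALSE]
    use <- utils::tail(seq_len(nrow(g)), n_final)
    data.frame(subject_id = g$subject_id[1], block = g$block[1],
               stimulus = g$stimulus[1],
               marker_asym = mean(g$marker[use]),
               n_used = length(use),
               flagged = length(use) < n_final)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
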