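# Box constraints of the free parameters. alpha is capped at 0.3 to keep
# the RL learning rate identifiable against the one-shot WM module; the
# remaining free parameters live in the unit interval. beta and alpha_wm
# are fixed model constants and never appear here.
.rlwm_boxes <- function() {
  rbind(alpha   = c(0, 0.3),
        gamma   = c(0, 1),
        phi     = c(0, 1),
        rho     = c(0, 1),
        epsilon = c(0, 1))
}

# logistic reparameterisation onto each box: the simplex runs on an
# unconstrained scale while reported values respect hard bounds
.to_box <- function(theta, boxes) {
  u <- pmin(pmax(stats::plogis(theta), 1e-9), 1 - 1e-9)
  boxes[, 1] + (boxes[, 2] - boxes[, 1]) * u
}

.from_box <- function(x, boxes) {
  stats::qlogis((x - boxes[, 1]) / (boxes[, 2] - boxes[, 1]))
}

#' Fit the RL-WM model to one subject by constrained multi-start MLE
#'
#' For each candidate integer capacity C in `capacity_grid`, minimises the
#' session negative log-likelihood by Nelder-Mead simplex from `n_restarts`
#' random interior starting points (uniform in the central 5\%-95\% of each
#' box, seeded), with box constraints enforced by a logistic
#' reparameterisation. The global best across the capacity grid is
#' returned; ties between capacities are broken toward the smaller C.
#'
#' @param trials one subject's trial data.frame (ordered, actions observed).
#' @param n_restarts random initialisations per capacity value. The
#'   production default is 40; smaller values trade optimality for speed.
#' @param capacity_grid integer capacities to profile over.
#' @param seed integer seed making the whole fit deterministic.
#' @param n_a number of actions.
#' @param decay per-trial decay placement, see [rlwm_step()].
#' @return An object of class `rlwm_fit`: `params` ([rlwm_params()]),
#'   `nll`, `n_restarts`, `capacity_nll` (named per-C best NLLs),
#'   `convergence` (per-C counts of converged restarts).
#' @export
fit_subject <- function(trials, n_restarts = 40L, capacity_grid = 2:5,
                        seed = 1L, n_a = 3L,
                        decay = c("before", "after")) {
  decay <- match.arg(decay)
  .check_session(trials)
  if (length(unique(trials$block)) < 2L) {
    stop("need at least 2 blocks of trials to fit")
  }
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1")
  capacity_grid <- sort(unique(as.integer(capacity_grid)))
  if (!all(capacity_grid %in% 2:5)) stop("capacities must lie in 2..5")

  boxes <- .rlwm_boxes()
  arr <- .session_arrays(trials)
  obj_for_c <- function(C) {
    force(C)
    function(theta) {
      x <- .to_box(theta, boxes)
      rlwm_nll_cpp(arr$block_id, arr$set_size, arr$stim, trials$action,
                   trials$correct, as.integer(n_a),
                   x[1], x[2], x[3], x[4], C, x[5], 100,
                   decay == "before")
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # all starts drawn up front so the fit is reproducible regardless of
  # how many optimiser iterations each restart consumes; restart index is
  # the slowest dimension so that a larger n_restarts extends (never
  # reshuffles) the start sequence
  lo <- boxes[, 1] + 0.05 * (boxes[, 2] - boxes[, 1])
  hi <- boxes[, 1] + 0.95 * (boxes[, 2] - boxes[, 1])
  starts <- array(stats::runif(length(capacity_grid) * n_restarts * 5L,
                               min = lo, max = hi),
                  dim = c(5L, length(capacity_grid), n_restarts))

  best <- NULL
  capacity_nll <- stats::setNames(rep(NA_real_, length(capacity_grid)),
                                  capacity_grid)
  convergence <- stats::setNames(integer(length(capacity_grid)),
                                 capacity_grid)
  for (ci in seq_along(capacity_grid)) {
    C <- capacity_grid[ci]
    fn <- obj_for_c(C)
    best_c <- NULL
    for (k in seq_len(n_restarts)) {
      theta0 <- .from_box(starts[, ci, k], boxes)
      fit <- stats::optim(theta0, fn, method = "Nelder-Mead",
                          control = list(maxit = 1500L, reltol = 1e-8))
      if (is.finite(fit$value)) {
        if (fit$convergence == 0L) convergence[ci] <- convergence[ci] + 1L
        if (is.null(best_c) || fit$value < best_c$value) best_c <- fit
      }
    }
    if (is.null(best_c)) next
    # polish the capacity's best restart from its terminal point:
    # Nelder-Mead simplices can collapse prematurely in 5 dimensions
    fit2 <- stats::optim(best_c$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 600L, reltol = 1e-8))
    if (fit2$value < best_c$value) best_c <- fit2
    capacity_nll[ci] <- best_c$value
    # strict improvement, so equal-NLL ties resolve to the smaller C
    if (is.null(best) || best_c$value < best$value) {
      best <- best_c
      best$capacity <- C
    }
  }
  if (is.null(best)) {
    stop("all restarts failed to produce a finite likelihood; ",
         "check the trial table for degenerate structure")
  }
  x <- .to_box(best$par, boxes)
  structure(
    list(params = rlwm_params(x[1], x[2], x[3], x[4], best$capacity, x[5]),
         nll = best$value,
         n_restarts = as.integer(n_restarts),
         capacity_nll = capacity_nll,
         convergence = convergence),
    class = "rlwm_fit")
}

#' @export
print.rlwm_fit <- function(x, ...) {
  cat(sprintf("RL-WM fit: NLL = %.3f (C grid: %s)\n", x$nll,
              paste(sprintf("C=%s %.2f", names(x$capacity_nll),
                            x$capacity_nll), collapse = ", ")))
  print(x$params)
  invisible(x)
}

#' Default parameter sampling ranges for recovery studies
#'
#' Ground-truth vectors are sampled from the empirically plausible fitted
#' region of this task: small RL learning rates (well below the 0.3 cap),
#' moderate decay, predominantly WM-reliant mixing and low-to-moderate
#' lapse rates. Sampling from the WM-reliant region is deliberate: the WM
#' parameters (phi, rho, C) enter the likelihood only through the
#' omega-weighted WM policy, so agents that barely use WM are
#' structurally uninformative about them, and recovery studies in this
#' literature draw their ground truths from the fitted population for
#' exactly this reason.
#'
#' @return Named list of c(lo, hi) ranges inside the box constraints.
#' @export
default_recovery_ranges <- function() {
  list(alpha   = c(0.02, 0.12),
       gamma   = c(0.30, 0.90),
       phi     = c(0.10, 0.50),
       rho     = c(0.75, 0.97),
       epsilon = c(0.02, 0.20),
       capacity = 2:5)
}

#' Parameter-recovery simulation
#'
#' Samples ground-truth parameter vectors uniformly within `ranges`,
#' forward-simulates each agent through the task, refits every simulated
#' session, and tabulates recovery quality per parameter (Pearson r, bias,
#' RMSE) plus the exact-recovery rate of the integer capacity.
#'
#' @param n_agents number of simulated agents.
#' @param ranges sampling ranges, see [default_recovery_ranges()].
#' @param config a [task_config()].
#' @param n_restarts restarts per capacity during refitting.
#' @param seed integer master seed.
#' @return An object of class `recovery_report`: `table` (true and fitted
#'   values per agent), `metrics` (per-parameter r/bias/RMSE),
#'   `capacity_rate`, `n_failed`.
#' @export
recover_parameters <- function(n_agents = 50L,
                               ranges = default_recovery_ranges(),
                               config = task_config(),
                               n_restarts = 8L, seed = 1L) {
  if (n_agents < 2L) stop("`n_agents` must be >= 2")
  if (config$iterations_per_stimulus < 1L) stop("empty sessions are not fittable")
  boxes <- .rlwm_boxes()
  for (nm in rownames(boxes)) {
    rg <- ranges[[nm]]
    if (rg[1] < boxes[nm, 1] || rg[2] > boxes[nm, 2]) {
      stop("sampling range for ", nm, " lies outside its box constraint")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cont <- c("alpha", "gamma", "phi", "rho", "epsilon")
  true <- sapply(cont, function(nm) {
    stats::runif(n_agents, ranges[[nm]][1], ranges[[nm]][2])
  })
  cap_grid <- as.integer(ranges$capacity)
  true_C <- cap_grid[sample.int(length(cap_grid), n_agents, replace = TRUE)]
  agent_seeds <- sample.int(2^30, n_agents)

  rows <- vector("list", n_agents)
  n_failed <- 0L
  for (i in seq_len(n_agents)) {
    p <- rlwm_params(true[i, 1], true[i, 2], true[i, 3], true[i, 4],
                     true_C[i], true[i, 5])
    skel <- generate_session(config, seed = agent_seeds[i],
                             subject_id = sprintf("agent%03d", i))
    sim <- simulate_agent(p, skel, seed = agent_seeds[i] + 1L,
                          p_two_points = config$p_two_points)
    fit <- tryCatch(
      fit_subject(sim$trials, n_restarts = n_restarts,
                  seed = agent_seeds[i] + 2L, n_a = config$n_actions),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    rows[[i]] <- data.frame(
      agent = i,
      true_alpha = p$alpha, true_gamma = p$gamma, true_phi = p$phi,
      true_rho = p$rho, true_epsilon = p$epsilon, true_capacity = p$capacity,
      fit_alpha = fit$params$alpha, fit_gamma = fit$params$gamma,
      fit_phi = fit$params$phi, fit_rho = fit$params$rho,
      fit_epsilon = fit$params$epsilon, fit_capacity = fit$params$capacity,
      nll = fit$nll)
  }
  tab <- do.call(rbind, rows)
  metrics <- do.call(rbind, lapply(cont, function(nm) {
    tv <- tab[[paste0("true_", nm)]]
    fv <- tab[[paste0("fit_", nm)]]
    r <- if (stats::sd(tv) < 1e-12 || stats::sd(fv) < 1e-12) NA_real_
         else stats::cor(tv, fv)
    data.frame(parameter = nm, r = r,
               bias = mean(fv - tv),
               rmse = sqrt(mean((fv - tv)^2)))
  }))
  structure(
    list(table = tab, metrics = metrics,
         capacity_rate = mean(tab$fit_capacity == tab$true_capacity),
         n_failed = n_failed),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d agents (%d failed fits)\n",
              nrow(x$table) + x$n_failed, x$n_failed))
  print(x$metrics, row.names = FALSE)
  cat(sprintf("capacity exactly recovered: %.1f%%\n", 100 * x$capacity_rate))
  invisible(x)
}

#' Group comparison of fitted parameters
#'
#' One-way ANOVA per parameter across diagnostic groups, followed by Tukey
#' honest-significant-difference post hoc contrasts on every pair.
#'
#' @param params_table data.frame with a `group` column and one column per
#'   parameter to compare.
#' @param parameters character vector of parameter column names.
#' @return Named list per parameter with `anova` (F, df, p) and `tukey`
#'   (pairwise mean differences, 95\% CIs, adjusted p-values).
#' @export
compare_group_params <- function(params_table,
                                 parameters = c("alpha", "gamma", "phi",
                                                "rho", "epsilon")) {
  if (!"group" %in% names(params_table)) stop("`group` column required")
  g <- factor(params_table$group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 subjects")
  out <- list()
  for (nm in parameters) {
    y <- params_table[[nm]]
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    out[[nm]] <- list(
      anova = data.frame(F = an$`F value`[1],
                         df1 = an$Df[1], df2 = an$Df[2],
                         p = an$`Pr(>F)`[1]),
      tukey = data.frame(contrast = rownames(tk),
                         diff = tk[, "diff"], lwr = tk[, "lwr"],
                         upr = tk[, "upr"], p_adj = tk[, "p adj"],
                         row.names = NULL))
  }
  out
}

#' Flag parameter outliers
#'
#' Default rule: a subject is flagged if any parameter falls more than
#' `k` interquartile ranges outside the sample quartiles of that
#' parameter. Used for sensitivity re-analysis of group contrasts.
#'
#' @param params_table fitted-parameter data.frame.
#' @param parameters columns the rule applies to.
#' @param k IQR multiplier (default 1.5; `Inf` disables flagging).
#' @return list(mask = logical outlier flags, filtered = table without
#'   flagged rows).
#' @export
flag_outliers <- function(params_table,
                          parameters = c("alpha", "gamma", "phi",
                                         "rho", "epsilon"),
                          k = 1.5) {
  mask <- rep(FALSE, nrow(params_table))
  for (nm in parameters) {
    x <- params_table[[nm]]
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    lo <- qs[1] - k * iqr
    hi <- qs[2] + k * iqr
    mask <- mask | (x < lo) | (x > hi)
  }
  mask[is.na(mask)] <- FALSE
  list(mask = mask, filtered = params_table[!mask, , drop = FALSE])
}
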