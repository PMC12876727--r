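#' Fit a mixed-effects model with subject random intercepts
#'
#' Thin wrapper over lme4 that fits either a logistic (binomial) or linear
#' (gaussian) mixed model with a random intercept per subject, z-scores
#' continuous covariates within subject beforehand, and reports
#' Wald-approximate coefficients (estimate, SE, z, p, 95\% CI). Group
#' factors are treatment-coded against the configured reference level.
#'
#' @param data model data.frame containing `subject_id`.
#' @param formula fixed-effects formula (response on the left); the
#'   subject random intercept is appended automatically.
#' @param family `"gaussian"` or `"binomial"`.
#' @param scale_covariates character vector of continuous covariates to
#'   z-score within subject before fitting (default: none; the batteries
#'   pass their own lists).
#' @param reference_group reference level for a `group` factor, if present.
#' @return An object of class `coef_report`: `coefficients` data.frame,
#'   `singular` flag, `fit` (the lme4 object).
#' @export
fit_mixed_model <- function(data, formula,
                            family = c("gaussian", "binomial"),
                            scale_covariates = character(),
                            reference_group = "CTRL") {
  family <- match.arg(family)
  if (!"subject_id" %in% names(data)) stop("`subject_id` column required")
  if (length(unique(data$subject_id)) < 2L) {
    stop("need at least 2 subjects")
  }
  for (nm in scale_covariates) {
    data[[nm]] <- stats::ave(data[[nm]], data$subject_id, FUN = function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s < 1e-12) x - mean(x) else (x - mean(x)) / s
    })
  }
  if ("group" %in% names(data)) {
    g <- factor(data$group)
    if (reference_group %in% levels(g)) {
      g <- stats::relevel(g, ref = reference_group)
    }
    data$group <- g
  }
  full <- stats::update(stats::as.formula(formula), . ~ . + (1 | subject_id))
  fit <- if (family == "gaussian") {
    lme4::lmer(full, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    lme4::glmer(full, data = data, family = stats::binomial(),
                control = lme4::glmerControl(
                  optimizer = "bobyqa", check.conv.singular = "ignore"))
  }
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf / se
  coefficients <- data.frame(
    term = names(cf), estimate = unname(cf), se = unname(se),
    z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
    ci_lo = unname(cf - 1.96 * se), ci_hi = unname(cf + 1.96 * se))
  structure(list(coefficients = coefficients,
                 singular = lme4::isSingular(fit), fit = fit),
            class = "coef_report")
}

#' @export
print.coef_report <- function(x, ...) {
  df <- x$coefficients
  df$estimate <- round(df$estimate, 4)
  df$se <- round(df$se, 4)
  df$p <- signif(df$p, 3)
  print(df[, c("term", "estimate", "se", "p")], row.names = FALSE)
  if (x$singular) cat("note: singular random-effects fit\n")
  invisible(x)
}

.coef_of <- function(report, term) {
  i <- match(term, report$coefficients$term)
  if (is.na(i)) stop("term not in model: ", term)
  report$coefficients[i, ]
}

#' Behavioral accuracy regressions
#'
#' The trial-level accuracy models: (i) accuracy on set size x delay x
#' reward history; (ii) the same with diagnostic-group interactions;
#' (iii) optionally, the moderation variant adding the trialwise neural
#' set-size marker. Logistic mixed models with subject random
#' intercepts; trials with undefined delay are dropped; continuous
#' covariates are z-scored within subject.
#'
#' @param trials cohort trial table (with `group` when model (ii) is
#'   wanted).
#' @param set_size_marker optional data.frame (`subject_id`, `block`,
#'   `trial`, `marker`) enabling the moderation model.
#' @return Named list of `coef_report`s: `demand`, `demand_by_group`
#'   (when groups present), `moderation` (when a marker is given).
#' @export
behavioral_battery <- function(trials, set_size_marker = NULL) {
  d <- trials[!is.na(trials$delay), , drop = FALSE]
  if (length(unique(d$correct)) < 2L) {
    stop("accuracy is constant after the delay-defined exclusion; ",
         "the sample is too small or at ceiling")
  }
  covs <- c("set_size", "delay", "pcor")
  out <- list()
  out$demand <- fit_mixed_model(
    d, correct ~ set_size * delay * pcor, family = "binomial",
    scale_covariates = covs)
  if ("group" %in% names(d) && length(unique(d$group)) > 1L) {
    out$demand_by_group <- fit_mixed_model(
      d, correct ~ (set_size + delay + pcor) * group +
        set_size:pcor, family = "binomial",
      scale_covariates = covs)
  }
  if (!is.null(set_size_marker)) {
    key_d <- paste(d$subject_id, d$block, d$trial)
    key_m <- paste(set_size_marker$subject_id, set_size_marker$block,
                   set_size_marker$trial)
    d$ss_marker <- set_size_marker$marker[match(key_d, key_m)]
    dm <- d[!is.na(d$ss_marker), , drop = FALSE]
    f <- if ("group" %in% names(dm) && length(unique(dm$group)) > 1L) {
      correct ~ set_size * ss_marker + pcor + delay + set_size:group
    } else {
      correct ~ set_size * ss_marker + pcor + delay
    }
    out$moderation <- fit_mixed_model(
      dm, f, family = "binomial",
      scale_covariates = c(covs, "ss_marker"))
  }
  out
}

#' Neural-marker regressions
#'
#' The marker-level models: the neural RL marker on reward history, set
#' size and the neural set-size marker; the neural set-size marker on set
#' size and reward history (with group interactions when groups are
#' present — the WM recruitment and WM management effects); the neural
#' RPE marker on reward history, set size, the set-size marker and the
#' same-trial neural RL marker (optionally also the model-derived RPE);
#' and asymptotic accuracy on the asymptotic RL marker x reward history.
#'
#' @param trials cohort trial table.
#' @param markers named list of marker data.frames (`rl`, `set_size`,
#'   `rpe`), each with `subject_id`, `block`, `trial`, `marker`.
#' @param latents optional latent traces; adds the model RPE covariate to
#'   the RPE model.
#' @return Named list of `coef_report`s.
#' @export
marker_battery <- function(trials, markers, latents = NULL) {
  key_t <- paste(trials$subject_id, trials$block, trials$trial)
  join <- function(mk) mk$marker[match(key_t, paste(mk$subject_id, mk$block,
                                                    mk$trial))]
  d <- trials
  d$rl_marker <- join(markers$rl)
  d$ss_marker <- join(markers$set_size)
  d$rpe_marker <- join(markers$rpe)
  if (!is.null(latents)) {
    key_l <- paste(latents$subject_id, latents$block, latents$trial)
    d$model_rpe <- latents$rpe[match(key_t, key_l)]
  }
  covs <- c("set_size", "pcor")
  has_group <- "group" %in% names(d) && length(unique(d$group)) > 1L
  out <- list()
  drl <- d[!is.na(d$rl_marker) & !is.na(d$ss_marker), , drop = FALSE]
  out$rl_marker <- fit_mixed_model(
    drl, rl_marker ~ pcor * set_size * ss_marker, family = "gaussian",
    scale_covariates = c(covs, "ss_marker"))
  dss <- d[!is.na(d$ss_marker), , drop = FALSE]
  out$ss_marker <- fit_mixed_model(
    dss,
    if (has_group) ss_marker ~ set_size * group + pcor * group
    else ss_marker ~ set_size * pcor,
    family = "gaussian", scale_covariates = covs)
  drpe <- d[!is.na(d$rpe_marker) & !is.na(d$rl_marker) &
              !is.na(d$ss_marker), , drop = FALSE]
  f_rpe <- if (is.null(latents)) {
    rpe_marker ~ pcor + set_size + ss_marker + rl_marker
  } else {
    rpe_marker ~ pcor + set_size + ss_marker + rl_marker + model_rpe
  }
  out$rpe_marker <- fit_mixed_model(
    drpe, f_rpe, family = "gaussian",
    scale_covariates = intersect(c(covs, "ss_marker", "rl_marker",
                                   "model_rpe"), names(drpe)))
  # asymptotic accuracy ~ asymptotic RL marker x reward history
  asym_rl <- asymptotic_marker(markers$rl, trials)
  acc <- stats::aggregate(
    cbind(acc = trials$correct, pcor = trials$pcor) ~
      subject_id + block + stimulus,
    data = cbind(trials[, c("subject_id", "block", "stimulus")],
                 correct = trials$correct, pcor = trials$pcor),
    FUN = mean)
  key_a <- paste(asym_rl$subject_id, asym_rl$block, asym_rl$stimulus)
  key_c <- paste(acc$subject_id, acc$block, acc$stimulus)
  asym_rl$acc <- acc$acc[match(key_a, key_c)]
  asym_rl$pcor <- acc$pcor[match(key_a, key_c)]
  out$asymptotic_accuracy <- fit_mixed_model(
    asym_rl, acc ~ marker_asym * pcor, family = "gaussian",
    scale_covariates = c("marker_asym", "pcor"))
  out
}

#' Cohort-table statistics
#'
#' Pearson chi-square tests of independence on demographic contingency
#' tables (no continuity correction), standardized residuals, pairwise
#' proportion comparisons with Holm adjustment, and one-way ANOVA from
#' per-group summary statistics (n, mean, SD) for variables where only
#' summaries exist.
#'
#' @param counts contingency matrix (groups x categories), with any
#'   category merges or exclusions already applied.
#' @return list(chisq = list(statistic, df, p, expected, stdres),
#'   pairwise = Holm-adjusted pairwise p matrix when 2 categories).
#' @export
cohort_table_stats <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  if (any(ct$expected < 1)) {
    warning("expected cell count below 1; chi-square approximation weak")
  }
  out <- list(chisq = list(statistic = unname(ct$statistic),
                           df = unname(ct$parameter),
                           p = ct$p.value,
                           expected = ct$expected,
                           stdres = ct$stdres))
  if (ncol(counts) == 2L) {
    pw <- stats::pairwise.prop.test(counts, p.adjust.method = "holm")
    out$pairwise <- pw$p.value
  }
  out
}

#' One-way ANOVA from per-group summary statistics
#'
#' Textbook decomposition: between-group and within-group sums of squares
#' computed from group sizes, means and SDs.
#'
#' @param n,means,sds equal-length vectors of group sizes, means, SDs.
#' @return list(F, df1, df2, p).
#' @export
anova_from_summary <- function(n, means, sds) {
  k <- length(n)
  if (k < 2L) stop("need at least 2 groups")
  grand <- sum(n * means) / sum(n)
  ss_b <- sum(n * (means - grand)^2)
  ss_w <- sum((n - 1) * sds^2)
  df1 <- k - 1L
  df2 <- sum(n) - k
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the end-to-end analysis on a forward-generated cohort:
#' behavior simulation, per-subject model fitting, EEG simulation,
#' mass-univariate robust regression, group cluster tests, marker
#' extraction, the behavioral and marker batteries, group parameter
#' comparisons, and the planted-effect checks (higher WM decay in the
#' SCZ/BP analogues, lower gamma in the SCZ analogue, blunted
#' reward-history coupling of the set-size marker in the MDD analogue).
#'
#' @param preset fixture size preset, see [make_fixture()].
#' @param seed integer master seed.
#' @param n_restarts restarts per capacity for subject fits.
#' @param n_perm permutations for the group cluster tests.
#' @param batteries run the behavioral and marker regression batteries
#'   (disable for a fits-and-markers-only pass).
#' @param snr footprint signal-to-noise ratio of the simulated EEG, see
#'   [snr_noise_sd()].
#' @param out_dir optional directory for the results JSON.
#' @param progress print stage progress.
#' @return list with `subjects`, `fits`, `cluster`, `markers`,
#'   `batteries`, `param_anova`, `planted_checks`, and `json_path` when
#'   `out_dir` is given.
#' @export
run_pipeline <- function(preset = "ci", seed = 1L, n_restarts = 8L,
                         n_perm = 1000L, snr = 1, batteries = TRUE,
                         out_dir = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(...)
  sizes <- switch(preset,
    tiny = list(n = 2L, config = task_config(set_sizes = c(2L, 4L),
                                             iterations_per_stimulus = 8L)),
    ci = list(n = 20L, config = task_config()),
    full = list(n = 40L, config = task_config()))
  spec <- default_cohort_spec(sizes$n)
  subjects <- sample_cohort(spec, seed = seed)
  say("simulating behavior for ", nrow(subjects), " subjects")
  beh <- simulate_behavior_cohort(subjects, sizes$config, seed = seed + 1L)

  say("fitting the model per subject")
  fit_rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    tr <- beh$trials[beh$trials$subject_id == subjects$subject_id[i], ]
    ft <- fit_subject(tr, n_restarts = n_restarts, seed = seed + 100L + i,
                      n_a = sizes$config$n_actions)
    fit_rows[[i]] <- data.frame(
      subject_id = subjects$subject_id[i], group = subjects$group[i],
      alpha = ft$params$alpha, gamma = ft$params$gamma,
      phi = ft$params$phi, rho = ft$params$rho,
      epsilon = ft$params$epsilon, capacity = ft$params$capacity,
      nll = ft$nll)
  }
  fits <- do.call(rbind, fit_rows)

  say("simulating and regressing EEG")
  templates <- template_library()
  locks <- c(stimulus = "stimulus", feedback = "feedback")
  beta_maps <- list(stimulus = list(), feedback = list())
  zepochs <- list(stimulus = list(), feedback = list())
  designs <- list(stimulus = list(), feedback = list())
  noise_sd <- snr_noise_sd(templates, gain = spec$CTRL$gains[["q_value"]],
                           snr = snr)
  for (lk in locks) {
    eps <- cohort_epochs(subjects, beh, templates, lock = lk,
                         seed = seed + 2L + match(lk, locks),
                         noise_sd = noise_sd)
    for (sid in subjects$subject_id) {
      tr <- beh$trials[beh$trials$subject_id == sid, ]
      la <- beh$latents[beh$latents$subject_id == sid, ]
      des <- build_design(tr, la, lock = lk)
      ze <- zscore_epochs(eps[[sid]], des$included)
      beta_maps[[lk]][[sid]] <- robust_mass_univariate(ze, des)
      zepochs[[lk]][[sid]] <- ze
      designs[[lk]][[sid]] <- des
    }
    rm(eps)
  }

  say("group cluster tests")
  adj <- channel_adjacency()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 7L)
  cluster <- list(
    q_value = group_cluster_test(beta_maps$stimulus, "q_value", adj,
                                 n_perm = n_perm),
    set_size = group_cluster_test(beta_maps$stimulus, "set_size", adj,
                                  n_perm = n_perm),
    rpe = group_cluster_test(beta_maps$feedback, "rpe", adj,
                             n_perm = n_perm))

  say("extracting trial markers")
  get_markers <- function(lk, mask) {
    if (!any(mask$mask)) return(NULL)   # an empty mask is a legal outcome
    do.call(rbind, lapply(subjects$subject_id, function(sid) {
      extract_trial_marker(zepochs[[lk]][[sid]], mask)
    }))
  }
  markers <- list(rl = get_markers("stimulus", cluster$q_value),
                  set_size = get_markers("stimulus", cluster$set_size),
                  rpe = get_markers("feedback", cluster$rpe))

  battery_out <- list()
  if (batteries) {
    say("regression batteries")
    battery_out$behavioral <- tryCatch(
      behavioral_battery(beh$trials, markers$set_size),
      error = function(e) conditionMessage(e))
    if (!any(vapply(markers, is.null, logical(1)))) {
      battery_out$marker <- tryCatch(
        marker_battery(beh$trials, markers, beh$latents),
        error = function(e) conditionMessage(e))
    }
  }
  param_anova <- compare_group_params(fits)

  # planted-effect checks; rank tests because fitted parameters are
  # bounded and pile up at the box edges
  phi_t <- stats::wilcox.test(fits$phi[fits$group %in% c("SCZ", "BP")],
                              fits$phi[fits$group == "CTRL"],
                              alternative = "greater", exact = FALSE)
  gamma_t <- stats::wilcox.test(fits$gamma[fits$group == "SCZ"],
                                fits$gamma[fits$group == "CTRL"],
                                alternative = "less", exact = FALSE)
  mdd_check <- list(estimate = NA_real_, p = NA_real_, pass = FALSE)
  if (!is.null(markers$set_size)) {
    slope_fit <- fit_mixed_model(
      merge(markers$set_size,
            beh$trials[, c("subject_id", "block", "trial", "group",
                           "pcor")],
            by = c("subject_id", "block", "trial")),
      marker ~ pcor * group, family = "gaussian",
      scale_covariates = "pcor")
    sl <- .coef_of(slope_fit, "pcor:groupMDD")
    mdd_check <- list(
      estimate = sl$estimate,
      p = stats::pnorm(sl$z),           # one-sided, negative direction
      pass = sl$estimate < 0 && stats::pnorm(sl$z) < 0.05)
  }
  planted_checks <- list(
    scz_bp_phi_gt_ctrl = list(p = phi_t$p.value,
                              pass = phi_t$p.value < 0.05),
    scz_gamma_lt_ctrl = list(p = gamma_t$p.value,
                             pass = gamma_t$p.value < 0.05),
    mdd_pcor_slope_lt_ctrl = mdd_check)

  res <- list(subjects = subjects, fits = fits, cluster = cluster,
              markers = markers, batteries = battery_out,
              param_anova = param_anova, planted_checks = planted_checks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(out_dir, "results.json")
    report <- list(
      seed = seed, preset = preset,
      n_subjects = nrow(subjects),
      planted_checks = lapply(planted_checks, function(x) {
        x$pass <- as.logical(x$pass); x
      }),
      fitted_params_by_group = stats::aggregate(
        fits[, c("alpha", "gamma", "phi", "rho", "epsilon")],
        by = list(group = fits$group), FUN = mean),
      mask_cells = lapply(cluster, function(cm) sum(cm$mask)))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
    res$json_path <- json_path
  }
  res
}
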