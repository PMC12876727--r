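test_that("uniform responding is fitted as a uniform policy", {
  p_noise <- rlwm_params(0.1, 0.5, 0.3, 0.8, 3, 0.999)
  sim <- simulated_session(seed = 51L, params = p_noise)
  f <- fit_subject(sim$trials, n_restarts = 4L, seed = 1L)
  # the optimum sits on the uniform-policy ridge: NLL ~ T log 3. (epsilon
  # itself is unidentified there — alpha ~ 0 with rho ~ 0 is an equally
  # uniform solution — so the policy, not the parameter, is asserted.)
  expect_lt(abs(f$nll - nrow(sim$trials) * log(3)), 0.05 * f$nll)
  lat <- compute_latents(f$params, sim$trials)
  expect_lt(mean(abs(lat$choice_prob - 1 / 3)), 0.06)
})

test_that("fitting is deterministic and monotone in restarts", {
  sim <- simulated_session(seed = 52L)
  f1 <- fit_subject(sim$trials, n_restarts = 4L, seed = 5L)
  f2 <- fit_subject(sim$trials, n_restarts = 4L, seed = 5L)
  expect_identical(f1, f2)
  f3 <- fit_subject(sim$trials, n_restarts = 8L, seed = 5L)
  expect_lte(f3$nll, f1$nll)
})

test_that("fitted likelihood never falls below the optimizer's own bound", {
  set.seed(61)
  for (rep in 1:4) {
    p <- rlwm_params(runif(1, .02, .15), runif(1, .2, .9),
                     runif(1, .1, .5), runif(1, .6, .95),
                     sample(2:5, 1), runif(1, .02, .25))
    sim <- simulated_session(seed = 70L + rep, params = p)
    f <- fit_subject(sim$trials, n_restarts = 6L, seed = 80L + rep)
    # MLE at least as good as the generating parameters
    expect_lte(f$nll, session_nll(p, sim$trials) + 1e-8)
    # reported best equals the minimum of the capacity profile
    expect_equal(f$nll, min(f$capacity_nll), tolerance = 1e-12)
    # box constraints respected
    expect_true(f$params$alpha > 0 && f$params$alpha < 0.3)
    expect_true(all(c(f$params$gamma, f$params$phi, f$params$rho,
                      f$params$epsilon) > 0))
    expect_true(all(c(f$params$gamma, f$params$phi, f$params$rho,
                      f$params$epsilon) < 1))
  }
})

test_that("fitting validates its inputs", {
  sim <- simulated_session(seed = 53L)
  one_block <- sim$trials[sim$trials$block == 1L, ]
  expect_error(fit_subject(one_block), "2 blocks")
  expect_error(fit_subject(sim$trials, capacity_grid = c(1, 9)), "2..5")
  expect_error(fit_subject(sim$trials, n_restarts = 0L), "n_restarts")
  # beta / alpha_wm are fixed constants, not reachable through fitting
  expect_false(any(c("beta", "alpha_wm") %in%
                     names(formals(fit_subject))))
})

test_that("degenerate recovery sampling collapses to the sampled point", {
  rg <- list(alpha = c(0.08, 0.08), gamma = c(0.5, 0.5),
             phi = c(0.3, 0.3), rho = c(0.85, 0.85),
             epsilon = c(0.1, 0.1), capacity = 3L)
  rec <- recover_parameters(n_agents = 3L, ranges = rg,
                            config = tiny_config(), n_restarts = 2L,
                            seed = 2L)
  expect_true(all(rec$table$true_alpha == 0.08))
  expect_true(all(rec$table$true_capacity == 3L))
  expect_equal(rec$metrics$bias[rec$metrics$parameter == "phi"],
               mean(rec$table$fit_phi - 0.3))
  expect_error(recover_parameters(n_agents = 1L), "n_agents")
  bad <- rg; bad$alpha <- c(0.5, 0.6)
  expect_error(recover_parameters(n_agents = 3L, ranges = bad), "box")
})

test_that("group ANOVA and Tukey contrasts behave on null and planted data", {
  set.seed(9)
  null_tab <- data.frame(group = rep(c("A", "B"), each = 20),
                         phi = rep(rnorm(20, 0.3, 0.05), 2))
  res <- compare_group_params(null_tab, parameters = "phi")
  expect_lt(res$phi$anova$F, 1e-10)
  expect_lt(abs(res$phi$tukey$diff), 1e-12)

  shift_tab <- data.frame(
    group = rep(c("CTRL", "SCZ"), each = 40),
    phi = c(rnorm(40, 0.25, 0.06), rnorm(40, 0.35, 0.06)))
  res2 <- compare_group_params(shift_tab, parameters = "phi")
  row <- res2$phi$tukey[res2$phi$tukey$contrast == "SCZ-CTRL", ]
  expect_gt(row$diff, 0)
  expect_lt(row$p_adj, 0.05)

  expect_error(compare_group_params(data.frame(group = "A", phi = 1)),
               "2 groups")
})

test_that("ANOVA from summary statistics matches aov on raw data", {
  set.seed(12)
  y <- c(rnorm(15, 10, 2), rnorm(15, 11, 2), rnorm(15, 12.5, 2))
  g <- factor(rep(1:3, each = 15))
  raw <- summary(stats::aov(y ~ g))[[1]]
  summ <- anova_from_summary(n = tapply(y, g, length),
                             means = tapply(y, g, mean),
                             sds = tapply(y, g, sd))
  expect_equal(summ$F, raw$`F value`[1], tolerance = 1e-10)
  expect_equal(summ$p, raw$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(summ$df1, raw$Df[1])
  expect_equal(summ$df2, raw$Df[2])
})

test_that("outlier flagging applies the IQR rule with sane boundaries", {
  tab <- data.frame(phi = c(runif(30, 0.1, 0.3), 0.999),
                    alpha = runif(31, 0.02, 0.1))
  res <- flag_outliers(tab, parameters = c("phi", "alpha"))
  expect_true(res$mask[31])
  expect_equal(nrow(res$filtered), sum(!res$mask))
  # identical values: zero IQR flags nothing
  same <- data.frame(phi = rep(0.3, 10))
  expect_false(any(flag_outliers(same, parameters = "phi")$mask))
  # infinite threshold disables the rule
  expect_false(any(flag_outliers(tab, parameters = c("phi", "alpha"),
                                 k = Inf)$mask))
})
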