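# small synthetic epoch helper: n trials x nch channels x nt timepoints of
# white noise plus optional per-trial signal painted on given cells
noise_epochs <- function(n = 40L, nch = 6L, nt = 20L, seed = 1L,
                         lock = "stimulus", subject = "s01") {
  set.seed(seed)
  v <- array(rnorm(n * nch * nt), dim = c(n, nch, nt))
  epoch_set(v, scalp_montage()$channel[seq_len(nch)],
            seq(0, by = 8, length.out = nt), lock,
            data.frame(subject_id = subject, block = 1L, trial = seq_len(n)))
}

test_that("epoch container validates axes and keys", {
  e <- noise_epochs()
  expect_s3_class(e, "epoch_set")
  expect_error(epoch_set(array(0, c(4, 2, 3)), c("a", "b"), c(0, 8, 17),
                         "stimulus",
                         data.frame(subject_id = "s", block = 1,
                                    trial = 1:4)),
               "uniformly spaced")
  expect_error(epoch_set(array(0, c(2, 2, 2)), c("a", "b"), c(0, 8),
                         "stimulus",
                         data.frame(subject_id = "s", block = 1,
                                    trial = c(1, 1))),
               "unique")
})

test_that("z-scoring standardises every cell and is idempotent", {
  e <- noise_epochs(seed = 3)
  z <- zscore_epochs(e)
  mu <- apply(z$voltages, c(2, 3), mean)
  sd <- apply(z$voltages, c(2, 3), sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(max(abs(sd - 1)), 1e-10)
  z2 <- zscore_epochs(z)
  expect_equal(z2$voltages, z$voltages, tolerance = 1e-10)
  # constant channel is an error naming the cell
  e$voltages[, 2, 5] <- 7
  expect_error(zscore_epochs(e), "zero variance.*Fp2")
  expect_error(zscore_epochs(noise_epochs(n = 12), trial_mask = rep(c(TRUE, FALSE), 6)),
               "10 included")
})

test_that("design construction filters, z-scores and names regressors", {
  sim <- simulated_session(seed = 31L)
  tr <- sim$trials
  des <- build_design(tr, sim$latents, lock = "stimulus")
  expect_equal(nrow(des$X), sum(tr$correct == 1 & !is.na(tr$delay)))
  expect_true(all(c("set_size", "q_value", "delay",
                    "set_size_x_q_value_x_delay", "log_rt",
                    "trial_in_block") %in% colnames(des$X)))
  expect_lt(max(abs(colMeans(des$X))), 1e-10)
  expect_lt(max(abs(apply(des$X, 2, sd) - 1)), 1e-10)
  # feedback lock swaps the value regressor for the RPE
  des_fb <- build_design(tr, sim$latents, lock = "feedback")
  expect_true("rpe" %in% colnames(des_fb$X))
  expect_false("q_value" %in% colnames(des_fb$X))
  # single-block input has constant set size: named degenerate column
  one <- tr[tr$block == 1, ]
  expect_error(build_design(one, sim$latents, lock = "stimulus"),
               "set_size")
})

test_that("robust regression recovers planted effects and resists outliers", {
  set.seed(44)
  n <- 300L
  x <- rnorm(n)
  X <- cbind(q_value = (x - mean(x)) / sd(x))
  nch <- 2L; nt <- 3L
  v <- array(rnorm(n * nch * nt, sd = 0.1), dim = c(n, nch, nt))
  v[, 1, 2] <- 0.5 * X[, 1] + rnorm(n, sd = 0.1)
  e <- epoch_set(v, c("Cz", "Pz"), c(0, 8, 16), "stimulus",
                 data.frame(subject_id = "s", block = 1, trial = 1:n))
  bm <- robust_mass_univariate(e, list(X = X))
  expect_lt(abs(bm$beta["q_value", 1, 2] - 0.5), 0.05)
  expect_lt(abs(bm$beta["q_value", 2, 2]), 0.05)

  # 5% gross outliers: Huber stays close, OLS does not
  v2 <- v
  bad <- sample(n, 15)
  v2[bad, 1, 2] <- v2[bad, 1, 2] + 50 * sample(c(-1, 1), 15, replace = TRUE)
  e2 <- epoch_set(v2, c("Cz", "Pz"), c(0, 8, 16), "stimulus",
                  e$trial_keys)
  bm2 <- robust_mass_univariate(e2, list(X = X))
  ols <- coef(lm(v2[, 1, 2] ~ X))[2]
  expect_lt(abs(bm2$beta["q_value", 1, 2] - 0.5), 0.1)
  expect_gt(abs(ols - 0.5), abs(bm2$beta["q_value", 1, 2] - 0.5))
})

test_that("robust estimates agree with an independent Huber implementation", {
  skip_if_not_installed("MASS")
  set.seed(45)
  n <- 120L
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 0.3 * X[, 1] - 0.2 * X[, 2] + rt(n, df = 3) * 0.3
  e <- epoch_set(array(y, c(n, 1, 1)), "Cz", 0, "stimulus",
                 data.frame(subject_id = "s", block = 1, trial = 1:n))
  bm <- robust_mass_univariate(e, list(X = X), tol = 1e-9, maxit = 200)
  ref <- MASS::rlm(y ~ X, k = 1.345, maxit = 200, acc = 1e-9)
  expect_equal(unname(bm$beta[, 1, 1]), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("cluster permutation is deterministic and finds planted effects", {
  set.seed(46)
  nch <- 8L; nt <- 15L; ns <- 30L
  mont <- scalp_montage()[1:nch, ]
  adj <- channel_adjacency(mont)
  mk_maps <- function(effect) {
    lapply(seq_len(ns), function(i) {
      b <- array(rnorm(2 * nch * nt, sd = 1), dim = c(2, nch, nt))
      dimnames(b) <- list(c("(Intercept)", "q_value"), mont$channel, NULL)
      if (effect) b["q_value", 1:4, 5:10] <- b["q_value", 1:4, 5:10] + 0.8
      structure(list(beta = b, channels = mont$channel,
                     times_ms = seq(0, by = 8, length.out = nt),
                     lock = "stimulus"), class = "beta_map")
    })
  }
  maps <- mk_maps(TRUE)
  set.seed(10)
  m1 <- group_cluster_test(maps, "q_value", adj, n_perm = 300)
  set.seed(10)
  m2 <- group_cluster_test(maps, "q_value", adj, n_perm = 300)
  expect_identical(m1$mask, m2$mask)
  # detects the planted patch with sensible overlap
  truth <- matrix(FALSE, nch, nt); truth[1:4, 5:10] <- TRUE
  jac <- sum(m1$mask & truth) / sum(m1$mask | truth)
  expect_gt(jac, 0.4)
  expect_true(all(m1$sign[m1$mask] == 1))
  expect_error(group_cluster_test(maps, "q_value", adj, n_perm = 50),
               "100 permutations")
  expect_error(group_cluster_test(maps[1:4], "q_value", adj), "8 subjects")
})

test_that("marker extraction reduces to cells and respects sign alignment", {
  e <- noise_epochs(n = 15L, nch = 4L, nt = 6L, seed = 8)
  z <- zscore_epochs(e)
  mask <- list(mask = matrix(FALSE, 4, 6), sign = matrix(0L, 4, 6))
  mask$mask[2, 3] <- TRUE; mask$sign[2, 3] <- 1L
  mk <- extract_trial_marker(z, mask)
  expect_equal(mk$marker, z$voltages[, 2, 3])
  # all-negative mask: marker equals the negated mean over cells
  mask2 <- list(mask = matrix(FALSE, 4, 6), sign = matrix(0L, 4, 6))
  mask2$mask[c(1, 3), 2] <- TRUE; mask2$sign[c(1, 3), 2] <- -1L
  mk2 <- extract_trial_marker(z, mask2)
  expect_equal(mk2$marker,
               -(z$voltages[, 1, 2] + z$voltages[, 3, 2]) / 2,
               tolerance = 1e-12)
  empty <- list(mask = matrix(FALSE, 4, 6), sign = matrix(0L, 4, 6))
  expect_error(extract_trial_marker(z, empty), "empty")
})

test_that("marker pipeline is invariant to affine voltage rescaling", {
  e <- noise_epochs(n = 30L, nch = 4L, nt = 6L, seed = 9)
  e2 <- e
  e2$voltages <- e2$voltages * 13.7 + 2.2
  mask <- list(mask = matrix(FALSE, 4, 6), sign = matrix(0L, 4, 6))
  mask$mask[1:2, 2:3] <- TRUE; mask$sign[1:2, 2:3] <- 1L
  m1 <- extract_trial_marker(zscore_epochs(e), mask)
  m2 <- extract_trial_marker(zscore_epochs(e2), mask)
  expect_equal(m1$marker, m2$marker, tolerance = 1e-10)
})

test_that("asymptotic summary averages the final four iterations", {
  tr <- data.frame(subject_id = "s", block = 1L, trial = 1:13,
                   stimulus = 1L, iteration = 1:13)
  mk <- data.frame(subject_id = "s", block = 1L, trial = 1:13,
                   marker = as.numeric(1:13))
  out <- asymptotic_marker(mk, tr)
  expect_equal(out$marker_asym, mean(10:13))
  expect_false(out$flagged)
  # exactly four iterations: mean of all four, and (1,2,3,4) -> 2.5
  tr4 <- tr[1:4, ]; mk4 <- mk[1:4, ]
  expect_equal(asymptotic_marker(mk4, tr4)$marker_asym, 2.5)
  # fewer than four: summarised over what exists, flagged
  out2 <- asymptotic_marker(mk[1:2, ], tr[1:2, ])
  expect_equal(out2$marker_asym, 1.5)
  expect_true(out2$flagged)
})

test_that("epoch sets round-trip through HDF5", {
  e <- noise_epochs(n = 12L, nch = 3L, nt = 5L, seed = 13,
                    lock = "feedback")
  path <- withr::local_tempfile(fileext = ".h5")
  write_epochs(e, path)
  back <- read_epochs(path)
  expect_equal(back$voltages, e$voltages, tolerance = 1e-12)
  expect_identical(back$channels, e$channels)
  expect_identical(back$lock, "feedback")
  expect_equal(back$trial_keys$trial, e$trial_keys$trial)
})
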