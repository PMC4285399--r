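test_that("canonical HRF has the stated landmarks", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_lt(abs(t[which.max(h)] - 6), 0.5)
  expect_equal(max(h), 1)
  expect_gt(sum(h), 0)              # peak dominates the undershoot
  expect_lt(min(h), 0)              # undershoot present
  expect_lt(abs(t[which.min(h)] - 16), 1.5)
  expect_error(canonical_hrf(0), "positive")
})

test_that("single-trial design has the expected structure", {
  ts <- simulate_timeseries(2, amplitudes = c(1, 1), tr = 2, seed = 1)
  dm <- build_single_trial_design(ts$events, tr = 2, n_volumes = ts$n_volumes)
  expect_length(dm$trial_columns, 2)
  expect_true(all(c("rating", "intercept", "drift") %in% dm$column_names))
  expect_equal(qr(dm$matrix)$rank, ncol(dm$matrix))
  # cosine count formula on a 200-volume run at tr = 2: floor(2*400/180) = 4
  ev <- data.frame(onset = c(20, 80, 150, 250), duration = 12.5,
                   type = "trial")
  dm2 <- build_single_trial_design(ev, tr = 2, n_volumes = 200)
  expect_equal(sum(grepl("^cos_", dm2$column_names)), 4)
  expect_equal(qr(dm2$matrix)$rank, ncol(dm2$matrix))
})

test_that("overlapping trial epochs and out-of-run events are rejected", {
  ev <- data.frame(onset = c(20, 25), duration = 12.5, type = "trial")
  expect_error(build_single_trial_design(ev, tr = 2, n_volumes = 100),
               "overlap")
  ev2 <- data.frame(onset = 390, duration = 12.5, type = "trial")
  expect_error(build_single_trial_design(ev2, tr = 2, n_volumes = 100),
               "fit within")
})

test_that("noise-free amplitudes are recovered exactly and match a pseudoinverse oracle", {
  amps <- c(3, -1, 2, 0.5, 4, 1.5)
  ts <- simulate_timeseries(6, amplitudes = amps, tr = 2, noise_sd = 0,
                            drift_slope = 7, seed = 2)
  dm <- build_single_trial_design(ts$events, tr = 2, n_volumes = ts$n_volumes)
  bs <- estimate_single_trial_betas(ts$series, dm)
  expect_equal(as.numeric(bs$betas), amps, tolerance = 1e-8)
  # constant shift absorbed by the intercept
  bs2 <- estimate_single_trial_betas(ts$series + 42, dm)
  expect_equal(bs2$betas, bs$betas, tolerance = 1e-10)
  # independent SVD-pseudoinverse oracle on a noisy series
  set.seed(3)
  noisy <- ts$series + rnorm(ts$n_volumes)
  bs3 <- estimate_single_trial_betas(noisy, dm)
  oracle <- pinv_solve(dm$matrix, noisy)[dm$trial_columns]
  expect_lt(max(abs(as.numeric(bs3$betas) - oracle)), 1e-10)
})

test_that("beta recovery is exact across many random noise-free designs", {
  set.seed(10)
  for (rep in 1:20) {
    n_tr <- sample(3:7, 1)
    amps <- rnorm(n_tr, 0, 3)
    ts <- simulate_timeseries(n_tr, amplitudes = amps, tr = 2, noise_sd = 0,
                              seed = rep)
    dm <- build_single_trial_design(ts$events, tr = 2,
                                    n_volumes = ts$n_volumes)
    bs <- estimate_single_trial_betas(ts$series, dm)
    expect_lt(max(abs(as.numeric(bs$betas) - amps)), 1e-6)
  }
})

test_that("VIFs match the brute-force 1/(1-R^2) oracle and flag exclusions at 2.5", {
  # mutually orthogonal (Hadamard) design -> all VIF 1
  H <- cbind(c(1, -1, 1, -1), c(1, -1, -1, 1), c(1, 1, 1, 1),
             c(1, 1, -1, -1))
  dm <- structure(list(matrix = H, trial_columns = 1:2,
                       nuisance_columns = 3:4,
                       column_names = c("t1", "t2", "n1", "n2"), tr = 2),
                  class = "design_matrix")
  expect_equal(compute_trial_vifs(dm), c(1, 1))
  # duplicated trial regressor -> infinite VIF, excluded
  ts <- simulate_timeseries(3, amplitudes = rep(1, 3), tr = 2, seed = 4)
  dmr <- build_single_trial_design(ts$events, tr = 2,
                                   n_volumes = ts$n_volumes)
  dup <- dmr
  dup$matrix <- cbind(dmr$matrix, dup_col = dmr$matrix[, 1])
  dup$nuisance_columns <- c(dup$nuisance_columns, ncol(dup$matrix))
  dup$column_names <- c(dmr$column_names, "dup_col")
  v <- compute_trial_vifs(dup)
  expect_equal(v[1], Inf)
  # constructed column with centered R^2 exactly 0.75 -> VIF = 4
  set.seed(5)
  n1 <- rnorm(200); n2 <- rnorm(200)
  base <- cbind(1, n1, n2)
  u <- residuals(lm(n1 ~ 1)); u <- u / sqrt(sum(u^2))     # in span(base)
  e <- rnorm(200); e <- residuals(lm(e ~ base))
  e <- e / sqrt(sum(e^2))                                  # orthogonal part
  xj <- sqrt(0.75) * u + sqrt(0.25) * e
  dm3 <- structure(list(matrix = cbind(xj = xj, base),
                        trial_columns = 1L, nuisance_columns = 2:4,
                        column_names = c("xj", "int", "n1", "n2"), tr = 2),
                   class = "design_matrix")
  expect_equal(compute_trial_vifs(dm3), 4, tolerance = 1e-8)
  # random designs vs the regression oracle
  set.seed(6)
  for (rep in 1:5) {
    M <- cbind(1, matrix(rnorm(50 * 7), 50, 7))
    colnames(M) <- paste0("c", 1:8)
    dm4 <- structure(list(matrix = M, trial_columns = 2:4,
                          nuisance_columns = c(1L, 5:8),
                          column_names = colnames(M), tr = 2),
                     class = "design_matrix")
    v4 <- compute_trial_vifs(dm4)
    oracle <- vapply(2:4, function(j) {
      r2 <- summary(lm(M[, j] ~ M[, -j] - 1))$r.squared
      # oracle: centered R^2 via explicit residual sums
      rss <- sum(residuals(lm(M[, j] ~ M[, -j] - 1))^2)
      tss <- sum((M[, j] - mean(M[, j]))^2)
      1 / (rss / tss)
    }, numeric(1))
    expect_lt(max(abs(v4 - oracle)), 1e-8)
  }
})

test_that("packing consecutive trial epochs closer inflates both trials' VIFs", {
  mk <- function(gap) {
    ev <- data.frame(onset = c(20, 20 + 12.5 + gap), duration = 12.5,
                     type = "trial")
    build_single_trial_design(ev, tr = 2, n_volumes = 120)
  }
  # monotone down to ~6-s gaps; below that the HRF undershoot makes the
  # regressor correlation (hence the VIF) non-monotone in the gap
  gaps <- c(30, 20, 12, 6)
  vifs <- t(vapply(gaps, function(g) compute_trial_vifs(mk(g)), numeric(2)))
  expect_true(all(diff(vifs[, 1]) >= -1e-8))
  expect_true(all(diff(vifs[, 2]) >= -1e-8))
  expect_gt(min(compute_trial_vifs(mk(2))), max(vifs[1, ]))
})

test_that("slow sinusoids inside the high-pass band barely move trial betas", {
  ts <- simulate_timeseries(11, amplitudes = rep(1, 11), tr = 2,
                            noise_sd = 0, seed = 5)
  dm <- build_single_trial_design(ts$events, tr = 2, n_volumes = ts$n_volumes)
  bs <- estimate_single_trial_betas(ts$series, dm)
  tt <- (0:(ts$n_volumes - 1)) * 2
  for (spec in list(c(400, 0.7), c(500, 1.5))) {
    sine <- sin(2 * pi * tt / spec[1] + spec[2])
    b2 <- estimate_single_trial_betas(ts$series + sine, dm)
    expect_lt(max(abs(b2$betas - bs$betas)), 0.01)
  }
  # near the 180-s cutoff the cosine filter rolls off gradually
  sine <- sin(2 * pi * tt / 300 + 0.3)
  b3 <- estimate_single_trial_betas(ts$series + sine, dm)
  expect_lt(max(abs(b3$betas - bs$betas)), 0.05)
})

test_that("rank-deficient designs raise with the offending column named", {
  ts <- simulate_timeseries(2, amplitudes = c(1, 1), tr = 2, seed = 7)
  dm <- build_single_trial_design(ts$events, tr = 2, n_volumes = ts$n_volumes)
  bad <- dm
  bad$matrix <- cbind(bad$matrix, intercept2 = bad$matrix[, "intercept"])
  bad$column_names <- c(dm$column_names, "intercept2")
  bad$nuisance_columns <- c(bad$nuisance_columns, ncol(bad$matrix))
  expect_error(estimate_single_trial_betas(ts$series, bad), "intercept")
})

test_that("concatenated runs get block-diagonal nuisance structure", {
  ts1 <- simulate_timeseries(3, amplitudes = 1:3, tr = 2, seed = 8)
  ts2 <- simulate_timeseries(3, amplitudes = 4:6, tr = 2, seed = 9)
  d1 <- build_single_trial_design(ts1$events, tr = 2, n_volumes = ts1$n_volumes)
  d2 <- build_single_trial_design(ts2$events, tr = 2, n_volumes = ts2$n_volumes)
  dc <- concatenate_designs(list(d1, d2))
  expect_length(dc$trial_columns, 6)
  bs <- estimate_single_trial_betas(c(ts1$series, ts2$series), dc)
  expect_equal(as.numeric(bs$betas), 1:6, tolerance = 1e-8)
  # run-2 intercept column is zero over run 1
  i2 <- which(dc$column_names == "run2_intercept")
  expect_true(all(dc$matrix[seq_len(ts1$n_volumes), i2] == 0))
})

test_that("injected spike volumes propagate to outlier detection end-to-end", {
  clean <- simulate_timeseries(4, amplitudes = rep(1, 4), tr = 2,
                               noise_sd = 0.2, seed = 10)
  spike_mag <- 10 * diff(range(clean$series)) # ten times the signal range
  ts <- simulate_timeseries(4, amplitudes = rep(1, 4), tr = 2,
                            noise_sd = 0.2, seed = 10,
                            outlier_spec = list(indices = 40,
                                                magnitude = spike_mag))
  # replicate the 1-D series across a small volume with voxel noise
  set.seed(11)
  arr <- array(rep(ts$series, each = 6 * 6 * 4), c(6, 6, 4, ts$n_volumes)) +
    array(rnorm(6 * 6 * 4 * ts$n_volumes, 0, 0.2), c(6, 6, 4, ts$n_volumes))
  flags <- detect_outlier_images(arr)
  expect_true(flags[40])
})
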