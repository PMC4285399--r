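test_that("noise-free subject fits recover the generating slopes exactly", {
  params <- noise_free_params(temp_to_pain = 4, reg_to_pain_direct = 2,
                              sig_to_pain = 0, m2_to_pain = 0)
  design <- generate_design(1, seed = 1)
  ds <- simulate_trial_responses(design, params, seed = 1)
  fit <- fit_subject_linear(ds)
  expect_equal(unname(fit$beta[c("reg_code", "temp", "reg_x_temp")]),
               c(2, 4, 0), tolerance = 1e-10)
  expect_true(isSymmetric(fit$cov))
  expect_true(all(eigen(fit$cov, only.values = TRUE)$values > -1e-12))
})

test_that("degenerate predictors are rejected with informative errors", {
  design <- generate_design(1, seed = 2)
  passive <- design[design$run_type == "passive", ]
  passive$rating <- rnorm(nrow(passive))
  expect_error(fit_subject_linear(passive), "constant")
  two <- design
  two$rating <- rnorm(nrow(two))
  two$temp_c <- 46.3 + two$reg_code # temp collinear with regulation
  expect_error(fit_subject_linear(two, interaction = FALSE), "collinear")
})

test_that("subject OLS matches a normal-equations oracle", {
  design <- generate_design(1, seed = 3)
  set.seed(3)
  design$rating <- rnorm(nrow(design), 50, 10)
  fit <- fit_subject_linear(design)
  tc <- design$temp_c - 46.3
  X <- cbind(1, design$reg_code, tc, design$reg_code * tc)
  oracle <- solve(t(X) %*% X, t(X) %*% design$rating)
  expect_lt(max(abs(unname(fit$beta) - as.numeric(oracle))), 1e-10)
})

test_that("logistic fits flag one-class subjects and separation", {
  design <- generate_design(1, seed = 4)
  all_pain <- design
  all_pain$decision <- 1L
  f1 <- fit_subject_logistic(all_pain)
  expect_false(f1$converged)
  sep <- design
  sep$decision <- as.integer(sep$temp_level >= 3) # perfectly ordered
  f2 <- fit_subject_logistic(sep, interaction = FALSE)
  expect_false(f2$converged)
})

test_that("logistic slope is recovered on large simulated data", {
  set.seed(5)
  n <- 5000
  lev <- sample(1:6, n, replace = TRUE)
  tc <- (44.3 + lev - 1) - 46.3
  eta <- 0.2 + 1.7 * tc
  d <- data.frame(subject = 1, temp_c = 44.3 + lev - 1,
                  reg_code = sample(c(-1, 0, 1), n, replace = TRUE),
                  decision = rbinom(n, 1, plogis(eta)))
  f <- fit_subject_logistic(d, interaction = FALSE)
  expect_true(f$converged)
  se <- sqrt(diag(f$cov))[3]
  expect_lt(abs(f$beta["temp"] - 1.7), 2 * se)
})

test_that("group-level test behaves as a second-stage OLS", {
  mk <- function(betas) {
    lapply(seq_along(betas), function(i) {
      structure(list(subject = i, beta = c(effect = betas[i]),
                     cov = matrix(1), n_trials = 10, converged = TRUE),
                class = "subject_coefficients")
    })
  }
  # constant betas -> degenerate zero SE, flagged
  res <- group_level_test(mk(rep(0.5, 10)))
  expect_true(res$degenerate)
  expect_equal(res$beta_hat, 0.5)
  # normal betas -> estimate near truth, df = n - 1
  set.seed(6)
  b <- rnorm(30, 0.5, 0.1)
  res2 <- group_level_test(mk(b))
  expect_equal(res2$df, 29)
  expect_lt(abs(res2$beta_hat - 0.5), 2 * 0.1 / sqrt(30))
  expect_equal(res2$beta_hat, mean(b)) # two-stage = grand mean, exactly
  expect_equal(abs(res2$t), abs(res2$beta_hat / res2$se), tolerance = 1e-10)
  # orthogonal mean-zero covariate leaves the intercept unchanged
  cov1 <- rnorm(30); cov1 <- residuals(lm(cov1 ~ b)); cov1 <- cov1 - mean(cov1)
  res3 <- group_level_test(mk(b), between_covariates = cbind(cov1))
  expect_equal(res3$beta_hat, res2$beta_hat, tolerance = 1e-10)
  # constant covariate dropped with a warning
  expect_warning(group_level_test(mk(b), between_covariates = cbind(rep(1, 30))),
                 "constant")
})

test_that("robust regression tracks OLS on clean data and resists gross outliers", {
  set.seed(7)
  n_sub <- 100; n_vox <- 20
  maps <- matrix(rnorm(n_sub * n_vox, 10, 1), n_sub, n_vox)
  rob <- robust_group_regression(maps)
  ols <- colMeans(maps)
  expect_lt(max(abs(rob$beta[1, ] - ols) / abs(ols)), 0.02)
  # corrupt one subject by 100x
  bad <- maps
  bad[3, ] <- bad[3, ] * 100
  rob_bad <- robust_group_regression(bad)
  ols_shift <- abs(colMeans(bad) - ols)
  rob_shift <- abs(rob_bad$beta[1, ] - rob$beta[1, ])
  expect_true(all(rob_shift < 0.10 * ols_shift))
})

test_that("bisquare weight at zero residual is 1", {
  expect_equal(MASS::psi.bisquare(0), 1)
})

test_that("the behavioral GLM wrapper recovers population effects with the run-order covariate", {
  params <- ground_truth_params()
  design <- generate_design(20, seed = 8)
  ds <- simulate_trial_responses(design, params, seed = 8)
  res <- multilevel_behavioral_glm(ds, outcome = "rating", family = "linear")
  est <- res[res$predictor == "temp", ]
  total_temp <- params$temp_to_pain + params$sig_to_pain * params$temp_to_sig
  expect_lt(abs(est$beta_hat - total_temp), 3 * est$se)
  expect_equal(est$df, 20 - 2) # intercept + run-order covariate
})
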