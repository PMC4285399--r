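test_that("noise-free full mediation gives the chain identity a = b = c = 1, c' = 0", {
  set.seed(100)
  x <- rnorm(50)
  m <- x + rnorm(50, 0, 1e-6)   # exact m = x is collinear in y ~ x + m
  f <- fit_two_path_subject(x, m = m, y = m)
  expect_equal(f$a, 1, tolerance = 1e-4)
  expect_equal(f$b, 1, tolerance = 1e-4)
  expect_equal(f$c, 1, tolerance = 1e-4)
  expect_equal(f$c_prime, 0, tolerance = 1e-4)
  expect_equal(f$ab, 1, tolerance = 1e-4)
  # a perfectly collinear mediator raises instead of fitting silently
  expect_error(fit_two_path_subject(x, m = x, y = x), "collinear")
})

test_that("c - c' = a*b holds to 1e-8 on random data, with and without covariates", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.3 * m + 0.2 * x + rnorm(n)
    f <- fit_two_path_subject(x, m, y)
    expect_lt(abs(f$c - f$c_prime - f$ab), 1e-8)
    cov <- cbind(rnorm(n))
    fc <- fit_two_path_subject(x, m, y, covariates = cov)
    expect_lt(abs(fc$c - fc$c_prime - fc$ab), 1e-8)
  }
})

test_that("a is null when the mediator ignores x (large-sample check)", {
  set.seed(2)
  n <- 10000
  x <- rnorm(n); m <- rnorm(n); y <- 0.3 * m + rnorm(n)
  f <- fit_two_path_subject(x, m, y)
  expect_lt(abs(f$a), 2 * sqrt(f$var_a))
})

test_that("sobel_variance matches arithmetic and a Monte-Carlo oracle", {
  expect_equal(sobel_variance(0, 0, 0.02, 0.03), 0.02 * 0.03)
  expect_equal(sobel_variance(0.5, 0.3, 0.01, 0.04),
               0.25 * 0.04 + 0.09 * 0.01 + 0.01 * 0.04)
  expect_equal(sobel_variance(0.5, 0.3, 0.01, 0.04, second_order = FALSE),
               0.25 * 0.04 + 0.09 * 0.01)
  set.seed(3)
  a_draw <- rnorm(1e6, 0.5, sqrt(0.01))
  b_draw <- rnorm(1e6, 0.3, sqrt(0.04))
  mc <- var(a_draw * b_draw)
  expect_lt(abs(sobel_variance(0.5, 0.3, 0.01, 0.04) - mc) / mc, 0.03)
})

test_that("delta_variance_product3 matches substitution cases and Monte Carlo", {
  expect_equal(delta_variance_product3(0, 2, 3, 0.1, 0.1, 0.1), 36 * 0.1)
  expect_equal(delta_variance_product3(1, 1, 1, 0.05, 0.05, 0.05), 0.15)
  set.seed(4)
  b <- c(1, 0.8, 1.2); v <- c(0.02, 0.02, 0.02) # moderate CVs
  draws <- rnorm(1e6, b[1], sqrt(v[1])) * rnorm(1e6, b[2], sqrt(v[2])) *
    rnorm(1e6, b[3], sqrt(v[3]))
  mc <- var(draws)
  est <- delta_variance_product3(b[1], b[2], b[3], v[1], v[2], v[3])
  expect_lt(abs(est - mc) / mc, 0.10)
})

test_that("bootstrap p-values behave at the degenerate extremes", {
  const <- matrix(1, 10, 1, dimnames = list(NULL, "a"))
  expect_warning(res <- bootstrap_paths(const, n_boot = 2000, seed = 1),
                 "degenerate")
  expect_equal(unname(res$p), 2 / 2000)
  sym <- matrix(rep(c(1, -1), 8), 16, 1, dimnames = list(NULL, "a"))
  res2 <- bootstrap_paths(sym, n_boot = 4000, seed = 2)
  expect_gt(unname(res2$p), 0.5)
})

test_that("bootstrap inference is reproducible and invariant to row order via the pipeline", {
  dat <- make_mediation_data(15, 40, seed = 5)
  r1 <- multilevel_mediation(dat, "x", "m", "y", n_boot = 2000, seed = 7)
  set.seed(99)
  r2 <- multilevel_mediation(dat[sample(nrow(dat)), ], "x", "m", "y",
                             n_boot = 2000, seed = 7)
  expect_equal(r1$paths, r2$paths, tolerance = 1e-10)
  r3 <- multilevel_mediation(dat, "x", "m", "y", n_boot = 2000, seed = 7)
  expect_identical(r1$paths, r3$paths)
})

test_that("group indirect effect is recovered within 2 bootstrap SEs", {
  dat <- make_mediation_data(30, 95, a = 0.5, b = 0.3, seed = 8)
  res <- multilevel_mediation(dat, "x", "m", "y", n_boot = 4000, seed = 9)
  ab <- res$paths[res$paths$path == "ab", ]
  expect_lt(abs(ab$estimate - 0.15), 2 * ab$boot_se)
  expect_true(res$significant)
})

test_that("weighted and unweighted modes agree on homogeneous data", {
  dat <- make_mediation_data(25, 80, seed = 10)
  rw <- multilevel_mediation(dat, "x", "m", "y", n_boot = 2000, seed = 11)
  ru <- multilevel_mediation(dat, "x", "m", "y", n_boot = 2000, seed = 11,
                             weighting = "unweighted")
  a_w <- rw$paths$estimate[rw$paths$path == "a"]
  a_u <- ru$paths$estimate[ru$paths$path == "a"]
  expect_lt(abs(a_w - a_u), 0.05)
})

test_that("delta variance agrees with a subject-level bootstrap variance at large n", {
  set.seed(12)
  n <- 1000
  x <- rnorm(n); m1 <- 0.5 * x + rnorm(n)
  m2 <- 0.6 * m1 + rnorm(n); y <- 0.7 * m2 + rnorm(n)
  f <- fit_three_path_subject(x, m1, m2, y)
  boot <- replicate(600, {
    i <- sample.int(n, n, replace = TRUE)
    fb <- fit_three_path_subject(x[i], m1[i], m2[i], y[i])
    fb$product
  })
  expect_lt(abs(f$delta_var_product - var(boot)) / var(boot), 0.15)
})

test_that("noise-free chain passes both three-path criteria with product 1", {
  set.seed(13)
  rows <- lapply(1:8, function(s) {
    x <- rnorm(40)
    # exact chains are collinear for OLS; jitters on separated scales keep
    # b2 (estimated from the m1-residual direction) well conditioned
    m1 <- x + rnorm(40, 0, 1e-3)
    m2 <- m1 + rnorm(40, 0, 1e-6)
    data.frame(subject = s, x = x, m1 = m1, m2 = m2, y = m2)
  })
  dat <- do.call(rbind, rows)
  res <- multilevel_three_path(dat, "x", "m1", "m2", "y", n_boot = 2000,
                               seed = 14)
  est <- setNames(res$paths$estimate, res$paths$path)
  expect_equal(unname(est["product"]), 1, tolerance = 1e-3)
  expect_true(res$joint_significant)
  expect_true(res$product_significant)
  expect_true(res$significant)
})

test_that("reversing the mediator order on chain data is non-significant", {
  params <- ground_truth_params()
  design <- generate_design(25, seed = 15)
  ds <- simulate_trial_responses(design, params, seed = 15)
  rev <- multilevel_three_path(ds, "reg_code", m1_name = "m2",
                               m2_name = "m1", y_name = "rating",
                               covariates = c("temp_c", "sig"),
                               n_boot = 2000, seed = 16)
  expect_false(rev$significant)
})

test_that("the two-criterion conjunction is never looser than either criterion alone", {
  set.seed(17)
  for (rep in 1:25) {
    a <- sample(c(0, 0.4), 1)
    dat <- make_mediation_data(12, 30, a = a, b = 0.3, seed = 170 + rep)
    dat$m1 <- dat$m
    dat$m2 <- 0.5 * dat$m1 + rnorm(nrow(dat), 0, 0.5)
    res <- multilevel_three_path(dat, "x", "m1", "m2", "y", n_boot = 1000,
                                 seed = rep)
    expect_true(!res$significant || res$joint_significant)
    expect_true(!res$significant || res$product_significant)
  }
})

test_that("too few subjects raises", {
  dat <- make_mediation_data(3, 30, seed = 18)
  expect_error(multilevel_mediation(dat, "x", "m", "y", n_boot = 1000,
                                    seed = 1), "5")
})
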