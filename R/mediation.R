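#' Subject-level two-path mediation fit
#'
#' Three OLS regressions on one subject's trials: `y ~ x (+cov)` gives the
#' total effect c; `m ~ x (+cov)` gives path a; `y ~ x + m (+cov)` gives
#' path b and the direct effect c'. Without covariates the single-level OLS
#' identity `c - c' = a * b` holds exactly.
#'
#' @param x,m,y numeric trial vectors (predictor, mediator, outcome).
#' @param covariates optional numeric matrix of trial-level covariates,
#'   entered as columns in every equation.
#' @param subject optional subject id carried through.
#' @return list of class `subject_path_estimates` with elements `a`, `b`,
#'   `c`, `c_prime`, `ab`, `var_a`, `var_b`, `var_c`, `var_c_prime`,
#'   `var_ab` (Sobel), `n_trials`.
#' @export
fit_two_path_subject <- function(x, m, y, covariates = NULL, subject = NA) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_cov <- if (is.null(C)) 0L else ncol(C)
  if (n <= n_cov + 3L) stop("too few trials for the two-path model")
  X1 <- cbind(1, x, C)
  if (qr(X1)$rank < ncol(X1)) stop("x is collinear with the covariates")
  X2 <- cbind(1, x, m, C)
  if (qr(X2)$rank < ncol(X2)) {
    stop("mediator is collinear with x and the covariates")
  }
  fit_c <- ols_coef_var(X1, y, 2L)
  fit_a <- ols_coef_var(X1, m, 2L)
  fit_bc <- ols_coef_var(X2, y, c(2L, 3L))
  a <- fit_a$coef[1L]; b <- fit_bc$coef[2L]
  structure(list(subject = subject,
                 a = a, b = b, c = fit_c$coef[1L],
                 c_prime = fit_bc$coef[1L], ab = a * b,
                 var_a = fit_a$var[1L], var_b = fit_bc$var[2L],
                 var_c = fit_c$var[1L], var_c_prime = fit_bc$var[1L],
                 var_ab = sobel_variance(a, b, fit_a$var[1L], fit_bc$var[2L]),
                 n_trials = n),
            class = "subject_path_estimates")
}

ols_coef_var <- function(X, y, which_cols) {
  fit <- stats::lm.fit(X, y)
  dfres <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / max(dfres, 1L)
  XtXi <- chol2inv(chol(crossprod(X)))
  list(coef = unname(fit$coefficients[which_cols]),
       var = unname(s2 * diag(XtXi)[which_cols]))
}

#' Subject-level three-path mediation fit
#'
#' Four OLS regressions implementing the x -> m1 -> m2 -> y chain on one
#' subject's trials: `m1 ~ x (+cov)` gives b1; `m2 ~ x + m1 (+cov)` gives
#' b2 (the m1 coefficient); `y ~ x + m1 + m2 (+cov)` gives b3 (the m2
#' coefficient); and `y ~ x (+cov)` gives the total effect c. The indirect
#' effect estimate is the product b1*b2*b3 with a first-order multivariate
#' delta variance.
#'
#' @inheritParams fit_two_path_subject
#' @param m1,m2 first and second mediator trial vectors.
#' @return list of class `three_path_estimates` with `b1`, `b2`, `b3`,
#'   `product`, `var_b1`, `var_b2`, `var_b3`, `delta_var_product`, `c`,
#'   `var_c`, `n_trials`.
#' @export
fit_three_path_subject <- function(x, m1, m2, y, covariates = NULL,
                                   subject = NA) {
  n <- length(x)
  stopifnot(length(m1) == n, length(m2) == n, length(y) == n)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_cov <- if (is.null(C)) 0L else ncol(C)
  if (n <= n_cov + 4L) stop("too few trials for the three-path model")
  X1 <- cbind(1, x, C)
  if (qr(X1)$rank < ncol(X1)) stop("x is collinear with the covariates")
  X3 <- cbind(1, x, m1, m2, C)
  if (qr(X3)$rank < ncol(X3)) {
    stop("mediators are collinear with x and the covariates")
  }
  f1 <- ols_coef_var(X1, m1, 2L)
  f2 <- ols_coef_var(cbind(1, x, m1, C), m2, 3L)
  f3 <- ols_coef_var(X3, y, 4L)
  fc <- ols_coef_var(X1, y, 2L)
  b1 <- f1$coef; b2 <- f2$coef; b3 <- f3$coef
  structure(list(subject = subject, b1 = b1, b2 = b2, b3 = b3,
                 product = b1 * b2 * b3,
                 var_b1 = f1$var, var_b2 = f2$var, var_b3 = f3$var,
                 delta_var_product = delta_variance_product3(
                   b1, b2, b3, f1$var, f2$var, f3$var),
                 c = fc$coef, var_c = fc$var, n_trials = n),
            class = "three_path_estimates")
}

#' Variance of a two-path indirect effect (product of coefficients)
#'
#' Second-order form `Var(ab) = a^2 var_b + b^2 var_a + var_a var_b`,
#' exact for independent normal estimates; `second_order = FALSE` drops the
#' `var_a * var_b` term (the first-order delta form).
#'
#' @param a,b path estimates.
#' @param var_a,var_b their variances (>= 0).
#' @param second_order include the second-order term?
#' @return the product variance.
#' @export
sobel_variance <- function(a, b, var_a, var_b, second_order = TRUE) {
  stopifnot(var_a >= 0, var_b >= 0)
  out <- a^2 * var_b + b^2 * var_a
  if (second_order) out <- out + var_a * var_b
  out
}

#' First-order multivariate delta variance of a triple product
#'
#' Under independence of the three estimates,
#' `Var(b1 b2 b3) ~ (b2 b3)^2 var_b1 + (b1 b3)^2 var_b2 + (b1 b2)^2 var_b3`.
#'
#' @param b1,b2,b3 path estimates.
#' @param var_b1,var_b2,var_b3 their variances (>= 0).
#' @return the approximate product variance (always >= 0).
#' @export
delta_variance_product3 <- function(b1, b2, b3, var_b1, var_b2, var_b3) {
  stopifnot(var_b1 >= 0, var_b2 >= 0, var_b3 >= 0)
  (b2 * b3)^2 * var_b1 + (b1 * b3)^2 * var_b2 + (b1 * b2)^2 * var_b3
}

#' Bootstrap inference on subject-level path coefficients
#'
#' Resamples subject rows of the path matrix jointly, with replacement; the
#' statistic for each draw is the (weighted) mean of each column. Two-tailed
#' p-values are `2 * min(share <= 0, share >= 0)`, floored at `2 / n_boot`,
#' with 95% percentile confidence intervals.
#'
#' @param path_matrix subjects x paths numeric matrix.
#' @param weights optional subject weights: a vector, or a matrix matching
#'   `path_matrix` for per-column weights. `NULL` means equal weights.
#' @param n_boot bootstrap draws (>= 1000 recommended).
#' @param seed integer seed.
#' @param ci_level confidence level for the percentile interval.
#' @return list with `estimate` (weighted column means), `boot_se`, `p`,
#'   `ci_lower`, `ci_upper` (named by column), plus `n_boot` and `seed`.
#' @export
bootstrap_paths <- function(path_matrix, weights = NULL, n_boot = 10000L,
                            seed = 1L, ci_level = 0.95) {
  path_matrix <- as.matrix(path_matrix)
  n <- nrow(path_matrix)
  if (n < 5L) stop("need at least 5 subjects for bootstrap inference")
  if (n_boot < 2L) stop("n_boot too small")
  if (is.null(weights)) weights <- rep(1, n)
  W <- if (is.matrix(weights)) weights else
    matrix(weights, n, ncol(path_matrix))
  if (any(!is.finite(W)) || any(W < 0)) stop("weights must be finite and >= 0")
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  p_cols <- ncol(path_matrix)
  est <- numeric(p_cols); pval <- numeric(p_cols)
  bse <- numeric(p_cols)
  lo <- numeric(p_cols); hi <- numeric(p_cols)
  a2 <- (1 - ci_level) / 2
  for (j in seq_len(p_cols)) {
    wj <- W[, j]
    est[j] <- sum(wj * path_matrix[, j]) / sum(wj)
    wb <- matrix(wj[idx], n_boot, n)
    xb <- matrix(path_matrix[idx, j], n_boot, n)
    stat <- rowSums(wb * xb) / rowSums(wb)
    if (stats::sd(stat) == 0) {
      warning("degenerate bootstrap distribution for column ", j,
              "; p reported at floor")
    }
    share_le <- mean(stat <= 0)
    share_ge <- mean(stat >= 0)
    pval[j] <- min(1, max(2 * min(share_le, share_ge), 2 / n_boot))
    bse[j] <- stats::sd(stat)
    qs <- stats::quantile(stat, c(a2, 1 - a2), names = FALSE, type = 6)
    lo[j] <- qs[1L]; hi[j] <- qs[2L]
  }
  nms <- colnames(path_matrix)
  names(est) <- names(pval) <- names(bse) <- names(lo) <- names(hi) <- nms
  list(estimate = est, boot_se = bse, p = pval,
       ci_lower = lo, ci_upper = hi, n_boot = n_boot, seed = seed)
}

# DerSimonian-Laird between-subject variance for inverse-variance weighting.
dl_tau2 <- function(est, v) {
  v <- pmax(v, .Machine$double.eps)
  w <- 1 / v
  k <- length(est)
  mu <- sum(w * est) / sum(w)
  Q <- sum(w * (est - mu)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (Q - (k - 1)) / denom)
}

# Build an inverse-variance weight matrix for a subjects x paths matrix with
# matching per-subject variances; tau^2 by method of moments per column.
iv_weights <- function(paths, vars) {
  W <- matrix(1, nrow(paths), ncol(paths))
  for (j in seq_len(ncol(paths))) {
    t2 <- dl_tau2(paths[, j], vars[, j])
    W[, j] <- 1 / (pmax(vars[, j], .Machine$double.eps) + t2)
  }
  W
}

#' Multilevel two-path mediation
#'
#' Per-subject two-path fits followed by bootstrap inference over subjects
#' on the `[a b c' c a*b]` path coefficient matrix. Subjects are combined
#' either by inverse-variance weights (within-subject OLS variance plus a
#' method-of-moments between-subject component) or unweighted. Mediation is
#' declared when the bootstrap p of `a*b` falls below `alpha`.
#'
#' @param data trial data frame covering all subjects (column `subject`
#'   required); rows are sorted by subject internally so results do not
#'   depend on row order.
#' @param x_name,m_name,y_name column names for predictor, mediator, outcome.
#' @param covariates optional character vector of trial-level covariate
#'   columns.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param alpha two-tailed significance level.
#' @param weighting `"inverse_variance"` or `"unweighted"`.
#' @return list of class `mediation_result`: `paths` data frame (estimate,
#'   bootstrap SE, p, CI per path), `significant`, `n_subjects`, `n_boot`,
#'   `seed`, `alpha`, and the per-subject `path_matrix`.
#' @export
multilevel_mediation <- function(data, x_name, m_name, y_name,
                                 covariates = NULL, n_boot = 10000L,
                                 seed = 1L, alpha = 0.05,
                                 weighting = c("inverse_variance",
                                               "unweighted")) {
  weighting <- match.arg(weighting)
  data <- data[order(data$subject), , drop = FALSE]
  if (!is.null(data$excluded)) data <- data[!data$excluded, , drop = FALSE]
  subjects <- unique(data$subject)
  fits <- list()
  for (s in subjects) {
    d <- data[data$subject == s, , drop = FALSE]
    C <- if (is.null(covariates)) NULL else
      as.matrix(d[, covariates, drop = FALSE])
    f <- tryCatch(
      fit_two_path_subject(d[[x_name]], d[[m_name]], d[[y_name]], C,
                           subject = s),
      error = function(e) NULL)
    if (is.null(f)) message("subject ", s, " dropped: first-level fit failed")
    else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) < 5L) stop("fewer than 5 usable subjects")
  P <- do.call(rbind, lapply(fits, function(f) {
    c(a = f$a, b = f$b, c_prime = f$c_prime, c = f$c, ab = f$ab)
  }))
  V <- do.call(rbind, lapply(fits, function(f) {
    c(a = f$var_a, b = f$var_b, c_prime = f$var_c_prime, c = f$var_c,
      ab = f$var_ab)
  }))
  W <- if (weighting == "inverse_variance") iv_weights(P, V) else NULL
  boot <- bootstrap_paths(P, weights = W, n_boot = n_boot, seed = seed)
  paths <- data.frame(path = colnames(P), estimate = boot$estimate,
                      boot_se = boot$boot_se, p = boot$p,
                      ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(paths = paths, significant = paths$p[paths$path == "ab"] < alpha,
                 n_subjects = length(fits), n_boot = n_boot, seed = seed,
                 alpha = alpha, weighting = weighting, path_matrix = P,
                 var_matrix = V),
            class = "mediation_result")
}

#' Multilevel three-path mediation
#'
#' Per-subject four-equation fits for the x -> m1 -> m2 -> y chain followed
#' by bootstrap inference over subjects on `[b1 b2 b3 b1b2b3 c]`, with the
#' multivariate delta variance of the product feeding the second-level
#' inverse-variance weights. The chain is declared a significant mediator
#' only when BOTH criteria hold: (1) joint significance — each of b1, b2, b3
#' individually significant at `alpha` — and (2) the bootstrap
#' product-of-coefficients test on b1*b2*b3 at `alpha`.
#'
#' @inheritParams multilevel_mediation
#' @param m1_name,m2_name first and second mediator columns.
#' @return list of class `mediation_result` with `paths`,
#'   `joint_significant`, `product_significant`, `significant` (their
#'   conjunction) and bookkeeping fields.
#' @export
multilevel_three_path <- function(data, x_name, m1_name, m2_name, y_name,
                                  covariates = NULL, n_boot = 10000L,
                                  seed = 1L, alpha = 0.05,
                                  weighting = c("inverse_variance",
                                                "unweighted")) {
  weighting <- match.arg(weighting)
  data <- data[order(data$subject), , drop = FALSE]
  if (!is.null(data$excluded)) data <- data[!data$excluded, , drop = FALSE]
  subjects <- unique(data$subject)
  fits <- list()
  for (s in subjects) {
    d <- data[data$subject == s, , drop = FALSE]
    C <- if (is.null(covariates)) NULL else
      as.matrix(d[, covariates, drop = FALSE])
    f <- tryCatch(
      fit_three_path_subject(d[[x_name]], d[[m1_name]], d[[m2_name]],
                             d[[y_name]], C, subject = s),
      error = function(e) NULL)
    if (is.null(f)) message("subject ", s, " dropped: first-level fit failed")
    else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) < 5L) stop("fewer than 5 usable subjects")
  P <- do.call(rbind, lapply(fits, function(f) {
    c(b1 = f$b1, b2 = f$b2, b3 = f$b3, product = f$product, c = f$c)
  }))
  V <- do.call(rbind, lapply(fits, function(f) {
    c(b1 = f$var_b1, b2 = f$var_b2, b3 = f$var_b3,
      product = f$delta_var_product, c = f$var_c)
  }))
  W <- if (weighting == "inverse_variance") iv_weights(P, V) else NULL
  boot <- bootstrap_paths(P, weights = W, n_boot = n_boot, seed = seed)
  paths <- data.frame(path = colnames(P), estimate = boot$estimate,
                      boot_se = boot$boot_se, p = boot$p,
                      ci_lower = boot$ci_lower, ci_upper = boot$ci_upper,
                      row.names = NULL, stringsAsFactors = FALSE)
  pj <- stats::setNames(paths$p, paths$path)
  joint <- all(pj[c("b1", "b2", "b3")] < alpha)
  prod_sig <- pj["product"] < alpha
  structure(list(paths = paths, joint_significant = joint,
                 product_significant = unname(prod_sig),
                 significant = joint && prod_sig,
                 n_subjects = length(fits), n_boot = n_boot, seed = seed,
                 alpha = alpha, weighting = weighting, path_matrix = P,
                 var_matrix = V),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Multilevel mediation (", x$n_subjects, " subjects, ",
      x$n_boot, " bootstrap draws)\n", sep = "")
  print(x$paths, digits = 4)
  if (!is.null(x$joint_significant)) {
    cat("joint significance:", x$joint_significant,
        "| product test:", x$product_significant, "\n")
  }
  cat("significant mediation:", x$significant, "\n")
  invisible(x)
}
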