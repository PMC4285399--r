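#' Fit the within-subject linear pain model
#'
#' OLS regression of the trial outcome on the regulation code (+1/0/-1),
#' the centred temperature, and (optionally) their interaction, using one
#' subject's non-excluded trials.
#'
#' @param trials data frame of one subject's trials with columns `reg_code`,
#'   `temp_c`, the outcome, and optionally `excluded`.
#' @param outcome outcome column name (default `"rating"`).
#' @param interaction include the regulation x temperature interaction?
#' @param center_c temperature centring constant in degC.
#' @return list of class `subject_coefficients`: `subject`, `beta`, `cov`,
#'   `n_trials`, `converged`.
#' @export
fit_subject_linear <- function(trials, outcome = "rating",
                               interaction = TRUE, center_c = 46.3) {
  if (!is.null(trials$excluded)) trials <- trials[!trials$excluded, , drop = FALSE]
  y <- trials[[outcome]]
  tc <- trials$temp_c - center_c
  X <- cbind(intercept = 1, reg_code = trials$reg_code, temp = tc)
  if (interaction) X <- cbind(X, reg_x_temp = trials$reg_code * tc)
  check_predictors(X)
  fit_ols_subject(X, y, subject = trials$subject[1L])
}

check_predictors <- function(X) {
  for (j in 2:ncol(X)) {
    if (length(unique(X[, j])) < 2L) {
      stop("predictor '", colnames(X)[j], "' is constant within subject")
    }
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("collinear predictors within subject: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

fit_ols_subject <- function(X, y, subject = NA) {
  fit <- stats::lm.fit(X, y)
  dfres <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / max(dfres, 1L)
  XtXi <- chol2inv(chol(crossprod(X)))
  cov <- s2 * XtXi
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(subject = subject, beta = stats::setNames(fit$coefficients,
                                                           colnames(X)),
                 cov = cov, n_trials = length(y), converged = TRUE),
            class = "subject_coefficients")
}

#' Fit the within-subject logistic decision model
#'
#' Maximum-likelihood logistic regression of the pain/no-pain decision on
#' regulation and centred temperature (and optionally their interaction).
#' Subjects with a single outcome class (e.g. always "pain") are flagged
#' non-converged and excluded from the group stage, as are fits showing
#' separation (coefficients diverging during iteration).
#'
#' @inheritParams fit_subject_linear
#' @param coef_bound absolute coefficient bound used to declare separation.
#' @return a `subject_coefficients` list; `converged = FALSE` marks subjects
#'   to drop at the group stage.
#' @export
fit_subject_logistic <- function(trials, outcome = "decision",
                                 interaction = TRUE, center_c = 46.3,
                                 coef_bound = 15) {
  if (!is.null(trials$excluded)) trials <- trials[!trials$excluded, , drop = FALSE]
  y <- trials[[outcome]]
  subject <- trials$subject[1L]
  nm <- c("intercept", "reg_code", "temp", if (interaction) "reg_x_temp")
  if (length(unique(y)) < 2L) {
    return(structure(list(subject = subject,
                          beta = stats::setNames(rep(NA_real_, length(nm)), nm),
                          cov = NULL, n_trials = length(y), converged = FALSE,
                          reason = "single outcome class"),
                     class = "subject_coefficients"))
  }
  tc <- trials$temp_c - center_c
  dat <- data.frame(y = y, reg_code = trials$reg_code, temp = tc)
  form <- if (interaction) y ~ reg_code * temp else y ~ reg_code + temp
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  beta <- stats::setNames(as.numeric(stats::coef(fit)), nm)
  separated <- !fit$converged || any(abs(beta) > coef_bound)
  structure(list(subject = subject, beta = beta,
                 cov = if (separated) NULL else stats::vcov(fit),
                 n_trials = length(y), converged = !separated,
                 reason = if (separated) "separation" else NULL),
            class = "subject_coefficients")
}

#' Population test of subject-level coefficients
#'
#' Second stage of the summary-statistics multilevel model: for each
#' first-level predictor, the subject coefficients are regressed by OLS on
#' an intercept plus any between-subject covariates, and the intercept (the
#' population effect) is tested against zero with a two-tailed t test on
#' `n_subjects - q` degrees of freedom (q = fitted columns). Non-converged
#' subjects are dropped; constant covariates are dropped with a warning.
#'
#' @param subject_coeffs list of `subject_coefficients`.
#' @param between_covariates optional data frame / matrix of subject-level
#'   covariates (rows aligned to `subject_coeffs`).
#' @return data frame with one row per predictor: `predictor`, `beta_hat`,
#'   `se`, `t`, `df`, `p`, `n_subjects`, `degenerate` (zero residual SE).
#' @export
group_level_test <- function(subject_coeffs, between_covariates = NULL) {
  keep <- vapply(subject_coeffs, function(s) isTRUE(s$converged), logical(1))
  if (any(!keep)) {
    message(sum(!keep), " non-converged subject(s) dropped from group stage")
  }
  if (!is.null(between_covariates)) {
    between_covariates <- as.matrix(between_covariates)[keep, , drop = FALSE]
  }
  subject_coeffs <- subject_coeffs[keep]
  n <- length(subject_coeffs)
  if (n < 3L) stop("need at least 3 usable subjects")
  B <- do.call(rbind, lapply(subject_coeffs, function(s) s$beta))
  Z <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if (!is.null(between_covariates)) {
    ok <- apply(between_covariates, 2L, function(v) stats::sd(v) > 0)
    if (any(!ok)) warning("dropping constant between-subject covariate(s)")
    if (any(ok)) Z <- cbind(Z, between_covariates[, ok, drop = FALSE])
  }
  q <- ncol(Z)
  ZtZi <- chol2inv(chol(crossprod(Z)))
  out <- lapply(colnames(B), function(pn) {
    y <- B[, pn]
    fit <- stats::lm.fit(Z, y)
    dfres <- n - q
    s2 <- sum(fit$residuals^2) / dfres
    se <- sqrt(s2 * ZtZi[1L, 1L])
    est <- fit$coefficients[1L]
    degenerate <- se < .Machine$double.eps^0.5 * max(1, abs(est))
    tval <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
    data.frame(predictor = pn, beta_hat = est, se = se, t = tval, df = dfres,
               p = 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE),
               n_subjects = n, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Voxel-wise robust second-level regression
#'
#' Per voxel, subjects' beta maps are regressed on an intercept plus
#' optional subject-level covariates by iteratively reweighted least squares
#' with bisquare weights (tuning constant 4.685, MAD scale), via
#' \code{MASS::rlm}. Voxels whose IRLS fails to converge fall back to OLS
#' and are flagged.
#'
#' @param maps subjects x voxels numeric matrix.
#' @param covariate optional numeric vector / matrix of subject covariates.
#' @param maxit IRLS iteration cap.
#' @return list with matrices `beta`, `se`, `t`, `p` (predictors x voxels)
#'   and logical vector `ols_fallback`.
#' @export
robust_group_regression <- function(maps, covariate = NULL, maxit = 50L) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 5L) stop("need at least 5 subjects")
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariate)) X <- cbind(X, covariate = as.matrix(covariate))
  p <- ncol(X)
  n_vox <- ncol(maps)
  beta <- se <- matrix(NA_real_, p, n_vox,
                       dimnames = list(colnames(X), NULL))
  fallback <- logical(n_vox)
  for (v in seq_len(n_vox)) {
    y <- maps[, v]
    fit <- tryCatch(
      MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                scale.est = "MAD", maxit = maxit),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      fallback[v] <- TRUE
      ols <- stats::lm.fit(X, y)
      s2 <- sum(ols$residuals^2) / (n - p)
      beta[, v] <- ols$coefficients
      se[, v] <- sqrt(diag(s2 * chol2inv(chol(crossprod(X)))))
    } else {
      sm <- summary(fit)
      beta[, v] <- sm$coefficients[, "Value"]
      se[, v] <- sm$coefficients[, "Std. Error"]
    }
  }
  tmat <- beta / se
  pmat <- 2 * stats::pt(abs(tmat), n - p, lower.tail = FALSE)
  list(beta = beta, se = se, t = tmat, p = pmat, ols_fallback = fallback)
}

#' Two-stage multilevel GLM of trial behaviour
#'
#' Convenience wrapper: per-subject first-level fits (linear or logistic)
#' followed by the group-level test with the run-order covariate.
#'
#' @param data simulated or observed trial table covering all subjects.
#' @param outcome outcome column (`"rating"` for linear, `"decision"` for
#'   logistic).
#' @param family `"linear"` or `"logistic"`.
#' @param interaction include the regulation x temperature interaction?
#' @param run_order_covariate use `reg_up_first` as a between-subject
#'   covariate when present?
#' @return the [group_level_test()] data frame, with the per-subject fits
#'   attached as attribute `"subject_fits"`.
#' @export
multilevel_behavioral_glm <- function(data, outcome = "rating",
                                      family = c("linear", "logistic"),
                                      interaction = TRUE,
                                      run_order_covariate = TRUE) {
  family <- match.arg(family)
  subjects <- sort(unique(data$subject))
  fits <- lapply(subjects, function(s) {
    tr <- data[data$subject == s, , drop = FALSE]
    if (family == "linear") {
      fit_subject_linear(tr, outcome = outcome, interaction = interaction)
    } else {
      fit_subject_logistic(tr, outcome = outcome, interaction = interaction)
    }
  })
  cov <- NULL
  if (run_order_covariate && !is.null(data$reg_up_first)) {
    cov <- cbind(reg_up_first = vapply(subjects, function(s) {
      data$reg_up_first[data$subject == s][1L]
    }, numeric(1)))
  }
  res <- group_level_test(fits, between_covariates = cov)
  attr(res, "subject_fits") <- fits
  res
}
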