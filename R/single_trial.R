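#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the response peaking at 6 s, the
#' undershoot at 16 s, an undershoot-to-peak ratio of 1/6, and 32 s of
#' support, rescaled so the peak equals 1.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel support in seconds.
#' @return numeric vector of kernel samples at `seq(0, duration, by = dt)`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 7, rate = 1) -
    stats::dgamma(t, shape = 17, rate = 1) / 6
  h / max(h)
}

# Convolve boxcar events with the canonical HRF on a fine grid and sample at
# the volume acquisition times.
convolve_events <- function(onsets, durations, amplitudes, n_volumes, tr,
                            dt = 0.1) {
  total <- n_volumes * tr
  grid_n <- ceiling(total / dt) + 1L
  x <- numeric(grid_n)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(grid_n, floor((onsets[i] + durations[i]) / dt))
    if (a <= b) x[a:b] <- x[a:b] + amplitudes[i]
  }
  h <- canonical_hrf(dt)
  y <- stats::convolve(x, rev(h), type = "open")[seq_len(grid_n)] * dt
  vol_idx <- pmin(grid_n, floor((0:(n_volumes - 1L)) * tr / dt) + 1L)
  y[vol_idx]
}

#' Simulate a single-trial fMRI time series for one run
#'
#' Generates `series = sum_trials amplitude * (HRF (*) boxcar) + rating
#' response + linear drift + Gaussian noise + injected spikes`. Trial timing
#' follows the task structure: 18 s initial fixation, 12.5 s stimulation,
#' a 4.5-8.5 s jittered pre-rating period, 11 s rating, and a 5-9 s
#' inter-trial interval (jitters uniform over the printed ranges).
#'
#' @param n_trials trials in the run.
#' @param amplitudes per-trial stimulus response amplitudes.
#' @param tr repetition time in seconds.
#' @param noise_sd SD of i.i.d. Gaussian volume noise.
#' @param drift_slope linear drift in signal units over the whole run.
#' @param rating_amplitude common amplitude of the rating-period response.
#' @param outlier_spec optional `list(indices =, magnitude =)` of spike
#'   volumes to inject.
#' @param seed integer seed (jitters and noise).
#' @return list with `series` (numeric vector), `n_volumes`, `tr`, and an
#'   `events` data frame (`onset`, `duration`, `type`) suitable for
#'   [build_single_trial_design()].
#' @export
simulate_timeseries <- function(n_trials, amplitudes, tr = 2,
                                noise_sd = 0, drift_slope = 0,
                                rating_amplitude = 0,
                                outlier_spec = NULL, seed = 1L) {
  stopifnot(length(amplitudes) == n_trials)
  set.seed(as.integer(seed))
  onset <- 18
  stim_on <- numeric(n_trials); rate_on <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    stim_on[i] <- onset
    pre <- stats::runif(1, 4.5, 8.5)
    rate_on[i] <- stim_on[i] + 12.5 + pre
    iti <- stats::runif(1, 5, 9)
    onset <- rate_on[i] + 11 + iti
  }
  total <- onset + 10
  n_volumes <- as.integer(ceiling(total / tr))
  if (max(rate_on) + 11 > n_volumes * tr) stop("onsets exceed series length")
  series <- convolve_events(stim_on, rep(12.5, n_trials), amplitudes,
                            n_volumes, tr) +
    convolve_events(rate_on, rep(11, n_trials),
                    rep(rating_amplitude, n_trials), n_volumes, tr)
  series <- series + drift_slope * seq(0, 1, length.out = n_volumes)
  if (noise_sd > 0) series <- series + stats::rnorm(n_volumes, 0, noise_sd)
  if (!is.null(outlier_spec)) {
    idx <- outlier_spec$indices
    if (any(idx < 1L | idx > n_volumes)) stop("outlier indices out of range")
    series[idx] <- series[idx] + outlier_spec$magnitude
  }
  events <- rbind(
    data.frame(onset = stim_on, duration = 12.5, type = "trial"),
    data.frame(onset = rate_on, duration = 11, type = "rating")
  )
  list(series = series, n_volumes = n_volumes, tr = tr, events = events)
}

#' Build a single-trial ("beta series") design matrix
#'
#' One HRF-convolved 12.5-s boxcar regressor per trial, a single regressor
#' for all rating periods in the run, a run intercept, a linear drift term,
#' a discrete-cosine basis implementing a 180-s high-pass cutoff
#' (`floor(2 * T / cutoff)` terms), and optional spike-indicator and
#' user-supplied nuisance columns. The fixation baseline is implicit (no
#' regressor).
#'
#' @param events data frame with `onset`, `duration`, `type` ("trial" or
#'   "rating"); trial epochs must not overlap and must fit in the run.
#' @param tr repetition time (s).
#' @param n_volumes volumes in the run.
#' @param hp_cutoff high-pass cutoff in seconds.
#' @param spikes optional integer volume indices to model with indicators.
#' @param extra_nuisance optional numeric matrix of precomputed nuisance
#'   columns (e.g. movement parameters), `n_volumes` rows.
#' @return object of class `design_matrix`: `matrix`, `trial_columns`,
#'   `nuisance_columns`, `column_names`, `tr`.
#' @export
build_single_trial_design <- function(events, tr, n_volumes,
                                      hp_cutoff = 180, spikes = NULL,
                                      extra_nuisance = NULL) {
  trials <- events[events$type == "trial", , drop = FALSE]
  ratings <- events[events$type == "rating", , drop = FALSE]
  if (nrow(trials) == 0L) stop("no trial events supplied")
  if (max(events$onset + events$duration) > n_volumes * tr) {
    stop("events do not fit within n_volumes * tr")
  }
  ord <- order(trials$onset)
  trials <- trials[ord, , drop = FALSE]
  if (nrow(trials) > 1L) {
    ends <- trials$onset + trials$duration
    if (any(trials$onset[-1L] < ends[-nrow(trials)])) {
      stop("overlapping trial epochs")
    }
  }
  n_tr <- nrow(trials)
  X_trial <- vapply(seq_len(n_tr), function(i) {
    convolve_events(trials$onset[i], trials$duration[i], 1, n_volumes, tr)
  }, numeric(n_volumes))
  colnames(X_trial) <- sprintf("trial_%02d", seq_len(n_tr))
  cols <- list(X_trial)
  if (nrow(ratings) > 0L) {
    rate <- convolve_events(ratings$onset, ratings$duration,
                            rep(1, nrow(ratings)), n_volumes, tr)
    cols <- c(cols, list(rating = rate))
  }
  cols <- c(cols, list(intercept = rep(1, n_volumes),
                       drift = seq(-0.5, 0.5, length.out = n_volumes)))
  total_t <- n_volumes * tr
  k_hp <- floor(2 * total_t / hp_cutoff)
  if (k_hp > 0L) {
    t_idx <- seq_len(n_volumes) - 0.5
    dct <- vapply(seq_len(k_hp), function(k) {
      cos(pi * k * t_idx / n_volumes)
    }, numeric(n_volumes))
    colnames(dct) <- sprintf("cos_%02d", seq_len(k_hp))
    cols <- c(cols, list(dct))
  }
  if (!is.null(spikes)) {
    sp <- vapply(spikes, function(i) {
      v <- numeric(n_volumes); v[i] <- 1; v
    }, numeric(n_volumes))
    colnames(sp) <- sprintf("spike_%03d", spikes)
    cols <- c(cols, list(sp))
  }
  if (!is.null(extra_nuisance)) {
    extra_nuisance <- as.matrix(extra_nuisance)
    if (is.null(colnames(extra_nuisance))) {
      colnames(extra_nuisance) <- sprintf("nuis_%02d",
                                          seq_len(ncol(extra_nuisance)))
    }
    cols <- c(cols, list(extra_nuisance))
  }
  X <- do.call(cbind, cols)
  if (any(colSums(abs(X)) == 0)) stop("design contains an all-zero column")
  structure(list(matrix = X,
                 trial_columns = seq_len(n_tr),
                 nuisance_columns = (n_tr + 1L):ncol(X),
                 column_names = colnames(X), tr = tr),
            class = "design_matrix")
}

#' Concatenate run designs with block-diagonal nuisance structure
#'
#' Stacks several per-run design matrices: trial columns are concatenated
#' (zero outside their own run) and every nuisance column stays specific to
#' its run, giving per-run intercepts, drifts and cosine sets.
#'
#' @param designs list of `design_matrix` objects.
#' @return a single `design_matrix`.
#' @export
concatenate_designs <- function(designs) {
  stopifnot(length(designs) >= 1L)
  n_rows <- vapply(designs, function(d) nrow(d$matrix), integer(1))
  offsets <- cumsum(c(0L, n_rows[-length(n_rows)]))
  total <- sum(n_rows)
  blocks <- vector("list", length(designs))
  for (r in seq_along(designs)) {
    d <- designs[[r]]
    M <- matrix(0, total, ncol(d$matrix))
    M[offsets[r] + seq_len(n_rows[r]), ] <- d$matrix
    colnames(M) <- paste0("run", r, "_", d$column_names)
    blocks[[r]] <- M
  }
  trial_flags <- unlist(lapply(designs, function(d) {
    seq_len(ncol(d$matrix)) %in% d$trial_columns
  }))
  X <- do.call(cbind, blocks)
  structure(list(matrix = X,
                 trial_columns = which(trial_flags),
                 nuisance_columns = which(!trial_flags),
                 column_names = colnames(X), tr = designs[[1L]]$tr),
            class = "design_matrix")
}

#' Estimate single-trial response amplitudes by OLS
#'
#' Ordinary least-squares fit of the series on the full design; per-trial
#' betas are read off the trial columns, per-trial variance inflation
#' factors are computed from the design, and trials with VIF > 2.5 are
#' flagged excluded.
#'
#' @param series numeric vector (or time x targets matrix) matching the
#'   design rows.
#' @param design a `design_matrix`.
#' @param vif_cutoff exclusion threshold (default 2.5).
#' @return object of class `beta_series`: `betas` (trials x targets),
#'   `all_coefficients`, `vif`, `excluded`, `residual_variance`.
#' @export
estimate_single_trial_betas <- function(series, design, vif_cutoff = 2.5) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- as.matrix(series)
  X <- design$matrix
  if (nrow(Y) != nrow(X)) stop("series length does not match design rows")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- design$column_names[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  dfres <- nrow(X) - ncol(X)
  resvar <- colSums(res^2) / dfres
  vif <- compute_trial_vifs(design)
  betas <- coefs[design$trial_columns, , drop = FALSE]
  rownames(betas) <- design$column_names[design$trial_columns]
  structure(list(betas = betas, all_coefficients = coefs, vif = vif,
                 excluded = vif > vif_cutoff, residual_variance = resvar),
            class = "beta_series")
}

#' Per-trial variance inflation factors
#'
#' For each trial column j, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes
#' from regressing column j on all remaining columns (nuisance included;
#' total sum of squares taken about the column mean). Perfect collinearity
#' yields `Inf`.
#'
#' @param design a `design_matrix`.
#' @return numeric vector of VIFs, one per trial column (all >= 1).
#' @export
compute_trial_vifs <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  vapply(design$trial_columns, function(j) {
    xj <- X[, j]
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(others, xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    if (tss <= 0) return(Inf)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1))
}
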