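#' Ground-truth generative parameters
#'
#' Bundles the population path coefficients, between-subject standard
#' deviations, and residual noise levels of the generative model used by
#' [simulate_trial_responses()]. The model encodes the dissociation under
#' study as recoverable ground truth: a signature-like scalar response driven
#' by temperature only, and an m1 -> m2 mediator chain (an accumbens-to-vmPFC
#' style pathway) driven by regulation only. Sign conventions follow the
#' phenomenon being emulated: regulation lowers m1 (`reg_to_m1 < 0`), m1
#' drives m2 positively, and m2 predicts reduced pain (`m2_to_pain < 0`), so
#' the indirect regulation effect d1*d2*b3 is positive (regulate-up raises
#' pain).
#'
#' @param temp_to_pain direct rating slope per degC (not via the signature).
#' @param reg_to_pain_direct direct rating slope per regulation code unit (c').
#' @param temp_to_sig signature units per degC.
#' @param sig_to_pain rating units per signature unit (path b).
#' @param reg_to_m1 m1 units per regulation code unit (path d1).
#' @param m1_to_m2 m2 units per m1 unit (path d2).
#' @param m2_to_pain rating units per m2 unit (path b3).
#' @param rating_intercept population mean rating at 46.3 degC, passive.
#' @param sig_intercept population mean signature response at 46.3 degC.
#' @param between_sd named numeric vector of between-subject SDs, one per
#'   path/intercept (see defaults for the required names).
#' @param residual_sd named numeric vector of trial-level residual SDs for
#'   the rating, signature, m1 and m2 equations.
#' @param decision_threshold rating above which the trial is judged painful.
#' @param seed optional default seed carried with the parameters.
#' @return an object of class `ground_truth_params`.
#' @export
ground_truth_params <- function(temp_to_pain = 5,
                                reg_to_pain_direct = 3,
                                temp_to_sig = 2.4,
                                sig_to_pain = 1.2,
                                reg_to_m1 = -0.5,
                                m1_to_m2 = 0.8,
                                m2_to_pain = -5,
                                rating_intercept = 50,
                                sig_intercept = 10,
                                between_sd = c(rating_intercept = 8,
                                               temp_to_pain = 1,
                                               reg_to_pain_direct = 1,
                                               sig_intercept = 2,
                                               temp_to_sig = 0.4,
                                               sig_to_pain = 0.3,
                                               reg_to_m1 = 0.15,
                                               m1_to_m2 = 0.2,
                                               m2_to_pain = 1.5),
                                residual_sd = c(rating = 10, sig = 3,
                                                m1 = 0.5, m2 = 0.6),
                                decision_threshold = 50,
                                seed = NULL) {
  bs_names <- c("rating_intercept", "temp_to_pain", "reg_to_pain_direct",
                "sig_intercept", "temp_to_sig", "sig_to_pain",
                "reg_to_m1", "m1_to_m2", "m2_to_pain")
  rs_names <- c("rating", "sig", "m1", "m2")
  between_sd <- unlist(between_sd)[bs_names]
  residual_sd <- unlist(residual_sd)[rs_names]
  if (anyNA(between_sd) || anyNA(residual_sd)) {
    stop("between_sd and residual_sd must supply all named components")
  }
  if (any(between_sd < 0) || any(residual_sd < 0)) {
    stop("all SD fields must be >= 0")
  }
  structure(list(
    temp_to_pain = temp_to_pain, reg_to_pain_direct = reg_to_pain_direct,
    temp_to_sig = temp_to_sig, sig_to_pain = sig_to_pain,
    reg_to_m1 = reg_to_m1, m1_to_m2 = m1_to_m2, m2_to_pain = m2_to_pain,
    rating_intercept = rating_intercept, sig_intercept = sig_intercept,
    between_sd = as.list(between_sd), residual_sd = as.list(residual_sd),
    decision_threshold = decision_threshold,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "ground_truth_params")
}

#' Write ground-truth parameters to YAML
#' @param params a `ground_truth_params` object.
#' @param path file to write.
#' @export
write_ground_truth <- function(params, path) {
  stopifnot(inherits(params, "ground_truth_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read ground-truth parameters from YAML
#' @param path file written by [write_ground_truth()].
#' @return a `ground_truth_params` object identical to the one written.
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ground_truth_params, c(
    x[setdiff(names(x), c("between_sd", "residual_sd", "seed"))],
    list(between_sd = unlist(x$between_sd),
         residual_sd = unlist(x$residual_sd),
         seed = x$seed)
  ))
}

#' Simulate trial-level responses with known ground truth
#'
#' For every subject, per-path random effects are drawn around the population
#' paths with the configured between-subject SDs; then, per trial (with
#' temperature centred at 46.3 degC, `tc = temp_c - 46.3`):
#' \itemize{
#'   \item `sig = alpha_s + temp_to_sig_s * tc + e_sig` (no regulation path),
#'   \item `m1 = d1_s * reg_code + e_m1` (no temperature path),
#'   \item `m2 = d2_s * m1 + e_m2`,
#'   \item `rating = mu_s + temp_to_pain_s * tc + cprime_s * reg_code +
#'     sig_to_pain_s * (sig - alpha_s) + b3_s * m2 + e_y`, clipped to
#'     \[0, 100\],
#'   \item `decision = 1` iff the clipped rating exceeds the threshold.
#' }
#'
#' @param design trial table from [generate_design()].
#' @param params a [ground_truth_params()] object.
#' @param seed integer seed.
#' @return the design with columns `sig`, `m1`, `m2`, `rating`, `decision`
#'   filled in; the parameters are attached as attribute `"truth"` and the
#'   per-subject effect draws as attribute `"subject_effects"`.
#' @export
simulate_trial_responses <- function(design, params, seed) {
  stopifnot(inherits(params, "ground_truth_params"))
  bs <- unlist(params$between_sd)
  rs <- unlist(params$residual_sd)
  if (any(bs < 0) || any(rs < 0)) stop("all SD fields must be >= 0")
  set.seed(as.integer(seed))
  subjects <- unique(design$subject)
  eff <- data.frame(
    subject = subjects,
    mu = rnorm(length(subjects), params$rating_intercept, bs["rating_intercept"]),
    beta_temp = rnorm(length(subjects), params$temp_to_pain, bs["temp_to_pain"]),
    cprime = rnorm(length(subjects), params$reg_to_pain_direct, bs["reg_to_pain_direct"]),
    alpha_sig = rnorm(length(subjects), params$sig_intercept, bs["sig_intercept"]),
    beta_sig = rnorm(length(subjects), params$temp_to_sig, bs["temp_to_sig"]),
    b_sig = rnorm(length(subjects), params$sig_to_pain, bs["sig_to_pain"]),
    d1 = rnorm(length(subjects), params$reg_to_m1, bs["reg_to_m1"]),
    d2 = rnorm(length(subjects), params$m1_to_m2, bs["m1_to_m2"]),
    b3 = rnorm(length(subjects), params$m2_to_pain, bs["m2_to_pain"])
  )
  idx <- match(design$subject, eff$subject)
  n <- nrow(design)
  tc <- design$temp_c - 46.3
  sig <- eff$alpha_sig[idx] + eff$beta_sig[idx] * tc + rnorm(n, 0, rs["sig"])
  m1 <- eff$d1[idx] * design$reg_code + rnorm(n, 0, rs["m1"])
  m2 <- eff$d2[idx] * m1 + rnorm(n, 0, rs["m2"])
  rating <- eff$mu[idx] + eff$beta_temp[idx] * tc +
    eff$cprime[idx] * design$reg_code +
    eff$b_sig[idx] * (sig - eff$alpha_sig[idx]) +
    eff$b3[idx] * m2 + rnorm(n, 0, rs["rating"])
  rating <- pmin(pmax(rating, 0), 100)
  out <- design
  out$sig <- sig
  out$m1 <- m1
  out$m2 <- m2
  out$rating <- rating
  out$decision <- as.integer(rating > params$decision_threshold)
  attr(out, "truth") <- params
  attr(out, "subject_effects") <- eff
  out
}

#' Simulate a desk-scale voxel brain with planted mediator clusters
#'
#' Builds per-trial beta volumes on a small 3-D grid in which three disjoint
#' cubic clusters carry, respectively, the trial's signature response, its m1
#' value and its m2 value (each plus independent voxel noise), while
#' background voxels carry pure noise. A signature weight map supported on
#' the signature cluster is returned alongside, so pattern-expression scoring
#' of a trial volume is a fixed linear transform of that trial's signature
#' value.
#'
#' @param dataset simulated trial data from [simulate_trial_responses()].
#' @param grid_shape integer length-3 voxel counts (kept small, <= 30^3).
#' @param voxel_size isotropic voxel edge in mm.
#' @param voxel_noise_sd SD of independent voxel noise added everywhere.
#' @param cluster_half_width clusters are cubes of edge `2*half_width + 1`.
#' @param seed integer seed.
#' @return an object of class `synthetic_brain`: `grid_shape`, `voxel_size`,
#'   `affine` (voxel-to-world), `mask` (logical array), `labels` (integer
#'   array: 0 background, 1 signature, 2 m1, 3 m2), `betas` (trials x voxels
#'   matrix over in-mask voxels, column order = ascending linear voxel
#'   index), `signature` (a [signature_pattern()]), and the originating
#'   `dataset` rows.
#' @export
simulate_voxel_brain <- function(dataset, grid_shape = c(14L, 14L, 10L),
                                 voxel_size = 2, voxel_noise_sd = 0.4,
                                 cluster_half_width = 1L, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 6L),
            all(grid_shape <= 30L))
  set.seed(as.integer(seed))
  hw <- cluster_half_width
  labels <- array(0L, dim = grid_shape)
  centers <- list(
    sig = c(2L + hw, 2L + hw, 2L + hw),
    m1  = c(grid_shape[1L] - 1L - hw, 2L + hw, grid_shape[3L] - 1L - hw),
    m2  = c(2L + hw, grid_shape[2L] - 1L - hw, grid_shape[3L] - 1L - hw)
  )
  for (k in seq_along(centers)) {
    ctr <- centers[[k]]
    box <- lapply(1:3, function(d) (ctr[d] - hw):(ctr[d] + hw))
    if (any(labels[box[[1L]], box[[2L]], box[[3L]]] != 0L)) {
      stop("planted clusters overlap; enlarge the grid")
    }
    labels[box[[1L]], box[[2L]], box[[3L]]] <- k
  }
  mask <- array(TRUE, dim = grid_shape)
  n_vox <- prod(grid_shape)
  n_trials <- nrow(dataset)
  lab_vec <- as.integer(labels)
  signal <- cbind(0, dataset$sig, dataset$m1, dataset$m2) # column lab+1
  betas <- signal[, lab_vec + 1L, drop = FALSE] +
    matrix(rnorm(n_trials * n_vox, 0, voxel_noise_sd), n_trials, n_vox)
  w <- array(0, dim = grid_shape)
  sig_idx <- which(lab_vec == 1L)
  w[sig_idx] <- runif(length(sig_idx), 0.5, 1.5)
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  signature <- signature_pattern(weights = w, mask = labels == 1L,
                                 affine = affine)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 affine = affine, mask = mask, labels = labels,
                 betas = betas, signature = signature, dataset = dataset),
            class = "synthetic_brain")
}
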