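#' Pipeline configuration
#'
#' A fully serializable description of one synthetic study run: the
#' generative truth, sample size, the small voxel grid, and the inference
#' settings. A run is reproducible from the config alone.
#'
#' @param truth a [ground_truth_params()] object.
#' @param n_subjects subjects to simulate.
#' @param brain list with `grid_shape`, `voxel_size`, `voxel_noise_sd`.
#' @param inference list with `n_boot`, `alpha`, `n_iter`, `primary_p`.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param run_search run the voxel-wise three-path search stage?
#' @param from_timeseries estimate the signature response through the full
#'   single-trial GLM time-series path instead of using the directly
#'   simulated scalar (slower; exercises the beta-series machinery).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(truth = ground_truth_params(),
                            n_subjects = 30L,
                            brain = list(grid_shape = c(14L, 14L, 10L),
                                         voxel_size = 2,
                                         voxel_noise_sd = 0.4),
                            inference = list(n_boot = 5000L, alpha = 0.05,
                                             n_iter = 2000L,
                                             primary_p = 0.005),
                            seed = 1L, run_search = TRUE,
                            from_timeseries = FALSE) {
  structure(list(truth = truth, n_subjects = as.integer(n_subjects),
                 brain = brain, inference = inference,
                 seed = as.integer(seed), run_search = isTRUE(run_search),
                 from_timeseries = isTRUE(from_timeseries)),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$truth <- unclass(x$truth)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  tr <- x$truth
  truth <- do.call(ground_truth_params, c(
    tr[setdiff(names(tr), c("between_sd", "residual_sd", "seed"))],
    list(between_sd = unlist(tr$between_sd),
         residual_sd = unlist(tr$residual_sd), seed = tr$seed)))
  pipeline_config(truth = truth, n_subjects = x$n_subjects,
                  brain = x$brain, inference = x$inference, seed = x$seed,
                  run_search = x$run_search,
                  from_timeseries = x$from_timeseries)
}

# Deterministic stage seeds derived from the master seed (kept < 2^31).
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9973) %% 2147483647)
}

#' Run the full synthetic study
#'
#' Executes the complete chain on simulated data with known truth:
#' design generation and trial simulation; (optionally) time-series
#' simulation and single-trial GLM estimation of the signature response;
#' voxel-brain simulation and pattern-expression scoring; the two-stage
#' behavioural GLMs (linear and logistic); the two-path mediation models
#' (temperature -> signature -> pain with regulation as covariate, and
#' regulation -> signature -> pain with temperature as covariate); the
#' three-path model regulation -> m1 -> m2 -> pain with temperature and the
#' signature response as covariates, plus its reversed-order control; and,
#' optionally, the voxel-wise three-path search with Monte-Carlo
#' cluster-extent correction on the planted brain.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` (see [make_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inf <- config$inference
  design <- generate_design(config$n_subjects, seed = stage_seed(config$seed, 1L))
  dataset <- simulate_trial_responses(design, config$truth,
                                      seed = stage_seed(config$seed, 2L))
  if (config$from_timeseries) {
    dataset <- rescore_sig_from_timeseries(dataset,
                                           seed = stage_seed(config$seed, 3L))
  }
  brain <- simulate_voxel_brain(dataset,
                                grid_shape = config$brain$grid_shape,
                                voxel_size = config$brain$voxel_size,
                                voxel_noise_sd = config$brain$voxel_noise_sd,
                                seed = stage_seed(config$seed, 4L))
  # score every trial volume against the signature (exercises the scoring
  # path; equals sig up to voxel noise and the weight-sum scale)
  wvec <- brain$signature$weights[brain$signature$mask]
  sig_idx <- which(as.integer(brain$labels) == 1L)
  dataset$sig_scored <- as.numeric(brain$betas[, sig_idx, drop = FALSE] %*% wvec)
  behav_linear <- multilevel_behavioral_glm(dataset, outcome = "rating",
                                            family = "linear")
  behav_logistic <- multilevel_behavioral_glm(dataset, outcome = "decision",
                                              family = "logistic")
  med_temp <- multilevel_mediation(
    dataset, x_name = "temp_c", m_name = "sig", y_name = "rating",
    covariates = "reg_code", n_boot = inf$n_boot,
    seed = stage_seed(config$seed, 5L), alpha = inf$alpha)
  med_reg <- multilevel_mediation(
    dataset, x_name = "reg_code", m_name = "sig", y_name = "rating",
    covariates = "temp_c", n_boot = inf$n_boot,
    seed = stage_seed(config$seed, 6L), alpha = inf$alpha)
  med3 <- multilevel_three_path(
    dataset, x_name = "reg_code", m1_name = "m1", m2_name = "m2",
    y_name = "rating", covariates = c("temp_c", "sig"),
    n_boot = inf$n_boot, seed = stage_seed(config$seed, 7L),
    alpha = inf$alpha)
  med3_rev <- multilevel_three_path(
    dataset, x_name = "reg_code", m1_name = "m2", m2_name = "m1",
    y_name = "rating", covariates = c("temp_c", "sig"),
    n_boot = inf$n_boot, seed = stage_seed(config$seed, 8L),
    alpha = inf$alpha)
  search <- NULL
  if (config$run_search) {
    sr <- mediation_brain_search(
      dataset, brain$betas, x_name = "reg_code", y_name = "rating",
      model = "three_path_m2", fixed_mediator = "m1",
      covariates = c("temp_c", "sig"), n_boot = inf$n_boot,
      seed = stage_seed(config$seed, 9L), alpha = inf$alpha)
    thr <- monte_carlo_cluster_threshold(
      brain$mask, fwhm_mm = 0, voxel_size_mm = config$brain$voxel_size,
      primary_p = inf$primary_p, alpha_fwer = inf$alpha,
      n_iter = inf$n_iter, seed = stage_seed(config$seed, 10L))
    p_map <- map_to_volume(sr$p_product, brain$mask, fill = 1)
    sig_vox <- map_to_volume(as.numeric(sr$significant), brain$mask, fill = 0)
    supra <- p_map < inf$primary_p & sig_vox > 0
    labels <- label_clusters(supra)
    n_cl <- attr(labels, "n_clusters")
    keep <- array(FALSE, dim = dim(labels))
    if (n_cl > 0L) {
      sizes <- tabulate(labels[labels > 0L], nbins = n_cl)
      for (cl in seq_len(n_cl)) {
        if (sizes[cl] >= thr$k_min) keep[labels == cl] <- TRUE
      }
    }
    true_m2 <- brain$labels == 3L
    inter <- sum(keep & true_m2)
    dice <- if (sum(keep) + sum(true_m2) > 0) {
      2 * inter / (sum(keep) + sum(true_m2))
    } else 0
    search <- list(result = sr, threshold = thr, detected = keep,
                   dice_m2 = dice)
  }
  make_report(list(config = config, dataset = dataset, brain = brain,
                   behav_linear = behav_linear,
                   behav_logistic = behav_logistic,
                   med_temp = med_temp, med_reg = med_reg,
                   med3 = med3, med3_rev = med3_rev, search = search))
}

# Re-estimate the per-trial signature response through simulated run time
# series and the single-trial GLM, replacing the directly simulated scalar.
rescore_sig_from_timeseries <- function(dataset, seed) {
  out <- dataset
  key <- interaction(dataset$subject, dataset$run, drop = TRUE)
  k <- 0L
  for (grp in levels(key)) {
    rows <- which(key == grp)
    k <- k + 1L
    amp <- dataset$sig[rows]
    ts <- simulate_timeseries(length(rows), amplitudes = amp, tr = 2,
                              noise_sd = 0.5, drift_slope = 2,
                              seed = stage_seed(seed, k))
    dm <- build_single_trial_design(ts$events, tr = ts$tr,
                                    n_volumes = ts$n_volumes)
    bs <- estimate_single_trial_betas(ts$series, dm)
    out$sig[rows] <- as.numeric(bs$betas)
    out$vif[rows] <- bs$vif
    out$excluded[rows] <- out$excluded[rows] | bs$excluded
  }
  out
}

#' Assemble a run report
#'
#' Collects the pipeline artifacts into tables plus a qualitative
#' dissociation summary, and audits internal consistency (every stored
#' significance flag is recomputed from the stored p-values). Missing stages
#' are listed and the report is still rendered.
#'
#' @param artifacts named list of pipeline stage outputs.
#' @return list of class `run_report` with `tables`, `dissociation`,
#'   `missing_stages`, `flags_consistent`, `seed`, and the raw `artifacts`.
#' @export
make_report <- function(artifacts) {
  expected <- c("config", "dataset", "behav_linear", "behav_logistic",
                "med_temp", "med_reg", "med3", "med3_rev")
  missing <- setdiff(expected, names(artifacts)[!vapply(artifacts, is.null,
                                                        logical(1))])
  med_table <- function(m, label) {
    if (is.null(m)) return(NULL)
    cbind(model = label, m$paths)
  }
  tables <- list(
    behavioral_linear = artifacts$behav_linear,
    behavioral_logistic = artifacts$behav_logistic,
    mediation = do.call(rbind, Filter(Negate(is.null), list(
      med_table(artifacts$med_temp, "temp_sig_pain"),
      med_table(artifacts$med_reg, "reg_sig_pain"),
      med_table(artifacts$med3, "reg_m1_m2_pain"),
      med_table(artifacts$med3_rev, "reg_m2_m1_pain_reversed"))))
  )
  dissociation <- list(
    temp_sig_mediation_significant =
      if (is.null(artifacts$med_temp)) NA else artifacts$med_temp$significant,
    reg_sig_mediation_significant =
      if (is.null(artifacts$med_reg)) NA else artifacts$med_reg$significant,
    reg_chain_mediation_significant =
      if (is.null(artifacts$med3)) NA else artifacts$med3$significant,
    reversed_chain_significant =
      if (is.null(artifacts$med3_rev)) NA else artifacts$med3_rev$significant
  )
  flags_ok <- TRUE
  for (nm in c("med_temp", "med_reg", "med3", "med3_rev")) {
    m <- artifacts[[nm]]
    if (is.null(m)) next
    pj <- stats::setNames(m$paths$p, m$paths$path)
    recomputed <- if ("ab" %in% names(pj)) {
      unname(pj["ab"] < m$alpha)
    } else {
      all(pj[c("b1", "b2", "b3")] < m$alpha) && pj["product"] < m$alpha
    }
    flags_ok <- flags_ok && identical(recomputed, m$significant)
  }
  structure(list(tables = tables, dissociation = dissociation,
                 missing_stages = missing, flags_consistent = flags_ok,
                 seed = if (!is.null(artifacts$config)) artifacts$config$seed
                        else NA_integer_,
                 search_dice = if (!is.null(artifacts$search))
                   artifacts$search$dice_m2 else NA_real_,
                 artifacts = artifacts),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Synthetic study run (seed ", x$seed, ")\n", sep = "")
  if (length(x$missing_stages) > 0L) {
    cat("skipped stages:", paste(x$missing_stages, collapse = ", "), "\n")
  }
  cat("\nBehavioral (linear) group effects:\n")
  print(x$tables$behavioral_linear, digits = 3)
  cat("\nMediation paths:\n")
  print(x$tables$mediation, digits = 3)
  cat("\nDissociation summary:\n")
  for (nm in names(x$dissociation)) {
    cat(" ", nm, ":", x$dissociation[[nm]], "\n")
  }
  if (!is.na(x$search_dice)) {
    cat("planted-m2 search Dice:", round(x$search_dice, 3), "\n")
  }
  cat("significance flags consistent with stored p-values:",
      x$flags_consistent, "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report a `run_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(seed = report$seed,
              behavioral_linear = report$tables$behavioral_linear,
              behavioral_logistic = report$tables$behavioral_logistic,
              mediation = report$tables$mediation,
              dissociation = report$dissociation,
              search_dice = report$search_dice,
              missing_stages = report$missing_stages,
              flags_consistent = report$flags_consistent,
              r_version = as.character(getRversion()))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
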