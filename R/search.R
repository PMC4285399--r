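#' Voxel-wise multilevel mediation search
#'
#' Runs the multilevel mediation model at every in-mask voxel, using that
#' voxel's per-trial beta series as the free mediator. Three modes:
#' `"two_path"` (the voxel is the sole mediator m), `"three_path_m2"` (a
#' fixed first mediator m1 is supplied and the voxel plays m2), and
#' `"three_path_m1"` (a fixed second mediator m2 is supplied and the voxel
#' plays m1). Per-subject fits are computed in closed form
#' (Frisch-Waugh residualization against the fixed regressors), so the whole
#' search is a handful of matrix products per subject; group inference is an
#' unweighted subject bootstrap of each path and of the path product, shared
#' across voxels through a common resampling plan.
#'
#' Voxels whose mediator series has (numerically) zero residual variance in
#' any subject are skipped and recorded in the skip mask.
#'
#' @param data trial data frame with `subject` and the named columns; rows
#'   must align with the rows of `betas`.
#' @param betas trials x voxels matrix of per-trial voxel amplitudes.
#' @param x_name,y_name predictor and outcome columns in `data`.
#' @param model search mode (see above).
#' @param fixed_mediator column name in `data` of the fixed mediator
#'   (required for the three-path modes).
#' @param covariates optional character vector of trial-level covariate
#'   columns.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param alpha two-tailed level used for the per-voxel significance flags.
#' @return list with per-voxel vectors: path estimates (`a`/`b` or
#'   `b1`/`b2`/`b3`), `product`, bootstrap p-values per path and for the
#'   product, `significant` (joint significance of all free paths AND the
#'   product test in the three-path modes; both paths and the product in the
#'   two-path mode), and `skipped`.
#' @export
mediation_brain_search <- function(data, betas, x_name, y_name,
                                   model = c("two_path", "three_path_m2",
                                             "three_path_m1"),
                                   fixed_mediator = NULL, covariates = NULL,
                                   n_boot = 2000L, seed = 1L, alpha = 0.05) {
  model <- match.arg(model)
  betas <- as.matrix(betas)
  stopifnot(nrow(betas) == nrow(data))
  if (model != "two_path" && is.null(fixed_mediator)) {
    stop("fixed_mediator is required for three-path searches")
  }
  ord <- order(data$subject)
  data <- data[ord, , drop = FALSE]
  betas <- betas[ord, , drop = FALSE]
  subjects <- unique(data$subject)
  n_sub <- length(subjects)
  n_vox <- ncol(betas)
  per_subject <- lapply(subjects, function(s) {
    rows <- which(data$subject == s)
    d <- data[rows, , drop = FALSE]
    B <- betas[rows, , drop = FALSE]
    C <- if (is.null(covariates)) NULL else
      as.matrix(d[, covariates, drop = FALSE])
    x <- d[[x_name]]; y <- d[[y_name]]
    mfix <- if (is.null(fixed_mediator)) NULL else d[[fixed_mediator]]
    switch(model,
      two_path = subject_search_two_path(x, y, B, C),
      three_path_m2 = subject_search_m2(x, mfix, y, B, C),
      three_path_m1 = subject_search_m1(x, mfix, y, B, C))
  })
  skipped <- Reduce(`|`, lapply(per_subject, function(p) p$skip))
  path_names <- names(per_subject[[1L]]$paths)
  # subjects x voxels matrix per path
  path_arrays <- lapply(path_names, function(pn) {
    do.call(rbind, lapply(per_subject, function(p) p$paths[[pn]]))
  })
  names(path_arrays) <- path_names
  prod_mat <- Reduce(`*`, path_arrays)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n_sub, n_sub * n_boot, replace = TRUE),
                n_boot, n_sub)
  counts <- t(apply(idx, 1L, tabulate, nbins = n_sub))
  boot_p <- function(M) {
    stat <- (counts %*% M) / n_sub
    est <- colMeans(M)
    le <- colMeans(stat <= 0)
    ge <- colMeans(stat >= 0)
    p <- pmin(1, pmax(2 * pmin(le, ge), 2 / n_boot))
    list(estimate = est, p = p)
  }
  path_res <- lapply(path_arrays, boot_p)
  prod_res <- boot_p(prod_mat)
  out <- list(skipped = skipped, model = model, n_subjects = n_sub,
              n_boot = n_boot, seed = seed, alpha = alpha,
              product = prod_res$estimate, p_product = prod_res$p)
  for (pn in path_names) {
    out[[pn]] <- path_res[[pn]]$estimate
    out[[paste0("p_", pn)]] <- path_res[[pn]]$p
  }
  joint <- Reduce(`&`, lapply(path_names, function(pn) {
    out[[paste0("p_", pn)]] < alpha
  }))
  out$significant <- joint & (out$p_product < alpha) & !skipped
  out$n_voxels <- n_vox
  out
}

# Two-path: free mediator per voxel. a_v from m_v ~ [1 x C]; b_v from
# y ~ [1 x C m_v] via residualization.
subject_search_two_path <- function(x, y, B, C) {
  X <- cbind(1, x, C)
  qx <- qr(X)
  A <- qr.coef(qx, B)            # coefficients of m_v ~ X
  a <- A[2L, ]
  RB <- B - X %*% A              # mediator residuals on [1 x C]
  ry <- stats::lm.fit(X, y)$residuals
  ss <- colSums(RB^2)
  skip <- ss < 1e-12 * max(1, mean(ss))
  ss[skip] <- NA_real_
  b <- colSums(RB * ry) / ss
  list(paths = list(a = a, b = b), skip = skip)
}

# Three-path with fixed m1, free m2 per voxel.
subject_search_m2 <- function(x, m1, y, B, C) {
  X1 <- cbind(1, x, C)
  b1 <- stats::lm.fit(X1, m1)$coefficients[2L]
  X2 <- cbind(1, x, m1, C)
  qx2 <- qr(X2)
  A <- qr.coef(qx2, B)           # m2_v ~ [1 x m1 C]
  b2 <- A[3L, ]
  RB <- B - X2 %*% A             # m2 residuals on [1 x m1 C]
  ry <- qr.resid(qx2, y)
  ss <- colSums(RB^2)
  skip <- ss < 1e-12 * max(1, mean(ss))
  ss[skip] <- NA_real_
  b3 <- colSums(RB * ry) / ss
  list(paths = list(b1 = rep(b1, ncol(B)), b2 = b2, b3 = b3), skip = skip)
}

# Three-path with free m1 per voxel, fixed m2.
subject_search_m1 <- function(x, m2, y, B, C) {
  X1 <- cbind(1, x, C)
  qx1 <- qr(X1)
  A <- qr.coef(qx1, B)           # m1_v ~ [1 x C]
  b1 <- A[2L, ]
  U <- B - X1 %*% A              # m1 residuals on [1 x C]
  rw <- qr.resid(qx1, m2)        # m2 residuals
  ry <- qr.resid(qx1, y)
  uu <- colSums(U^2)
  skip <- uu < 1e-12 * max(1, mean(uu))
  uu[skip] <- NA_real_
  uw <- colSums(U * rw)
  uy <- colSums(U * ry)
  ww <- sum(rw^2)
  wy <- sum(rw * ry)
  b2 <- uw / uu                  # m2 ~ m1_v controlling [1 x C]
  det <- uu * ww - uw^2
  bad <- det < 1e-12 * max(1, mean(uu) * ww)
  det[bad] <- NA_real_
  skip <- skip | bad
  b3 <- (uu * wy - uw * uy) / det  # m2 coefficient in y ~ m1_v + m2 | X1
  list(paths = list(b1 = b1, b2 = b2, b3 = b3), skip = skip)
}

#' Put a per-voxel vector back on its 3-D grid
#'
#' @param values numeric vector over in-mask voxels (ascending linear index).
#' @param mask logical array.
#' @param fill value outside the mask.
#' @return numeric array shaped like `mask`.
#' @export
map_to_volume <- function(values, mask, fill = NA_real_) {
  out <- array(fill, dim = dim(mask))
  out[mask] <- values
  out
}
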