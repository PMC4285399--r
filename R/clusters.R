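#' Estimate spatial smoothness of residual volumes
#'
#' Per-axis FWHM from the variance of spatial first differences relative to
#' the voxel variance, using the Gaussian-autocorrelation relation
#' `FWHM = delta * sqrt(4 ln 2 * var / vardiff)` (the small-lag expansion),
#' averaged across volumes. White noise gives the estimator's floor
#' `delta * sqrt(2 ln 2)` per axis; the estimate is mildly biased upward at
#' coarse sampling relative to smoothness.
#'
#' @param residual_volumes 4-D array (x, y, z, volume) of residual images,
#'   at least 10 volumes.
#' @param mask logical 3-D array; differences are taken only between
#'   neighbouring in-mask voxels.
#' @param voxel_size_mm numeric length-3 voxel edges in mm.
#' @return numeric length-3 vector of FWHM estimates in mm.
#' @export
estimate_smoothness <- function(residual_volumes, mask, voxel_size_mm) {
  d <- dim(residual_volumes)
  if (length(d) != 4L) stop("residual_volumes must be 4-D")
  if (d[4L] < 10L) stop("need at least 10 residual volumes")
  mask <- array(as.logical(mask), dim = d[1:3])
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  var_tot <- 0; vardiff <- numeric(3L); n_pairs <- numeric(3L)
  for (t in seq_len(d[4L])) {
    vol <- residual_volumes[, , , t]
    v <- vol[mask]
    var_tot <- var_tot + stats::var(v)
    for (ax in 1:3) {
      dv <- axis_diffs(vol, mask, ax)
      vardiff[ax] <- vardiff[ax] + sum(dv^2)
      n_pairs[ax] <- n_pairs[ax] + length(dv)
    }
  }
  var_tot <- var_tot / d[4L]
  if (var_tot <= 0) stop("zero-variance residuals")
  vardiff <- vardiff / pmax(n_pairs, 1)
  r <- vardiff / var_tot
  voxel_size_mm * sqrt(4 * log(2) / pmax(r, .Machine$double.eps))
}

axis_diffs <- function(vol, mask, axis) {
  d <- dim(vol)
  idx1 <- switch(axis,
    `1` = list(1:(d[1] - 1), 1:d[2], 1:d[3]),
    `2` = list(1:d[1], 1:(d[2] - 1), 1:d[3]),
    `3` = list(1:d[1], 1:d[2], 1:(d[3] - 1)))
  idx2 <- switch(axis,
    `1` = list(2:d[1], 1:d[2], 1:d[3]),
    `2` = list(1:d[1], 2:d[2], 1:d[3]),
    `3` = list(1:d[1], 1:d[2], 2:d[3]))
  a <- do.call(`[`, c(list(vol), idx1))
  b <- do.call(`[`, c(list(vol), idx2))
  ma <- do.call(`[`, c(list(mask), idx1))
  mb <- do.call(`[`, c(list(mask), idx2))
  (b - a)[ma & mb]
}

# Separable Gaussian smoothing of a 3-D array (full kernels, matrix form).
smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = s)
    m <- apply(arr, setdiff(1:3, ax), identity) # n x (prod others)
    dim(m) <- c(n, prod(d[-ax]))
    sm <- k %*% m
    dim(sm) <- c(n, d[-ax])
    arr <- aperm(sm, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# Precompute the pointwise variance of a mask-restricted smoothed unit-noise
# field: separable convolution of the mask with squared kernels.
smooth_mask_var <- function(mask, sigma_vox) {
  d <- dim(mask)
  arr <- array(as.numeric(mask), dim = d)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    k <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = s)^2
    m <- apply(arr, setdiff(1:3, ax), identity)
    dim(m) <- c(n, prod(d[-ax]))
    sm <- k %*% m
    dim(sm) <- c(n, d[-ax])
    arr <- aperm(sm, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

# One standardized null field on the mask: white noise inside the mask,
# Gaussian-smoothed, divided by its pointwise SD (edge renormalization).
null_field <- function(mask, sigma_vox, sd_map) {
  noise <- array(0, dim = dim(mask))
  noise[mask] <- stats::rnorm(sum(mask))
  if (all(sigma_vox <= 0)) return(noise)
  sm <- smooth_3d(noise, sigma_vox)
  sm / sd_map
}

#' Monte-Carlo cluster-extent threshold for FWER control
#'
#' Simulates Gaussian null fields with the given smoothness on the mask,
#' applies the two-tailed voxel-level primary threshold, records the maximum
#' face-connected cluster size per iteration, and returns the smallest
#' cluster extent `k_min` whose exceedance probability under the null is at
#' most `alpha_fwer`.
#'
#' @param mask logical 3-D array.
#' @param fwhm_mm smoothness of the simulated fields (scalar or length 3).
#' @param voxel_size_mm voxel edges in mm (scalar or length 3).
#' @param primary_p voxel-level two-tailed threshold.
#' @param alpha_fwer family-wise level.
#' @param n_iter Monte-Carlo iterations (>= 1000; fewer allowed with a
#'   warning).
#' @param seed integer seed.
#' @return list of class `cluster_threshold`: `k_min`, `primary_p`,
#'   `alpha_fwer`, `n_iter`, `fwhm_mm`, `seed`, and the simulated
#'   `max_cluster_sizes`.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm, voxel_size_mm = 2,
                                          primary_p = 0.001,
                                          alpha_fwer = 0.05,
                                          n_iter = 10000L, seed = 1L) {
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!any(mask)) stop("empty mask")
  if (n_iter < 1000L) warning("n_iter < 1000: reduced-replication mode")
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  sigma_vox <- fwhm_mm / voxel_size_mm / (2 * sqrt(2 * log(2)))
  sd_map <- if (all(sigma_vox <= 0)) NULL else {
    v <- smooth_mask_var(mask, sigma_vox)
    v[v <= 0] <- Inf
    sqrt(v)
  }
  zcrit <- stats::qnorm(1 - primary_p / 2)
  set.seed(as.integer(seed))
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    z <- null_field(mask, sigma_vox, sd_map)
    supra <- abs(z) > zcrit & mask
    max_sizes[i] <- max_cluster_size(supra)
  }
  exceed <- vapply(seq_len(max(max_sizes, 1L) + 1L), function(k) {
    mean(max_sizes >= k)
  }, numeric(1))
  k_min <- which(exceed <= alpha_fwer)[1L]
  if (is.na(k_min)) k_min <- max(max_sizes) + 1L
  structure(list(k_min = as.integer(max(1L, k_min)), primary_p = primary_p,
                 alpha_fwer = alpha_fwer, n_iter = n_iter, fwhm_mm = fwhm_mm,
                 voxel_size_mm = voxel_size_mm, seed = seed,
                 max_cluster_sizes = max_sizes),
            class = "cluster_threshold")
}

#' Label face-connected clusters in a logical volume
#'
#' Connected components of `TRUE` voxels under face (6-neighbour)
#' adjacency, by breadth-first flood fill.
#'
#' @param supra logical 3-D array.
#' @return integer array of cluster labels (0 = background), with the number
#'   of clusters as attribute `"n_clusters"`.
#' @export
label_clusters <- function(supra) {
  d <- dim(supra)
  labels <- array(0L, dim = d)
  vox <- which(supra)
  if (length(vox) == 0L) {
    attr(labels, "n_clusters") <- 0L
    return(labels)
  }
  coord <- arrayInd(vox, d)
  in_set <- array(FALSE, dim = d)
  in_set[vox] <- TRUE
  lab <- 0L
  for (v in vox) {
    if (labels[v] != 0L) next
    lab <- lab + 1L
    queue <- v
    labels[v] <- lab
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (ax in 1:3) {
        for (step in c(-1L, 1L)) {
          nb <- ci
          nb[ax] <- nb[ax] + step
          if (nb[ax] < 1L || nb[ax] > d[ax]) next
          lin <- nb[1L] + (nb[2L] - 1L) * d[1L] + (nb[3L] - 1L) * d[1L] * d[2L]
          if (in_set[lin] && labels[lin] == 0L) {
            labels[lin] <- lab
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  attr(labels, "n_clusters") <- lab
  labels
}

max_cluster_size <- function(supra) {
  labels <- label_clusters(supra)
  n <- attr(labels, "n_clusters")
  if (n == 0L) return(0L)
  max(tabulate(labels[labels > 0L], nbins = n))
}

#' Threshold a statistic map and tabulate surviving clusters
#'
#' Applies the two-tailed voxel-level primary threshold (|t| above the
#' critical value on `df` degrees of freedom, or |z| when `df = Inf`),
#' groups suprathreshold voxels by face connectivity, discards clusters
#' smaller than `k_min`, and tabulates the rest.
#'
#' @param stat_map numeric 3-D array of t (or z) values.
#' @param df degrees of freedom (`Inf` for a z map).
#' @param primary_p voxel-level two-tailed threshold.
#' @param k_min minimum cluster extent in voxels.
#' @return list with `clusters` (data frame: id, size, peak value, peak
#'   voxel coordinates) and `labels` (integer array; only surviving
#'   clusters, relabelled 1..k). An empty table is a valid result.
#' @export
threshold_and_label <- function(stat_map, df, primary_p, k_min) {
  stat_map <- as.array(stat_map)
  crit <- if (is.infinite(df)) stats::qnorm(1 - primary_p / 2) else
    stats::qt(1 - primary_p / 2, df)
  supra <- !is.na(stat_map) & abs(stat_map) > crit
  labels <- label_clusters(supra)
  n <- attr(labels, "n_clusters")
  out_labels <- array(0L, dim = dim(stat_map))
  rows <- list()
  keep_id <- 0L
  if (n > 0L) {
    sizes <- tabulate(labels[labels > 0L], nbins = n)
    for (cl in seq_len(n)) {
      if (sizes[cl] < k_min) next
      keep_id <- keep_id + 1L
      vox <- which(labels == cl)
      out_labels[vox] <- keep_id
      peak <- vox[which.max(abs(stat_map[vox]))]
      pc <- arrayInd(peak, dim(stat_map))
      rows[[keep_id]] <- data.frame(id = keep_id, size = sizes[cl],
                                    peak_value = stat_map[peak],
                                    peak_x = pc[1L], peak_y = pc[2L],
                                    peak_z = pc[3L])
    }
  }
  clusters <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(id = integer(), size = integer(), peak_value = numeric(),
               peak_x = integer(), peak_y = integer(), peak_z = integer())
  attr(out_labels, "n_clusters") <- keep_id
  list(clusters = clusters, labels = out_labels)
}
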