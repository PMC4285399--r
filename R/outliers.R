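#' Detect outlier volumes from slice-wise intensity features
#'
#' For each volume the slice-wise means and slice-wise standard deviations
#' (across in-plane voxels) are concatenated into a feature vector; squared
#' Mahalanobis distances of these vectors to their sample mean/covariance are
#' referred to a chi-squared tail, and a volume is flagged only when its tail
#' probability survives the more stringent of Bonferroni and
#' Benjamini-Hochberg FDR correction, i.e. it is significant under both.
#'
#' Zero-variance features are dropped; a (near-)singular covariance triggers
#' documented ridge shrinkage of the covariance diagonal with a warning. If
#' every feature is constant (identical volumes) no volume is flagged.
#'
#' @param series_4d numeric 4-D array (x, y, z, time) with at least 2 slices.
#' @param alpha significance level for both corrections.
#' @return logical vector, one flag per volume.
#' @export
detect_outlier_images <- function(series_4d, alpha = 0.05) {
  d <- dim(series_4d)
  if (length(d) != 4L) stop("series_4d must be a 4-D array (x, y, z, time)")
  if (d[3L] < 2L) stop("need at least 2 slices")
  n_t <- d[4L]
  feats <- matrix(NA_real_, n_t, 2L * d[3L])
  for (t in seq_len(n_t)) {
    vol <- series_4d[, , , t, drop = FALSE]
    sl <- apply(vol, 3L, function(s) c(mean(s), stats::sd(as.vector(s))))
    feats[t, ] <- as.vector(t(sl))
  }
  keep <- apply(feats, 2L, stats::sd) > 0
  if (!any(keep)) {
    warning("all slice features are constant; covariance shrunk, no flags")
    return(rep(FALSE, n_t))
  }
  Fm <- feats[, keep, drop = FALSE]
  mu <- colMeans(Fm)
  S <- stats::cov(Fm)
  if (rcond_safe(S) < 1e-10 || n_t <= ncol(Fm)) {
    warning("singular or ill-conditioned feature covariance; ",
            "applying ridge shrinkage")
    S <- S + diag(mean(diag(S)) * 0.05 + 1e-12, ncol(S))
  }
  ctr <- sweep(Fm, 2L, mu)
  d2 <- rowSums((ctr %*% solve(S)) * ctr)
  p <- stats::pchisq(d2, df = ncol(Fm), lower.tail = FALSE)
  sig_bonf <- stats::p.adjust(p, method = "bonferroni") < alpha
  sig_fdr <- stats::p.adjust(p, method = "BH") < alpha
  sig_bonf & sig_fdr
}

rcond_safe <- function(S) {
  out <- tryCatch(rcond(S), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}
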