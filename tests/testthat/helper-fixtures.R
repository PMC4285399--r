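# Shared fixtures and independent oracles, all built in code at test time.

# Moore-Penrose least squares via SVD: independent of the package's QR path.
pinv_solve <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
}

# Simple multilevel mediation dataset with subject random effects;
# a and b are population path slopes.
make_mediation_data <- function(n_subjects, n_trials, a = 0.5, b = 0.3,
                                sd_a = 0.15, sd_b = 0.1, noise = 1,
                                seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    x <- rnorm(n_trials)
    a_s <- rnorm(1, a, sd_a)
    b_s <- rnorm(1, b, sd_b)
    m <- a_s * x + rnorm(n_trials, 0, noise)
    y <- b_s * m + rnorm(n_trials, 0, noise)
    rows[[s]] <- data.frame(subject = s, x = x, m = m, y = y)
  }
  do.call(rbind, rows)
}

# Small noise-free ground truth: every SD zero.
noise_free_params <- function(...) {
  zeros_b <- c(rating_intercept = 0, temp_to_pain = 0, reg_to_pain_direct = 0,
               sig_intercept = 0, temp_to_sig = 0, sig_to_pain = 0,
               reg_to_m1 = 0, m1_to_m2 = 0, m2_to_pain = 0)
  zeros_r <- c(rating = 0, sig = 0, m1 = 0, m2 = 0)
  ground_truth_params(between_sd = zeros_b, residual_sd = zeros_r, ...)
}

# Face-adjacency connected components via igraph: independent labeling oracle.
igraph_components <- function(supra) {
  vox <- which(supra)
  if (length(vox) == 0L) return(integer(0))
  d <- dim(supra)
  coord <- arrayInd(vox, d)
  key <- function(ijk) ijk[, 1] + (ijk[, 2] - 1) * d[1] +
    (ijk[, 3] - 1) * d[1] * d[2]
  edges <- list()
  for (ax in 1:3) {
    nb <- coord
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    lin <- key(nb[ok, , drop = FALSE])
    present <- lin %in% vox
    from <- vox[ok][present]
    to <- lin[present]
    edges[[ax]] <- cbind(from, to)
  }
  E <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(rbind(E, cbind(vox, vox))), ncol = 2), directed = FALSE)
  comp <- igraph::components(g)
  stats::setNames(comp$membership[as.character(vox)], vox)
}
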