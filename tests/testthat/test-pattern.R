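make_signature <- function(dim3 = c(8, 8, 6), n_mask = 60, n_regions = 0,
                           seed = 1) {
  set.seed(seed)
  mask <- array(FALSE, dim3)
  mask[sample(prod(dim3), n_mask)] <- TRUE
  w <- array(0, dim3)
  w[mask] <- rnorm(n_mask)
  labels <- NULL
  if (n_regions > 0) {
    labels <- array(0L, dim3)
    labels[mask] <- sample(seq_len(n_regions), n_mask, replace = TRUE)
  }
  signature_pattern(w, mask, region_labels = labels)
}

test_that("pattern response equals the hand-computed dot product", {
  w <- array(0, c(3, 2, 2)); m <- array(FALSE, c(3, 2, 2))
  m[1:3, 1, 1] <- TRUE; w[1:3, 1, 1] <- c(1, -1, 2)
  sig <- signature_pattern(w, m)
  img <- array(0, c(3, 2, 2)); img[1:3, 1, 1] <- c(2, 3, 1)
  expect_equal(pattern_response(img, sig), 1)
  expect_equal(pattern_response(array(0, c(3, 2, 2)), sig), 0)
})

test_that("pattern response matches an explicit loop oracle on random images", {
  sig <- make_signature(dim3 = c(10, 10, 8), n_mask = 500, seed = 2)
  set.seed(3)
  img <- array(rnorm(prod(dim(sig$mask))), dim(sig$mask))
  loop <- 0
  for (i in which(sig$mask)) loop <- loop + sig$weights[i] * img[i]
  expect_lt(abs(pattern_response(img, sig) - loop), 1e-10)
})

test_that("pattern response is linear and warns on missing voxels", {
  sig <- make_signature(seed = 4)
  set.seed(5)
  X <- array(rnorm(prod(dim(sig$mask))), dim(sig$mask))
  Y <- array(rnorm(prod(dim(sig$mask))), dim(sig$mask))
  lhs <- pattern_response(2.5 * X + Y, sig)
  rhs <- 2.5 * pattern_response(X, sig) + pattern_response(Y, sig)
  expect_lt(abs(lhs - rhs), 1e-10)
  Xna <- X
  Xna[which(sig$mask)[1]] <- NA
  expect_warning(v <- pattern_response(Xna, sig), "missing")
  X0 <- X; X0[which(sig$mask)[1]] <- 0
  expect_equal(v, pattern_response(X0, sig))
})

test_that("grid mismatch raises instead of resampling", {
  sig <- make_signature(seed = 6)
  expect_error(pattern_response(array(0, c(4, 4, 4)), sig), "grid")
})

test_that("local responses over a partition sum to the whole-pattern response", {
  sig <- make_signature(n_mask = 300, n_regions = 15, seed = 7)
  set.seed(8)
  img <- array(rnorm(prod(dim(sig$mask))), dim(sig$mask))
  whole <- pattern_response(img, sig)
  parts <- vapply(seq_len(15), function(r) {
    local_pattern_response(img, sig, r)
  }, numeric(1))
  expect_lt(abs(sum(parts) - whole), 1e-10)
  # per-region loop oracle
  for (r in c(1, 7, 15)) {
    sel <- sig$mask & sig$region_labels == r
    expect_lt(abs(parts[r] - sum(sig$weights[sel] * img[sel])), 1e-10)
  }
})

test_that("single-voxel region scores weight times value; empty regions raise", {
  w <- array(0, c(3, 3, 3)); m <- array(FALSE, c(3, 3, 3))
  m[2, 2, 2] <- TRUE; w[2, 2, 2] <- 2
  lab <- array(0L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
  sig <- signature_pattern(w, m, region_labels = lab)
  img <- array(3, c(3, 3, 3))
  expect_equal(local_pattern_response(img, sig, 1), 6)
  expect_error(local_pattern_response(img, sig, 9), "empty")
})

test_that("sphere ROI averages match an explicit distance-loop oracle", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  dims <- c(9, 9, 9)
  set.seed(9)
  vol <- array(rnorm(prod(dims)), dims)
  # constant image: mean is the constant, any center/radius
  expect_equal(roi_sphere_average(array(5, dims), c(1, 2, -3), 6, aff), 5)
  # radius below half a voxel at a voxel center picks that voxel
  expect_equal(roi_sphere_average(vol, c(0, 0, 0), 0.9, aff), vol[5, 5, 5])
  # 6-mm sphere on the 2-mm grid: identical voxel set and mean as the loop
  idx <- sphere_voxels(dims, c(0, 0, 0), 6, aff)
  loop_idx <- c()
  for (i in 0:8) for (j in 0:8) for (k in 0:8) {
    wc <- c(2 * i - 8, 2 * j - 8, 2 * k - 8)
    if (sum(wc^2) <= 36) {
      loop_idx <- c(loop_idx, 1 + i + 9 * j + 81 * k)
    }
  }
  expect_setequal(idx, loop_idx)
  expect_equal(roi_sphere_average(vol, c(0, 0, 0), 6, aff),
               mean(vol[sort(loop_idx)]))
  expect_error(roi_sphere_average(vol, c(500, 0, 0), 3, aff), "no voxel")
})

test_that("responses are invariant to axis flips when the affine is honored", {
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  dims <- c(9, 9, 9)
  set.seed(10)
  vol <- array(rnorm(prod(dims)), dims)
  # flip the first axis on disk and adjust the affine accordingly
  vol_f <- vol[dims[1]:1, , ]
  aff_f <- aff
  aff_f[1, 1] <- -2
  aff_f[1, 4] <- 8
  expect_equal(roi_sphere_average(vol, c(3, -2, 4), 6, aff),
               roi_sphere_average(vol_f, c(3, -2, 4), 6, aff_f))
})

test_that("NIfTI round trip preserves data and affine", {
  dims <- c(6, 5, 4)
  set.seed(11)
  vol <- array(rnorm(prod(dims)), dims)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-6, -5, -4)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path, affine = aff)
  back <- read_volume(path)
  expect_equal(as.numeric(back$data), as.numeric(vol), tolerance = 1e-6)
  expect_equal(unname(back$affine[1:3, 1:3]), unname(aff[1:3, 1:3]),
               tolerance = 1e-6)
})
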