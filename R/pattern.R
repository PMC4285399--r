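#' Construct a multivariate signature pattern
#'
#' A signature is a voxel-weight map defined on a binary support mask, with
#' an optional integer partition of the support into sub-regions. Weights
#' outside the mask are ignored. Vectorization order is fixed as ascending
#' linear voxel index (first axis fastest), applied identically to weights
#' and images.
#'
#' @param weights 3-D numeric array of voxel weights.
#' @param mask logical array of the same dimensions defining the support.
#' @param region_labels optional integer array; non-zero labels must lie
#'   inside the mask.
#' @param affine optional 4 x 4 voxel-to-world transform.
#' @return object of class `signature_pattern`.
#' @export
signature_pattern <- function(weights, mask, region_labels = NULL,
                              affine = NULL) {
  weights <- as.array(weights)
  mask <- array(as.logical(mask), dim = dim(weights))
  if (!identical(dim(weights), dim(mask))) stop("weights/mask grid mismatch")
  if (!is.null(region_labels)) {
    region_labels <- array(as.integer(region_labels), dim = dim(weights))
    if (any(region_labels != 0L & !mask)) {
      stop("region labels must lie inside the mask")
    }
  }
  structure(list(weights = weights, mask = mask,
                 region_labels = region_labels, affine = affine),
            class = "signature_pattern")
}

#' Signature pattern-expression score of a beta image
#'
#' The dot product of the vectorized beta image with the signature weights
#' over the signature mask. Voxels that are missing (NA) in the beta image
#' contribute zero; their count is reported with a warning.
#'
#' @param beta_volume 3-D numeric array on the same grid as the signature.
#' @param signature a [signature_pattern()].
#' @return scalar pattern response (signature units).
#' @export
pattern_response <- function(beta_volume, signature) {
  stopifnot(inherits(signature, "signature_pattern"))
  beta_volume <- as.array(beta_volume)
  if (!identical(dim(beta_volume), dim(signature$mask))) {
    stop("beta volume grid does not match the signature grid; ",
         "no silent resampling is performed")
  }
  b <- beta_volume[signature$mask]
  w <- signature$weights[signature$mask]
  n_missing <- sum(is.na(b))
  if (n_missing > 0L) {
    warning(n_missing, " in-mask voxels missing in the beta image; ",
            "they contribute 0")
    b[is.na(b)] <- 0
  }
  sum(w * b)
}

#' Local pattern response within one signature sub-region
#'
#' Dot product restricted to the voxels carrying the given region label.
#'
#' @param beta_volume 3-D numeric array on the signature grid.
#' @param signature a [signature_pattern()] with `region_labels`.
#' @param region_id label to score.
#' @return scalar local pattern response.
#' @export
local_pattern_response <- function(beta_volume, signature, region_id) {
  stopifnot(inherits(signature, "signature_pattern"))
  if (is.null(signature$region_labels)) stop("signature has no region labels")
  sel <- signature$mask & signature$region_labels == region_id
  if (!any(sel)) stop("region ", region_id, " is empty")
  beta_volume <- as.array(beta_volume)
  if (!identical(dim(beta_volume), dim(signature$mask))) {
    stop("beta volume grid does not match the signature grid")
  }
  b <- beta_volume[sel]
  b[is.na(b)] <- 0
  sum(signature$weights[sel] * b)
}

#' Average beta value within a spherical ROI
#'
#' Unweighted mean of the beta values at voxels whose world-coordinate
#' centers lie within `radius_mm` (inclusive) of `center_mm` under the given
#' voxel-to-world affine.
#'
#' @param beta_volume 3-D numeric array.
#' @param center_mm length-3 world coordinates of the sphere center.
#' @param radius_mm sphere radius in mm.
#' @param affine 4 x 4 voxel-to-world transform (0-based voxel indices).
#' @return scalar mean; errors if the sphere contains no voxel centers.
#' @export
roi_sphere_average <- function(beta_volume, center_mm, radius_mm, affine) {
  beta_volume <- as.array(beta_volume)
  idx <- sphere_voxels(dim(beta_volume), center_mm, radius_mm, affine)
  if (length(idx) == 0L) stop("sphere contains no voxel centers")
  mean(beta_volume[idx])
}

#' Linear indices of voxels inside a sphere
#'
#' @inheritParams roi_sphere_average
#' @param grid_shape integer length-3 voxel counts.
#' @return integer vector of linear voxel indices (ascending).
#' @export
sphere_voxels <- function(grid_shape, center_mm, radius_mm, affine) {
  g <- expand.grid(i = 0:(grid_shape[1L] - 1L),
                   j = 0:(grid_shape[2L] - 1L),
                   k = 0:(grid_shape[3L] - 1L))
  world <- as.matrix(g) %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(g), 3L, byrow = TRUE)
  d2 <- (world[, 1L] - center_mm[1L])^2 + (world[, 2L] - center_mm[2L])^2 +
    (world[, 3L] - center_mm[3L])^2
  which(d2 <= radius_mm^2)
}

#' Read a NIfTI volume as a plain array with its affine
#' @param path NIfTI file path.
#' @return list with `data` (array) and `affine` (4 x 4 voxel-to-world).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write an array to NIfTI with an affine
#' @param data numeric array (3-D or 4-D).
#' @param path output file path.
#' @param affine 4 x 4 voxel-to-world transform.
#' @param voxel_size fallback isotropic voxel size if no affine is given.
#' @export
write_volume <- function(data, path, affine = NULL, voxel_size = 2) {
  if (is.null(affine)) affine <- diag(c(rep(voxel_size, 3), 1))
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
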