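# Static seed-based functional connectivity.

#' Spherical region of interest around a world-space coordinate
#'
#' Collects every voxel whose center lies within `radius_mm` of `center_mm`
#' under the image affine. The conventional choice for point-coordinate
#' seeds on 3 mm grids is a 6 mm radius.
#'
#' @param center_mm Numeric length-3 world coordinate (mm).
#' @param radius_mm Sphere radius (mm).
#' @param dim3 Integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @param name Optional ROI label.
#' @return An `roi_mask`: list with `name`, `center_mm`, `radius_mm`,
#'   `voxels` (linear indices into the grid) and `dim3`.
#' @export
make_sphere_roi <- function(center_mm, radius_mm, dim3, affine, name = "roi") {
  stopifnot(length(center_mm) == 3L, length(dim3) == 3L)
  coords <- voxel_coords_mm(dim3, affine)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  if (any(center_mm < lo - 1e-9) || any(center_mm > hi + 1e-9)) {
    abort_bh("ROI center lies outside the image bounds.", "config_error")
  }
  d2 <- rowSums(sweep(coords, 2, center_mm)^2)
  vox <- which(d2 <= radius_mm^2 + 1e-9)
  if (length(vox) == 0) {
    abort_bh("Sphere radius smaller than voxel spacing: empty ROI.", "config_error")
  }
  structure(
    list(
      name = name, center_mm = center_mm, radius_mm = radius_mm,
      voxels = vox, dim3 = as.integer(dim3)
    ),
    class = "roi_mask"
  )
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> '%s': %d voxels within %g mm of (%g, %g, %g)\n",
    x$name, length(x$voxels), x$radius_mm,
    x$center_mm[1], x$center_mm[2], x$center_mm[3]
  ))
  invisible(x)
}

#' Mean time series of a region of interest
#'
#' @param img A `ts_img`.
#' @param roi An `roi_mask`, or a logical 3D array / vector of linear voxel
#'   indices.
#' @return Numeric vector, one value per volume.
#' @export
roi_timeseries <- function(img, roi) {
  stopifnot(inherits(img, "ts_img"))
  vox <- if (inherits(roi, "roi_mask")) {
    if (!all(roi$dim3 == grid_dim(img))) {
      abort_bh("ROI grid does not match the image grid.", "data_error")
    }
    roi$voxels
  } else if (is.logical(roi) || is.array(roi)) {
    which(as.logical(roi))
  } else {
    as.integer(roi)
  }
  if (length(vox) == 0) abort_bh("Empty ROI.", "data_error")
  colMeans(as_voxel_matrix(img)[vox, , drop = FALSE])
}

#' Voxelwise seed correlation map
#'
#' Pearson correlation between a seed time series and every in-mask voxel.
#' Constant voxels yield `NA` and are flagged. Invariant to affine
#' rescaling of either series.
#'
#' @param img A `ts_img`.
#' @param seed_series Numeric vector, length = number of volumes.
#' @param mask Logical 3D array of analysis voxels (e.g. grey matter); if
#'   `NULL`, all voxels.
#' @return A tibble with `voxel` (linear index), `r`, and `flagged`
#'   (constant voxel).
#' @export
fc_map <- function(img, seed_series, mask = NULL) {
  stopifnot(inherits(img, "ts_img"))
  nv <- n_volumes(img)
  if (length(seed_series) != nv) {
    abort_bh("Seed series length must equal the number of volumes.", "data_error")
  }
  if (nv < 3) abort_bh("Need at least 3 volumes.", "data_error")
  if (stats::sd(seed_series) == 0) {
    abort_bh("Seed series is constant.", "data_error")
  }
  vox <- if (is.null(mask)) seq_len(prod(grid_dim(img))) else which(as.logical(mask))
  mat <- t(as_voxel_matrix(img)[vox, , drop = FALSE])
  r <- cor_vs_matrix(seed_series, mat)
  tibble::tibble(voxel = vox, r = r, flagged = is.na(r))
}

#' Seed-based Fisher-z connectivity map for one session
#'
#' Convenience wrapper: ROI mean series, voxelwise correlation over the
#' analysis mask, Fisher r-to-z.
#'
#' @param img A preprocessed `ts_img`.
#' @param roi An `roi_mask` (or mask/indices accepted by
#'   [roi_timeseries()]).
#' @param mask Analysis (grey-matter) mask; on synthetic data the union of
#'   atlas networks.
#' @return A tibble with `voxel`, `r`, `z`, `flagged`.
#' @export
seed_zmap <- function(img, roi, mask = NULL) {
  fc <- fc_map(img, roi_timeseries(img, roi), mask)
  fc$z <- fisher_z(fc$r)
  fc
}
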