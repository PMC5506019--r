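#' 4D BOLD time-series image container
#'
#' A lightweight container for a voxel-by-time signal on a 3D grid: a 4D
#' array `(x, y, z, t)` plus the repetition time and a voxel-to-world
#' affine. All preprocessing and connectivity functions accept and return
#' this class.
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param tr_s Repetition time in seconds (time between successive volumes).
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a diagonal
#'   3 mm isotropic affine.
#' @param t0_s Acquisition time of the first retained volume relative to the
#'   session start, in seconds (volume trimming advances this).
#' @return An object of class `ts_img`.
#' @export
ts_img <- function(data, tr_s, affine = NULL, t0_s = 0) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (!is.numeric(tr_s) || tr_s <= 0) {
    abort_bh("`tr_s` must be a positive repetition time in seconds.", "config_error")
  }
  if (is.null(affine)) {
    affine <- diag(c(3, 3, 3, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(
    list(data = data, tr_s = tr_s, affine = affine, t0_s = t0_s),
    class = "ts_img"
  )
}

#' @export
print.ts_img <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ts_img> %d x %d x %d grid, %d volumes, TR = %g s, t0 = %g s\n",
    d[1], d[2], d[3], d[4], x$tr_s, x$t0_s
  ))
  invisible(x)
}

#' @export
dim.ts_img <- function(x) dim(x$data)

n_volumes <- function(img) dim(img$data)[4]

grid_dim <- function(img) dim(img$data)[1:3]

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Voxel x time matrix view of a ts_img (voxels in array order).
as_voxel_matrix <- function(img) {
  d <- dim(img$data)
  matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])
}

# Rebuild a ts_img from a voxel x time matrix using `img` as geometry donor.
from_voxel_matrix <- function(mat, img) {
  d <- grid_dim(img)
  ts_img(array(mat, dim = c(d, ncol(mat))), img$tr_s, img$affine, img$t0_s)
}

# World-space (mm) coordinates of all voxel centers, V x 3, array order.
voxel_coords_mm <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(dim3[1]), j = seq_len(dim3[2]), k = seq_len(dim3[3])
  ))
  # 0-based voxel indices, as in the NIfTI convention
  xyz1 <- cbind(idx - 1, 1)
  t(affine %*% t(xyz1))[, 1:3, drop = FALSE]
}
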