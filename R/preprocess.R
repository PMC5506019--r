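# Temporal preprocessing of 4D BOLD images. Fixed stage order:
# trim -> (optional) smooth -> nuisance regression -> band-pass.

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes (magnetization stabilization) and
#' advances the image's time origin accordingly, so window grids laid out
#' on the trimmed series stay aligned with the PPG clock.
#'
#' @param img A `ts_img`.
#' @param n_discard Number of leading volumes to drop (default 5).
#' @return A trimmed `ts_img`.
#' @export
discard_initial_volumes <- function(img, n_discard = 5L) {
  stopifnot(inherits(img, "ts_img"))
  nv <- n_volumes(img)
  if (n_discard >= nv) {
    abort_bh(
      sprintf("Cannot discard %d of %d volumes.", n_discard, nv),
      "config_error"
    )
  }
  if (n_discard == 0L) return(img)
  ts_img(
    img$data[, , , (n_discard + 1L):nv, drop = FALSE],
    img$tr_s, img$affine, img$t0_s + n_discard * img$tr_s
  )
}

#' Mean tissue signals as confound columns
#'
#' @param img A `ts_img`.
#' @param masks Named list of logical 3D arrays (e.g. `wm`, `csf`).
#' @return A tibble with one column per tissue, one row per volume.
#' @export
extract_tissue_means <- function(img, masks) {
  stopifnot(inherits(img, "ts_img"), is.list(masks))
  mat <- as_voxel_matrix(img)
  out <- lapply(masks, function(m) {
    idx <- which(as.logical(m))
    if (length(idx) == 0) abort_bh("Empty tissue mask.", "data_error")
    colMeans(mat[idx, , drop = FALSE])
  })
  tibble::as_tibble(out)
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least squares of each voxel time series on the confound columns
#' plus an intercept; the returned image holds the residuals, which are
#' exactly orthogonal to every confound column.
#'
#' @param img A `ts_img`.
#' @param confounds Data frame of confounds (motion parameters, tissue
#'   means), one row per volume.
#' @return A `ts_img` of residuals.
#' @export
regress_nuisance <- function(img, confounds) {
  stopifnot(inherits(img, "ts_img"))
  confounds <- as.data.frame(confounds)
  nv <- n_volumes(img)
  if (nrow(confounds) != nv) {
    abort_bh(
      sprintf("Confounds have %d rows but image has %d volumes.", nrow(confounds), nv),
      "data_error"
    )
  }
  if (anyNA(confounds)) abort_bh("Confounds contain missing values.", "data_error")
  d <- cbind(intercept = 1, as.matrix(confounds))
  qrd <- qr(d)
  if (qrd$rank < ncol(d)) {
    drop_cols <- colnames(d)[qrd$pivot[(qrd$rank + 1):ncol(d)]]
    abort_bh(
      sprintf("Confound design is rank deficient (collinear: %s).",
              paste(drop_cols, collapse = ", ")),
      "data_error"
    )
  }
  mat <- t(as_voxel_matrix(img)) # time x voxels
  res <- qr.resid(qrd, mat)
  from_voxel_matrix(t(res), img)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) order-2 Butterworth band-pass applied to
#' every voxel time series. The default 0.009-0.08 Hz band retains slow
#' BOLD fluctuations while removing scanner drift and high-frequency
#' physiological noise; the DC component is removed entirely.
#'
#' @param img A `ts_img`.
#' @param low_hz,high_hz Band edges in Hz (defaults 0.009 and 0.08);
#'   `high_hz` must lie below the Nyquist frequency `1 / (2 * tr_s)`.
#' @param order Butterworth order per pass (default 2).
#' @return A filtered `ts_img`.
#' @export
bandpass <- function(img, low_hz = 0.009, high_hz = 0.08, order = 2L) {
  stopifnot(inherits(img, "ts_img"))
  nyq <- 1 / (2 * img$tr_s)
  if (high_hz >= nyq) {
    abort_bh(
      sprintf("high_hz (%g) must be below Nyquist (%g Hz).", high_hz, nyq),
      "config_error"
    )
  }
  if (low_hz >= high_hz) abort_bh("low_hz must be below high_hz.", "config_error")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  mat <- as_voxel_matrix(img)
  nt <- ncol(mat)
  # demean and reflect-pad each series to suppress filtfilt edge transients
  npad <- min(nt - 1L, 50L)
  pad_filter <- function(x) {
    mu <- mean(x)
    xc <- x - mu
    xp <- c(2 * xc[1] - xc[(npad + 1L):2L], xc, 2 * xc[nt] - xc[(nt - 1L):(nt - npad)])
    yf <- signal::filtfilt(bf, xp)
    yf[(npad + 1L):(npad + nt)]
  }
  out <- t(apply(mat, 1, pad_filter))
  # the pass band excludes DC: remove the residual finite-series mean
  out <- out - rowMeans(out)
  from_voxel_matrix(out, img)
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian convolution with kernel
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` in mm, converted to voxels via
#' the affine's voxel sizes. Zero padding at the boundary; the kernel sums
#' to one, so interior mass is preserved.
#'
#' @param img A `ts_img`.
#' @param fwhm_mm Full width at half maximum in mm (default 6; 0 is the
#'   identity).
#' @return A smoothed `ts_img`.
#' @export
smooth_image <- function(img, fwhm_mm = 6) {
  stopifnot(inherits(img, "ts_img"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(img)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_sizes(img$affine)
  dims <- grid_dim(img)
  kernels <- lapply(1:3, function(a) {
    s <- sig_mm / vs[a]
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k / sum(k)
  })
  dat <- img$data
  conv_axis <- function(arr, k, axis) {
    r <- (length(k) - 1L) / 2L
    out <- array(0, dim = dim(arr))
    n <- dim(arr)[axis]
    for (off in -r:r) {
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      idx_dst <- which(ok)
      idx_src <- src[ok]
      w <- k[off + r + 1L]
      if (axis == 1) {
        out[idx_dst, , , ] <- out[idx_dst, , , , drop = FALSE] +
          w * arr[idx_src, , , , drop = FALSE]
      } else if (axis == 2) {
        out[, idx_dst, , ] <- out[, idx_dst, , , drop = FALSE] +
          w * arr[, idx_src, , , drop = FALSE]
      } else {
        out[, , idx_dst, ] <- out[, , idx_dst, , drop = FALSE] +
          w * arr[, , idx_src, , drop = FALSE]
      }
    }
    out
  }
  for (a in 1:3) {
    if (dims[a] > 1L) dat <- conv_axis(dat, kernels[[a]], a)
  }
  ts_img(dat, img$tr_s, img$affine, img$t0_s)
}

#' Full temporal preprocessing of one session
#'
#' Fixed order: trim leading volumes, optional spatial smoothing, nuisance
#' regression (6 motion parameters + white-matter and CSF means), zero-phase
#' band-pass. Deterministic: re-running on identical input is bit-identical.
#'
#' @param session A `bh_session` (or a list with `img`, `motion`, `masks`).
#' @param n_discard Leading volumes to drop (default 5).
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 0 = none; synthetic
#'   data needs no smoothing).
#' @param low_hz,high_hz Band-pass edges (defaults 0.009, 0.08 Hz).
#' @return A preprocessed `ts_img`.
#' @export
preprocess_session <- function(session, n_discard = 5L, fwhm_mm = 0,
                               low_hz = 0.009, high_hz = 0.08) {
  img <- discard_initial_volumes(session$img, n_discard)
  if (fwhm_mm > 0) img <- smooth_image(img, fwhm_mm)
  motion <- session$motion[
    (n_discard + 1L):(n_discard + n_volumes(img)), ,
    drop = FALSE
  ]
  tissue <- extract_tissue_means(img, session$masks)
  img <- regress_nuisance(img, cbind(motion, tissue))
  bandpass(img, low_hz, high_hz)
}
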