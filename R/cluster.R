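# Cluster-level permutation inference on 3D statistic maps.
#
# The cluster-defining threshold (CDT) converts the voxelwise statistic map
# into suprathreshold sets (positive and negative separately); connected
# components are formed under a 6/18/26 lattice neighbourhood; the null
# distribution of the maximum cluster size is built by permutation
# (sign-flipping for one-sample designs, within-subject condition swaps for
# paired designs, covariate shuffling for regressions); and each observed
# cluster gets p_fwe = (1 + #{null max >= size}) / (n_perm + 1).

neighbour_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(offs)) == 1,
    "18" = rowSums(offs != 0) <= 2,
    "26" = rep(TRUE, nrow(offs)),
    abort_bh("`connectivity` must be 6, 18 or 26.", "config_error")
  )
  offs[keep, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' Flood-fill labelling of `TRUE` voxels under a 6-, 18- or 26-neighbour
#' lattice connectivity rule (18 is the default, the common convention in
#' fMRI cluster inference).
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array: 0 outside the mask, cluster id (1, 2, ...)
#'   inside.
#' @export
label_clusters <- function(mask, connectivity = 18) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  lab <- array(0L, dims)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  coord <- arrayInd(idx, dims)
  rownames(coord) <- NULL
  in_mask <- array(FALSE, dims)
  in_mask[idx] <- TRUE
  cur <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(coord[s, ], ncol = 3)
    lab[idx[s]] <- cur
    while (nrow(queue) > 0) {
      pts <- queue
      queue <- matrix(integer(0), ncol = 3)
      for (o in seq_len(nrow(offs))) {
        nb <- sweep(pts, 2, offs[o, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
        new <- in_mask[lin] & lab[lin] == 0L
        if (any(new)) {
          lab[lin[new]] <- cur
          queue <- rbind(queue, nb[new, , drop = FALSE])
        }
      }
      if (nrow(queue) > 0) {
        lin <- queue[, 1] + (queue[, 2] - 1L) * dims[1] +
          (queue[, 3] - 1L) * dims[1] * dims[2]
        keep <- !duplicated(lin)
        queue <- queue[keep, , drop = FALSE]
      }
    }
  }
  lab
}

# t map from a subjects x voxels matrix (one-sample against 0); returns the
# t values (NA where variance is 0).
t_map <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  tt <- m / (s / sqrt(n))
  tt[s == 0] <- NA_real_
  tt
}

# maximum suprathreshold cluster size (pos and neg handled separately)
max_cluster_size <- function(tvals, dims, thr, connectivity, mask_idx = NULL) {
  arr_pos <- array(FALSE, dims)
  arr_neg <- array(FALSE, dims)
  if (is.null(mask_idx)) mask_idx <- seq_len(prod(dims))
  arr_pos[mask_idx] <- !is.na(tvals) & tvals > thr
  arr_neg[mask_idx] <- !is.na(tvals) & tvals < -thr
  m <- 0L
  for (a in list(arr_pos, arr_neg)) {
    if (any(a)) {
      lab <- label_clusters(a, connectivity)
      m <- max(m, max(tabulate(lab[lab > 0L])))
    }
  }
  m
}

#' Permutation cluster-level family-wise error inference
#'
#' Voxelwise statistic maps are thresholded at a cluster-defining threshold
#' (CDT, an uncorrected two-sided p), suprathreshold voxels are grouped
#' into connected components (positive and negative separately), and the
#' observed cluster sizes are referred to a permutation null distribution
#' of the maximum cluster size. Permutation schemes: `sign_flip` for
#' one-sample designs (random sign per subject), `condition_swap` for
#' paired designs (random within-subject swap of the two conditions),
#' `score_permute` for covariate regressions (shuffle the score).
#'
#' @param data Subjects x voxels matrix. For `sign_flip` these are the
#'   values tested against 0; for `condition_swap` supply `data` and
#'   `data_b` (the two conditions); for `score_permute` supply `score`.
#' @param dims Integer length-3 grid dimensions of the map.
#' @param scheme One of `"sign_flip"`, `"condition_swap"`,
#'   `"score_permute"`.
#' @param data_b Second condition (subjects x voxels), `condition_swap`
#'   only.
#' @param score Covariate, `score_permute` only.
#' @param mask_idx Linear indices of analysis voxels (default: all).
#' @param cdt_p Cluster-defining threshold as an uncorrected two-sided p
#'   (0.001 for FC contrasts, 0.005 for synchronization and regressions).
#' @param alpha Cluster-level FWE level (default 0.05).
#' @param n_perm Number of permutations (>= 99).
#' @param connectivity Lattice neighbourhood (6/18/26, default 18).
#' @param seed Integer seed for the permutation draws.
#' @param affine Optional 4x4 affine; peak coordinates are reported in mm
#'   when given.
#' @return A `cluster_table`: tibble with `cluster`, `sign`, `n_voxels`,
#'   `peak_stat`, `peak_x/y/z` (mm if `affine` given, else voxel),
#'   `p_fwe`, `significant`; attributes carry the CDT, the statistic map
#'   and the null maxima.
#' @export
cluster_inference <- function(data, dims,
                              scheme = c("sign_flip", "condition_swap", "score_permute"),
                              data_b = NULL, score = NULL, mask_idx = NULL,
                              cdt_p = 0.001, alpha = 0.05, n_perm = 199L,
                              connectivity = 18, seed = 1L, affine = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 99) abort_bh("Use at least 99 permutations.", "config_error")
  x <- as.matrix(data)
  n <- nrow(x)
  if (scheme == "condition_swap") {
    if (is.null(data_b)) {
      abort_bh("`condition_swap` needs both conditions (`data_b`).", "config_error")
    }
    b <- as.matrix(data_b)
    if (!all(dim(b) == dim(x))) {
      abort_bh("Conditions have mismatched dimensions.", "data_error")
    }
    x <- x - b # paired differences; swaps become sign flips of differences
  }
  if (scheme == "score_permute") {
    if (is.null(score)) abort_bh("`score_permute` needs `score`.", "config_error")
    if (length(score) != n) abort_bh("Score length must equal subjects.", "data_error")
  }
  stat_of <- function(xmat, sc = NULL) {
    if (scheme == "score_permute") {
      res <- regress_covariate(xmat, sc)
      res$t
    } else {
      t_map(xmat)
    }
  }
  df <- if (scheme == "score_permute") n - 2 else n - 1
  thr <- stats::qt(1 - cdt_p / 2, df)
  obs_t <- stat_of(x, score)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      tv <- if (scheme == "score_permute") {
        stat_of(x, sample(score))
      } else {
        stat_of(x * sample(c(-1, 1), n, replace = TRUE))
      }
      max_cluster_size(tv, dims, thr, connectivity, mask_idx)
    }, numeric(1))
  })
  # observed clusters
  if (is.null(mask_idx)) mask_idx <- seq_len(prod(dims))
  rows <- list()
  for (sgn in c(1, -1)) {
    arr <- array(FALSE, dims)
    arr[mask_idx] <- !is.na(obs_t) & sgn * obs_t > thr
    if (!any(arr)) next
    lab <- label_clusters(arr, connectivity)
    for (cl in seq_len(max(lab))) {
      vox <- which(lab == cl)
      tv <- numeric(prod(dims))
      tv[mask_idx] <- obs_t
      pk <- vox[which.max(sgn * tv[vox])]
      pc <- arrayInd(pk, dims)
      if (!is.null(affine)) {
        pc <- (affine %*% c(pc - 1, 1))[1:3]
      }
      size <- length(vox)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sign = if (sgn > 0) "positive" else "negative",
        n_voxels = size,
        peak_stat = tv[pk],
        peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
        p_fwe = (1 + sum(null_max >= size)) / (n_perm + 1)
      )
    }
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(
      sign = character(), n_voxels = integer(), peak_stat = numeric(),
      peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
      p_fwe = numeric()
    )
  } else {
    dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(n_voxels))
  }
  out <- dplyr::mutate(
    out,
    cluster = dplyr::row_number(),
    significant = p_fwe <= alpha,
    .before = 1
  )
  attr(out, "cdt_p") <- cdt_p
  attr(out, "cdt_t") <- thr
  attr(out, "n_perm") <- n_perm
  attr(out, "connectivity") <- connectivity
  attr(out, "stat_map") <- obs_t
  attr(out, "null_max") <- null_max
  class(out) <- c("cluster_table", class(out))
  out
}
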