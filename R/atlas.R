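#' Build a block-structured synthetic network atlas
#'
#' Partitions a 3D voxel grid into `n_networks` disjoint, spatially
#' contiguous rectangular parcels separated by background (label 0), and
#' places named seed voxels (PCC, VMPFC, bilateral amygdala, bilateral
#' nucleus accumbens analogues) inside the parcels. The atlas plays the
#' role that published seed coordinates and matched IC network maps play on
#' real data: it is the ground truth every downstream stage is tested
#' against.
#'
#' Parcels are slabs along the longest grid axis, each spanning the full
#' extent of the two other axes, so contiguity holds by construction. Every
#' parcel must contain at least 27 voxels (a 3x3x3 neighbourhood).
#'
#' @param grid_shape Integer vector of length 3, voxel dimensions.
#' @param n_networks Number of networks `K >= 2`.
#' @param seed Integer seed (kept for interface stability; the construction
#'   is deterministic).
#' @param voxel_size_mm Isotropic voxel size used for the affine (default 3).
#' @return A `network_atlas`: list with `grid_shape`, `labels` (3D integer
#'   array, 0 = background), `seed_points` (named list of voxel index
#'   triplets), `affine`, and `network_names`.
#' @examples
#' atl <- make_network_atlas(c(16, 16, 8), n_networks = 5, seed = 1)
#' table(atl$labels)
#' @export
make_network_atlas <- function(grid_shape, n_networks, seed = 1L,
                               voxel_size_mm = 3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (n_networks < 2) {
    abort_bh("`n_networks` must be at least 2.", "config_error")
  }
  axis <- which.max(grid_shape)
  # one background plane between consecutive slabs
  slab <- (grid_shape[axis] - (n_networks - 1L)) %/% n_networks
  plane <- prod(grid_shape[-axis])
  if (slab < 1L || slab * plane < 27L) {
    abort_bh(
      sprintf(
        paste0(
          "Grid %s cannot hold %d disjoint contiguous networks of >= 27 ",
          "voxels each."
        ),
        paste(grid_shape, collapse = "x"), n_networks
      ),
      "capacity_error"
    )
  }
  labels <- array(0L, dim = grid_shape)
  starts <- integer(n_networks)
  for (k in seq_len(n_networks)) {
    start <- (k - 1L) * (slab + 1L) + 1L
    starts[k] <- start
    idx <- vector("list", 3L)
    for (a in 1:3) idx[[a]] <- seq_len(grid_shape[a])
    idx[[axis]] <- start:(start + slab - 1L)
    labels[idx[[1]], idx[[2]], idx[[3]]] <- k
  }
  network_names <- c(
    "dmn", "temporolimbic", "salience", "fp_left", "fp_right",
    paste0("net", seq_len(max(0L, n_networks - 5L)) + 5L)
  )[seq_len(n_networks)]

  centre_of <- function(k, shift = c(0L, 0L, 0L)) {
    ctr <- pmax(1L, pmin(grid_shape, (grid_shape + 1L) %/% 2L))
    ctr[axis] <- starts[k] + (slab - 1L) %/% 2L
    pmax(1L, pmin(grid_shape, ctr + shift))
  }
  clamp_into <- function(k, p) {
    p[axis] <- pmax(starts[k], pmin(starts[k] + slab - 1L, p[axis]))
    p
  }
  seed_points <- list(
    pcc     = centre_of(1L),
    vmpfc   = clamp_into(1L, centre_of(1L, c(1L, 1L, 0L))),
    amyg_l  = centre_of(min(2L, n_networks), c(-1L, 0L, 0L)),
    amyg_r  = centre_of(min(2L, n_networks), c(1L, 0L, 0L)),
    nacc_l  = centre_of(min(3L, n_networks), c(-1L, 0L, 0L)),
    nacc_r  = centre_of(min(3L, n_networks), c(1L, 0L, 0L))
  )
  seed_points <- lapply(seed_points, function(p) {
    k <- labels[p[1], p[2], p[3]]
    if (k == 0L) {
      # nudge along the slab axis until inside a parcel
      for (d in c(-1L, 1L, -2L, 2L)) {
        q <- p
        q[axis] <- min(max(1L, p[axis] + d), grid_shape[axis])
        if (labels[q[1], q[2], q[3]] != 0L) return(q)
      }
    }
    p
  })
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  structure(
    list(
      grid_shape = grid_shape, labels = labels, seed_points = seed_points,
      affine = affine, network_names = network_names,
      n_networks = as.integer(n_networks), seed = as.integer(seed)
    ),
    class = "network_atlas"
  )
}

#' @export
print.network_atlas <- function(x, ...) {
  cat(sprintf(
    "<network_atlas> %s grid, %d networks (%s), %d background voxels\n",
    paste(x$grid_shape, collapse = "x"), x$n_networks,
    paste(x$network_names, collapse = ", "), sum(x$labels == 0L)
  ))
  invisible(x)
}

#' Tidy per-network voxel counts for an atlas
#'
#' @param atlas A `network_atlas`.
#' @return A tibble with `network`, `label`, `n_voxels`.
#' @export
atlas_summary <- function(atlas) {
  stopifnot(inherits(atlas, "network_atlas"))
  tibble::tibble(
    network = atlas$network_names,
    label = seq_len(atlas$n_networks),
    n_voxels = vapply(
      seq_len(atlas$n_networks),
      function(k) sum(atlas$labels == k), integer(1)
    )
  )
}

#' Logical mask of one network, or of all networks ("grey matter")
#'
#' @param atlas A `network_atlas`.
#' @param network Network name or label; `NULL` (default) returns the union
#'   of all networks, the synthetic analogue of a grey-matter mask.
#' @return Logical 3D array.
#' @export
atlas_mask <- function(atlas, network = NULL) {
  if (is.null(network)) {
    atlas$labels > 0L
  } else if (is.character(network)) {
    k <- match(network, atlas$network_names)
    if (is.na(k)) abort_bh(sprintf("Unknown network '%s'.", network), "config_error")
    atlas$labels == k
  } else {
    atlas$labels == as.integer(network)
  }
}
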