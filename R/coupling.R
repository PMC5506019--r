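# Sliding-window dynamic FC and the brain-heart synchronization statistic.

#' Sliding-window functional connectivity
#'
#' Per-window Pearson correlation (Fisher z transformed) between a
#' reference series and one or many target series on a [window_grid()].
#' Windows in which either series is constant yield `NA` with a flag.
#'
#' @param ref Numeric reference series (seed or network time course).
#' @param target Numeric vector, matrix (time x targets), or `ts_img`.
#' @param grid A `window_grid`.
#' @return A tibble with `target`, `window`, `start_s`, `r`, `z`,
#'   `flagged`.
#' @export
sliding_fc <- function(ref, target, grid) {
  stopifnot(inherits(grid, "window_grid"))
  tmat <- if (inherits(target, "ts_img")) {
    t(as_voxel_matrix(target))
  } else if (is.matrix(target)) {
    target
  } else {
    matrix(target, ncol = 1)
  }
  if (nrow(tmat) != length(ref)) {
    abort_bh("Reference and target series have different lengths.", "data_error")
  }
  idx <- window_volume_index(grid, length(ref))
  nt <- ncol(tmat)
  out_r <- matrix(NA_real_, grid$n_windows, nt)
  for (w in seq_len(grid$n_windows)) {
    i <- idx[[w]]
    rs <- ref[i]
    if (stats::sd(rs) == 0) next
    out_r[w, ] <- cor_vs_matrix(rs, tmat[i, , drop = FALSE])
  }
  tibble::tibble(
    target = rep(seq_len(nt), each = grid$n_windows),
    window = rep(seq_len(grid$n_windows), nt),
    start_s = rep(grid$starts_s, nt),
    r = as.vector(out_r),
    z = fisher_z(as.vector(out_r)),
    flagged = is.na(as.vector(out_r))
  )
}

#' Brain-heart temporal synchronization
#'
#' Pearson correlation, across sliding windows, between windowed functional
#' connectivity and windowed heart rate - the per-subject strength of
#' FC-HR co-fluctuation. Windows flagged missing in either input are
#' dropped pairwise; fewer than 3 complete pairs, or zero-variance HR,
#' yields `NA` with a reason. Invariant to affine rescaling of either
#' series (bpm vs Hz, r vs z).
#'
#' @param wfc Windowed FC: tibble from [sliding_fc()] (column `z`), or a
#'   numeric vector of per-window values.
#' @param whr Windowed HR: tibble from [windowed_hr()] (column `hr_bpm`),
#'   or a numeric vector.
#' @return A tibble with `target`, `sync_r`, `n_windows`, `reason` (`NA`
#'   when the value is defined).
#' @export
fc_hr_sync <- function(wfc, whr) {
  hr <- if (is.data.frame(whr)) {
    v <- whr$hr_bpm
    v[whr$flagged & whr$n_beats == 0] <- NA_real_
    v
  } else {
    as.numeric(whr)
  }
  if (is.data.frame(wfc)) {
    targets <- split(wfc$z, wfc$target)
  } else {
    targets <- list(`1` = as.numeric(wfc))
  }
  res <- purrr::map_dfr(names(targets), function(tn) {
    z <- targets[[tn]]
    if (length(z) != length(hr)) {
      abort_bh("Windowed FC and HR are on different grids.", "data_error")
    }
    ok <- !is.na(z) & !is.na(hr)
    if (sum(ok) < 3) {
      return(tibble::tibble(
        target = tn, sync_r = NA_real_, n_windows = sum(ok),
        reason = "fewer than 3 complete windows"
      ))
    }
    if (stats::sd(hr[ok]) == 0) {
      return(tibble::tibble(
        target = tn, sync_r = NA_real_, n_windows = sum(ok),
        reason = "zero-variance heart rate"
      ))
    }
    if (stats::sd(z[ok]) == 0) {
      return(tibble::tibble(
        target = tn, sync_r = NA_real_, n_windows = sum(ok),
        reason = "zero-variance windowed FC"
      ))
    }
    tibble::tibble(
      target = tn, sync_r = stats::cor(z[ok], hr[ok]),
      n_windows = sum(ok), reason = NA_character_
    )
  })
  res
}

#' Group-level test of FC-HR synchronization
#'
#' Fisher-z transforms the per-subject synchronization correlations and
#' runs a one-sample t-test per target; edgewise families are corrected by
#' Benjamini-Hochberg FDR. (For voxelwise maps use [cluster_inference()]
#' with the sign-flip scheme on the z values instead.)
#'
#' @param subject_r Subjects x targets matrix (or data frame) of per-subject
#'   synchronization correlations; `NA`s are dropped per target.
#' @param q FDR level for edgewise correction (default 0.05).
#' @return A tibble with `target`, `n`, `mean_z`, `t`, `df`, `p`, `p_fdr`,
#'   `significant`.
#' @export
group_sync <- function(subject_r, q = 0.05) {
  x <- as.matrix(subject_r)
  if (is.null(colnames(x))) colnames(x) <- paste0("target", seq_len(ncol(x)))
  z <- fisher_z(x)
  res <- one_sample_t(z)
  if (sum(!is.na(res$p)) == 0) {
    abort_bh("No target has enough subjects for a group test.", "data_error")
  }
  fdr <- fdr_bh(res$p, q = q)
  res$p_fdr <- fdr$p_adjusted
  res$significant <- fdr$significant
  res$mean_z <- res$estimate
  out <- res[, c("target", "n", "mean_z", "t", "df", "p", "p_fdr", "significant")]
  class(out) <- c("bh_sync", class(out))
  out
}
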