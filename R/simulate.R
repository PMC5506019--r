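# Synthetic session and cohort generation.
#
# Voxel signal model: each network has a latent time course that is a sum of
# random-phase sinusoids confined to the 0.009-0.08 Hz band plus a small
# AR(1) jitter, standardized to unit variance. Latents for different
# networks are independent unless an injected effect correlates them (the
# target correlation matrix is realized through a Cholesky mixing of the
# independent latents). Every voxel of a network carries its network latent
# plus white noise; background voxels carry noise only; a smooth drift can
# be leaked into all voxels to exercise nuisance regression.

condition_levels <- c(
  "rest_baseline", "gratitude", "rest_post_gratitude",
  "resentment", "rest_post_resentment"
)

intervention_conditions <- c("gratitude", "resentment")

# One band-limited, unit-variance latent time course.
gen_latent <- function(n_vol, tr_s, band, n_sin, ar_frac, ar_phi) {
  t <- (seq_len(n_vol) - 1) * tr_s
  freqs <- stats::runif(n_sin, band[1], band[2])
  phases <- stats::runif(n_sin, 0, 2 * pi)
  x <- rowSums(vapply(
    seq_len(n_sin),
    function(i) sin(2 * pi * freqs[i] * t + phases[i]),
    numeric(n_vol)
  ))
  x <- x / stats::sd(x)
  if (ar_frac > 0) {
    e <- stats::rnorm(n_vol)
    j <- as.numeric(stats::filter(e, ar_phi, method = "recursive"))
    j <- j / stats::sd(j) * sqrt(ar_frac)
    x <- x + j
  }
  as.numeric(scale(x))
}

edge_index <- function(atlas, net_a, net_b) {
  a <- match(net_a, atlas$network_names)
  b <- match(net_b, atlas$network_names)
  if (anyNA(c(a, b))) {
    abort_bh(
      sprintf("Edge (%s, %s) names networks absent from the atlas.", net_a, net_b),
      "config_error"
    )
  }
  c(a, b)
}

# Target latent correlation matrix for one condition: base_r everywhere off
# the diagonal, plus additive deltas from fc_effects rows matching the
# condition and any extra per-subject edge offsets.
condition_cor_matrix <- function(atlas, spec, condition, extra_edges = NULL) {
  k <- atlas$n_networks
  R <- matrix(spec$base_r, k, k)
  diag(R) <- 1
  apply_edges <- function(R, edges) {
    if (is.null(edges) || nrow(edges) == 0) return(R)
    for (i in seq_len(nrow(edges))) {
      ab <- edge_index(atlas, edges$net_a[i], edges$net_b[i])
      v <- R[ab[1], ab[2]] + edges$delta_r[i]
      v <- pmin(pmax(v, -0.9), 0.9)
      R[ab[1], ab[2]] <- v
      R[ab[2], ab[1]] <- v
    }
    R
  }
  fc <- spec$fc_effects
  if (nrow(fc) > 0) {
    R <- apply_edges(R, fc[fc$condition == condition, , drop = FALSE])
  }
  R <- apply_edges(R, extra_edges)
  R
}

# Mean instantaneous HR per window from beat times (interval midpoints),
# mirroring the analysis-side windowed_hr().
windowed_mean_from_beats <- function(beat_ms, grid) {
  ibi <- diff(beat_ms)
  mid_s <- (beat_ms[-length(beat_ms)] + ibi / 2) / 1000
  hr <- 60000 / ibi
  vapply(seq_len(grid$n_windows), function(w) {
    inw <- mid_s >= grid$starts_s[w] & mid_s < grid$starts_s[w] + grid$window_s
    if (!any(inw)) NA_real_ else mean(hr[inw])
  }, numeric(1))
}

# Beat times (ms from session start) from a piecewise-constant rate on the
# 10 s bin grid (rate before the first bin / after the last is held flat).
beats_from_bins <- function(bins_bpm, bin_start_s, bin_len_s, dur_s) {
  t <- 0
  out <- numeric(ceiling(dur_s * max(bins_bpm) / 60) + 8L)
  k <- 0L
  repeat {
    b <- floor((t - bin_start_s) / bin_len_s) + 1
    b <- min(max(b, 1), length(bins_bpm))
    t <- t + 60 / bins_bpm[b]
    if (t >= dur_s) break
    k <- k + 1L
    out[k] <- t
  }
  out[seq_len(k)] * 1000
}

# Back-fill beat times whose windowed mean HR (beat-weighted, exactly as
# the analysis computes it) reproduces the target windows: minimum-norm
# deconvolution of the overlapping-window averaging, then a few damped
# fixed-point corrections against the realized windowed means. Bin rates
# are kept inside a plausible envelope around the session mean.
hr_bins_backfill <- function(hr_windows, mean_hr, grid, dur_s,
                             max_iter = 8L, tol_bpm = 0.05,
                             envelope_bpm = 20) {
  per_win <- as.integer(round(grid$window_s / grid$step_s))
  n_bins <- grid$n_windows + per_win - 1L
  B <- matrix(0, grid$n_windows, n_bins)
  for (w in seq_len(grid$n_windows)) B[w, w:(w + per_win - 1L)] <- 1 / per_win
  BtBi <- solve(tcrossprod(B))
  lo <- max(mean_hr - envelope_bpm, 35)
  hi <- min(mean_hr + envelope_bpm, 190)
  bins <- pmin(pmax(
    mean_hr + as.numeric(crossprod(B, BtBi %*% (hr_windows - mean_hr))),
    lo
  ), hi)
  beat_ms <- NULL
  for (i in seq_len(max_iter)) {
    beat_ms <- beats_from_bins(bins, grid$t0_s, grid$step_s, dur_s)
    realized <- windowed_mean_from_beats(beat_ms, grid)
    err <- hr_windows - realized
    err[is.na(err)] <- 0
    if (max(abs(err)) < tol_bpm) break
    bins <- pmin(pmax(
      bins + 0.8 * as.numeric(crossprod(B, BtBi %*% err)), lo
    ), hi)
  }
  beat_ms
}

# 50 Hz PPG waveform: one Gaussian pulse (100 ms FWHM) per beat.
ppg_from_beats <- function(beat_times_ms, dur_s, rate_hz, noise_sd) {
  n <- as.integer(floor(dur_s * rate_hz))
  tms <- (seq_len(n) - 1) / rate_hz * 1000
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  x <- numeric(n)
  half <- ceiling(4 * sigma / 1000 * rate_hz)
  for (tb in beat_times_ms) {
    c0 <- as.integer(round(tb / 1000 * rate_hz)) + 1L
    i <- max(1L, c0 - half):min(n, c0 + half)
    x[i] <- x[i] + exp(-((tms[i] - tb)^2) / (2 * sigma^2))
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  structure(
    list(samples = x, rate_hz = rate_hz, start_time_s = 0),
    class = "ppg_trace"
  )
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf(
    "<ppg_trace> %d samples at %g Hz (%.1f s), start offset %g s\n",
    length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz, x$start_time_s
  ))
  invisible(x)
}

#' Simulate one fMRI session (with PPG for interventions)
#'
#' Generates a session bundle: a 4D BOLD image on the atlas grid, a
#' six-column motion table, white-matter and CSF masks, and - for
#' intervention conditions - a 50 Hz PPG trace whose windowed heart rate is
#' coupled to the windowed connectivity of the designated network edge with
#' the target correlation `sync_rho` (exact by construction on the analysis
#' window grid). Ground truth (latent time courses, true windowed FC and
#' HR, beat times, session mean HR) is stored in `$truth` so recovery can
#' be verified without re-running the pipeline.
#'
#' @param atlas A `network_atlas`.
#' @param spec A `coupling_spec`.
#' @param condition One of `"rest_baseline"`, `"gratitude"`,
#'   `"rest_post_gratitude"`, `"resentment"`, `"rest_post_resentment"`.
#' @param n_volumes Volumes acquired (default 155; the first `n_discard`
#'   are later trimmed by preprocessing).
#' @param tr_s Repetition time in seconds (default 2).
#' @param seed Integer seed for this session.
#' @param hr_offset_bpm Additional subject-level HR offset (bpm).
#' @param extra_edges Optional data frame (`net_a`, `net_b`, `delta_r`) of
#'   subject-specific edge offsets for this session.
#' @param n_discard Volumes the downstream pipeline will trim; the coupling
#'   window grid is laid out on the retained part (default 5).
#' @return A `bh_session`: list with `img` (`ts_img`), `motion` (tibble),
#'   `masks` (list of logical 3D arrays `wm`, `csf`), `ppg` (or `NULL`),
#'   `condition`, and `truth`.
#' @export
simulate_session <- function(atlas, spec, condition,
                             n_volumes = 155L, tr_s = 2,
                             seed = spec$random_seed,
                             hr_offset_bpm = 0,
                             extra_edges = NULL,
                             n_discard = 5L) {
  stopifnot(inherits(atlas, "network_atlas"), inherits(spec, "coupling_spec"))
  condition <- match.arg(condition, condition_levels)
  is_intervention <- condition %in% intervention_conditions
  grid_kept <- window_grid(
    n_volumes - n_discard, tr_s,
    t0_s = n_discard * tr_s
  )
  if (is_intervention && !all(spec$sync_edge %in% atlas$network_names)) {
    abort_bh(
      sprintf(
        "sync_edge (%s) names networks absent from the atlas.",
        paste(spec$sync_edge, collapse = ", ")
      ),
      "config_error"
    )
  }
  with_seed(seed, {
    k <- atlas$n_networks
    raw <- vapply(
      seq_len(k),
      function(i) {
        gen_latent(
          n_volumes, tr_s, spec$band, spec$n_sinusoids,
          spec$ar_frac, spec$ar_phi
        )
      },
      numeric(n_volumes)
    )
    R <- condition_cor_matrix(atlas, spec, condition, extra_edges)
    latents <- raw %*% chol(R)

    # voxel data
    dims <- atlas$grid_shape
    v <- prod(dims)
    lab <- as.integer(atlas$labels)
    dat <- matrix(0, nrow = v, ncol = n_volumes)
    for (i in seq_len(k)) {
      m <- lab == i
      if (any(m)) dat[m, ] <- matrix(latents[, i], sum(m), n_volumes, byrow = TRUE)
    }
    drift <- as.numeric(scale(cumsum(stats::rnorm(n_volumes))))
    if (spec$motion_leak > 0) {
      dat <- dat + matrix(spec$motion_leak * drift, v, n_volumes, byrow = TRUE)
    }
    # distinct physiological fluctuations per tissue compartment (so the
    # white-matter and CSF confound columns are never collinear)
    bg <- which(lab == 0L)
    if (length(bg) < 2L) {
      abort_bh("Atlas leaves too few background voxels for tissue masks.", "capacity_error")
    }
    half <- length(bg) %/% 2L
    wm_idx <- bg[seq_len(half)]
    csf_idx <- bg[(half + 1L):length(bg)]
    dat[wm_idx, ] <- dat[wm_idx, ] + matrix(
      0.2 * as.numeric(scale(cumsum(stats::rnorm(n_volumes)))),
      length(wm_idx), n_volumes,
      byrow = TRUE
    )
    dat[csf_idx, ] <- dat[csf_idx, ] + matrix(
      0.2 * as.numeric(scale(cumsum(stats::rnorm(n_volumes)))),
      length(csf_idx), n_volumes,
      byrow = TRUE
    )
    if (spec$noise_sd > 0) {
      dat <- dat + matrix(stats::rnorm(v * n_volumes, sd = spec$noise_sd), v, n_volumes)
    }
    img <- ts_img(array(dat, dim = c(dims, n_volumes)), tr_s, atlas$affine)

    motion <- tibble::as_tibble(
      as.data.frame(vapply(
        1:6,
        function(i) 0.05 * as.numeric(scale(cumsum(stats::rnorm(n_volumes)))),
        numeric(n_volumes)
      ))
    )
    names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

    wm <- array(FALSE, dims); csf <- array(FALSE, dims)
    wm[wm_idx] <- TRUE
    csf[csf_idx] <- TRUE

    ppg <- NULL
    truth <- list(
      latents = latents, grid = grid_kept, condition = condition,
      cor_matrix = R
    )
    if (is_intervention) {
      kept <- (n_discard + 1L):n_volumes
      ab <- edge_index(atlas, spec$sync_edge[1], spec$sync_edge[2])
      wfc_r <- sliding_cor_series(latents[kept, ab[1]], latents[kept, ab[2]], grid_kept)
      wfc_z <- fisher_z(wfc_r)
      mean_hr <- spec$hr_baseline_bpm + hr_offset_bpm +
        (condition == spec$delta_condition) * spec$hr_condition_delta_bpm +
        stats::rnorm(1, sd = spec$hr_session_sd)
      # noise component generated on the 10 s bin grid and averaged through
      # the same 60 s windows, so the windowed-HR target has the temporal
      # smoothness that overlapping windows impose on any real rate curve
      per_win <- as.integer(round(grid_kept$window_s / grid_kept$step_s))
      e_bins <- stats::rnorm(grid_kept$n_windows + per_win - 1L)
      e <- vapply(
        seq_len(grid_kept$n_windows),
        function(w) mean(e_bins[w:(w + per_win - 1L)]),
        numeric(1)
      )
      couple <- condition %in% spec$sync_condition && spec$sync_rho != 0
      if (couple) {
        zs <- as.numeric(scale(wfc_z))
        ep <- stats::residuals(stats::lm(e ~ zs))
        ep <- as.numeric(scale(ep))
        dev <- spec$sync_rho * zs + sqrt(1 - spec$sync_rho^2) * ep
      } else {
        dev <- as.numeric(scale(e))
      }
      hr_target <- mean_hr + spec$hr_window_sd * dev
      beat_ms <- hr_bins_backfill(hr_target, mean_hr, grid_kept, n_volumes * tr_s)
      # ground truth = what the beats actually realize on the window grid
      hr_windows <- windowed_mean_from_beats(beat_ms, grid_kept)
      ppg <- ppg_from_beats(
        beat_ms, n_volumes * tr_s, spec$ppg_rate_hz, spec$ppg_noise
      )
      truth$wfc_z <- wfc_z
      truth$hr_windows <- hr_windows
      truth$beat_times_ms <- beat_ms
      truth$session_mean_hr <- mean_hr
    }

    structure(
      list(
        img = img, motion = motion, masks = list(wm = wm, csf = csf),
        ppg = ppg, condition = condition, truth = truth, seed = seed
      ),
      class = "bh_session"
    )
  })
}

#' @export
print.bh_session <- function(x, ...) {
  cat(sprintf(
    "<bh_session> condition '%s', %d volumes, PPG: %s\n",
    x$condition, n_volumes(x$img), if (is.null(x$ppg)) "none" else "50 Hz"
  ))
  invisible(x)
}

#' Simulate a counterbalanced cohort
#'
#' Builds `n_subjects` five-session bundles in the study's counterbalanced
#' order: odd-numbered subjects receive the gratitude intervention first
#' (set I), even-numbered subjects the resentment intervention first
#' (set II). Behavioural scores are drawn from the `behavior_base`
#' distributions; any `behavior_effects` rows make the named edge's
#' connectivity depend linearly on the subject's score in the named
#' condition.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param spec A `coupling_spec`.
#' @param atlas A `network_atlas` (default: the 16 x 16 x 8 five-network
#'   atlas).
#' @param seed Master seed; per-subject and per-session seeds are derived
#'   deterministically from it.
#' @param n_volumes,tr_s Session geometry (defaults 155 volumes, TR 2 s).
#' @return A `bh_cohort`: list with `subjects` (list of per-subject bundles,
#'   each holding `subject_id`, `order_set`, `sessions` - a named list of
#'   five `bh_session`s in acquisition order - and `truth`), `behaviors`
#'   (tibble), `atlas`, `spec`, `seed`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(2, coupling_spec(), seed = 7)
#' coh$behaviors
#' }
#' @export
simulate_cohort <- function(n_subjects, spec = coupling_spec(),
                            atlas = make_network_atlas(c(16, 16, 8), 5),
                            seed = spec$random_seed,
                            n_volumes = 155L, tr_s = 2) {
  if (n_subjects < 2) abort_bh("`n_subjects` must be at least 2.", "config_error")
  bb <- spec$behavior_base
  behaviors <- with_seed(derive_seed(seed, 0L), {
    out <- tibble::tibble(subject = seq_len(n_subjects))
    for (i in seq_len(nrow(bb))) {
      x <- stats::rnorm(n_subjects, bb$mean[i], bb$sd[i])
      if (bb$integer[i]) x <- pmin(pmax(round(x), 0), 21)
      out[[bb$score[i]]] <- x
    }
    out
  })
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    order_set <- if (s %% 2L == 1L) "I" else "II"
    conds <- if (order_set == "I") {
      c(
        "rest_baseline", "gratitude", "rest_post_gratitude",
        "resentment", "rest_post_resentment"
      )
    } else {
      c(
        "rest_baseline", "resentment", "rest_post_resentment",
        "gratitude", "rest_post_gratitude"
      )
    }
    hr_offset <- with_seed(
      derive_seed(seed, 10000L + s),
      stats::rnorm(1, 0, spec$hr_subject_sd)
    )
    sessions <- vector("list", 5L)
    names(sessions) <- conds
    for (j in seq_along(conds)) {
      be <- spec$behavior_effects
      extra <- NULL
      if (nrow(be) > 0) {
        rows <- be[be$condition == conds[j], , drop = FALSE]
        if (nrow(rows) > 0) {
          extra <- tibble::tibble(
            net_a = rows$net_a, net_b = rows$net_b,
            delta_r = vapply(seq_len(nrow(rows)), function(i) {
              sc <- behaviors[[rows$score[i]]][s]
              mu <- bb$mean[match(rows$score[i], bb$score)]
              rows$slope[i] * (sc - mu)
            }, numeric(1))
          )
        }
      }
      sessions[[j]] <- simulate_session(
        atlas, spec, conds[j],
        n_volumes = n_volumes, tr_s = tr_s,
        seed = derive_seed(seed, s * 100L + j),
        hr_offset_bpm = hr_offset, extra_edges = extra
      )
    }
    subjects[[s]] <- list(
      subject_id = sprintf("sub-%02d", s), order_set = order_set,
      sessions = sessions,
      truth = list(hr_offset_bpm = hr_offset)
    )
  }
  structure(
    list(
      subjects = subjects, behaviors = behaviors, atlas = atlas,
      spec = spec, seed = as.integer(seed)
    ),
    class = "bh_cohort"
  )
}

#' @export
print.bh_cohort <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf(
    "<bh_cohort> %d subjects (%d set I / %d set II), %d sessions each, grid %s\n",
    n, sum(vapply(x$subjects, function(s) s$order_set == "I", logical(1))),
    sum(vapply(x$subjects, function(s) s$order_set == "II", logical(1))),
    5L, paste(x$atlas$grid_shape, collapse = "x")
  ))
  invisible(x)
}
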