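# End-to-end orchestration: synth -> physio/preprocess -> seedfc/gica ->
# coupling -> stats, from a single config.

#' Default pipeline configuration
#'
#' @param n_subjects Cohort size.
#' @param grid_shape Atlas grid (default 16 x 16 x 8, five networks).
#' @param n_networks Number of ground-truth networks.
#' @param spec A [coupling_spec()].
#' @param master_seed Master seed; every stochastic stage draws a seed
#'   derived from it.
#' @param n_volumes,tr_s Session geometry.
#' @param n_discard Leading volumes trimmed per session.
#' @param fwhm_mm Spatial smoothing FWHM (0 = none).
#' @param band Band-pass edges in Hz.
#' @param roi_radius_mm Seed sphere radius (mm).
#' @param window_s,step_s Sliding-window length and step (s).
#' @param n_pcs,n_ics First-level and group ICA dimensions.
#' @param cdt_fc,cdt_sync Cluster-defining thresholds (uncorrected p) for
#'   FC contrasts and for synchronization/regression maps.
#' @param fwe_alpha Cluster-level FWE level.
#' @param fdr_q,fdr_q_exploratory Edgewise FDR levels (primary and
#'   exploratory).
#' @param n_perm Permutations for cluster inference.
#' @param sync_seeds Seed ROIs used for voxelwise synchronization maps.
#' @return A named list of class `bh_config`.
#' @export
pipeline_config <- function(n_subjects = 8L,
                            grid_shape = c(16L, 16L, 8L),
                            n_networks = 5L,
                            spec = coupling_spec(),
                            master_seed = 1L,
                            n_volumes = 155L, tr_s = 2,
                            n_discard = 5L, fwhm_mm = 0,
                            band = c(0.009, 0.08),
                            roi_radius_mm = 6,
                            window_s = 60, step_s = 10,
                            n_pcs = 30L, n_ics = 20L,
                            cdt_fc = 0.001, cdt_sync = 0.005,
                            fwe_alpha = 0.05,
                            fdr_q = 0.05, fdr_q_exploratory = 0.10,
                            n_perm = 99L,
                            sync_seeds = c("vmpfc", "amyg_l", "nacc_l")) {
  cfg <- as.list(environment())
  stopifnot(
    cdt_fc > 0, cdt_fc < 1, cdt_sync > 0, cdt_sync < 1,
    fwe_alpha > 0, fwe_alpha < 1, fdr_q > 0, fdr_q < 1,
    n_pcs > 0, n_ics > 0
  )
  class(cfg) <- "bh_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the whole study graph from one config: cohort simulation,
#' heart-rate extraction from PPG (session means, per-window paired tests,
#' windowed HR), temporal preprocessing, seed-based Fisher-z maps with
#' paired contrasts under permutation cluster-level FWE, group ICA with
#' dual regression and template matching, inter-network FC matrices per
#' session with paired-t and repeated-measures ANOVA (FDR-corrected, with
#' Bonferroni post-hocs), sliding-window FC-HR synchronization (edge level
#' with FDR; voxel level per seed with cluster-level FWE), and behavioural
#' regressions on connectivity. Deterministic for a fixed `master_seed`.
#'
#' @param config A [pipeline_config()].
#' @return A `bh_results` list: `hr` (session means, paired test, window
#'   table), `seedfc` (z maps and cluster tables), `networks` (edge tables,
#'   paired/RM-ANOVA/post-hoc results, template matching), `sync` (edge and
#'   voxel results), `behavior` (edge correlations and voxel regressions),
#'   and `manifest` (config snapshot, seeds, stage timings).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "bh_config"))
  t_start <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- local({
    last <- t_start
    function(stage) {
      now <- proc.time()[["elapsed"]]
      timings[[stage]] <<- round(now - last, 2)
      last <<- now
    }
  })

  atlas <- make_network_atlas(config$grid_shape, config$n_networks,
                              seed = derive_seed(config$master_seed, 1L))
  cohort <- simulate_cohort(
    config$n_subjects, config$spec, atlas,
    seed = derive_seed(config$master_seed, 2L),
    n_volumes = config$n_volumes, tr_s = config$tr_s
  )
  tick("synth")

  n_kept <- config$n_volumes - config$n_discard
  grid <- window_grid(
    n_kept, config$tr_s, config$window_s, config$step_s,
    t0_s = config$n_discard * config$tr_s
  )

  ## ---- physio ----
  hr_rows <- list(); hrw_rows <- list()
  for (sub in cohort$subjects) {
    for (cond in intervention_conditions) {
      ses <- sub$sessions[[cond]]
      res <- ppg_to_hr(ses$ppg, grid)
      hr_rows[[length(hr_rows) + 1L]] <- tibble::tibble(
        subject = sub$subject_id, condition = cond, mean_hr_bpm = res$mean_bpm
      )
      hrw_rows[[length(hrw_rows) + 1L]] <- dplyr::mutate(
        res$windows, subject = sub$subject_id, condition = cond
      )
    }
  }
  hr_means <- dplyr::bind_rows(hr_rows)
  hr_windows <- dplyr::bind_rows(hrw_rows)
  wide <- tidyr::pivot_wider(
    hr_means, names_from = "condition", values_from = "mean_hr_bpm"
  )
  hr_test <- paired_t(
    matrix(wide$gratitude, ncol = 1), matrix(wide$resentment, ncol = 1)
  )
  # per-window paired tests, reported uncorrected at the two conventional
  # thresholds
  hw <- tidyr::pivot_wider(
    hr_windows[, c("subject", "condition", "window", "hr_bpm")],
    names_from = "condition", values_from = "hr_bpm"
  )
  by_win <- dplyr::group_by(hw, .data$window)
  hr_window_tests <- dplyr::summarise(
    by_win,
    t = one_sample_t(matrix(.data$gratitude - .data$resentment, ncol = 1))$t,
    p = one_sample_t(matrix(.data$gratitude - .data$resentment, ncol = 1))$p,
    .groups = "drop"
  )
  hr_window_tests$sig_05 <- hr_window_tests$p < 0.05
  hr_window_tests$sig_005 <- hr_window_tests$p < 0.005
  tick("physio")

  ## ---- preprocess ----
  pre <- lapply(cohort$subjects, function(sub) {
    lapply(sub$sessions, preprocess_session,
      n_discard = config$n_discard, fwhm_mm = config$fwhm_mm,
      low_hz = config$band[1], high_hz = config$band[2]
    )
  })
  tick("preprocess")

  ## ---- seed-based FC ----
  gm_mask <- atlas_mask(atlas)
  mask_idx <- which(gm_mask)
  rois <- lapply(names(atlas$seed_points), function(nm) {
    vox <- atlas$seed_points[[nm]]
    ctr <- (atlas$affine %*% c(vox - 1, 1))[1:3]
    make_sphere_roi(ctr, config$roi_radius_mm, atlas$grid_shape, atlas$affine, nm)
  })
  names(rois) <- names(atlas$seed_points)
  zmaps <- lapply(rois, function(roi) {
    lapply(seq_along(cohort$subjects), function(s) {
      sapply(condition_levels, function(cond) {
        seed_zmap(pre[[s]][[cond]], roi, gm_mask)$z
      })
    })
  })
  seed_contrasts <- list()
  for (nm in names(rois)) {
    a <- t(sapply(zmaps[[nm]], function(m) m[, "gratitude"]))
    b <- t(sapply(zmaps[[nm]], function(m) m[, "resentment"]))
    a[is.na(a)] <- 0; b[is.na(b)] <- 0
    seed_contrasts[[nm]] <- cluster_inference(
      a, atlas$grid_shape,
      scheme = "condition_swap", data_b = b, mask_idx = mask_idx,
      cdt_p = config$cdt_fc, alpha = config$fwe_alpha,
      n_perm = config$n_perm, seed = derive_seed(config$master_seed, 3L),
      affine = atlas$affine
    )
  }
  tick("seedfc")

  ## ---- group ICA ----
  gica <- run_group_ica(
    pre, n_pcs = config$n_pcs, n_ics = config$n_ics,
    seed = derive_seed(config$master_seed, 4L)
  )
  templates <- do.call(rbind, lapply(seq_len(atlas$n_networks), function(k) {
    as.numeric(atlas$labels == k)
  }))
  rownames(templates) <- atlas$network_names
  matched <- match_templates(gica$group_maps, templates)
  net_edges <- list()
  for (s in seq_along(cohort$subjects)) {
    for (cond in condition_levels) {
      tc <- gica$dual[[s]]$session_timecourses[[cond]][, matched$component, drop = FALSE]
      tc <- sweep(tc, 2, sign(matched$correlation), `*`)
      colnames(tc) <- matched$template
      fc <- internetwork_fc(tc, session_label = cond)
      net_edges[[length(net_edges) + 1L]] <- dplyr::mutate(
        fc$edges, subject = cohort$subjects[[s]]$subject_id, condition = cond
      )
    }
  }
  net_edges <- dplyr::bind_rows(net_edges)
  edge_mat <- function(cond) {
    d <- net_edges[net_edges$condition == cond, ]
    d$edge <- paste(d$net_a, d$net_b, sep = "~")
    m <- tidyr::pivot_wider(
      d[, c("subject", "edge", "z")], names_from = "edge", values_from = "z"
    )
    as.matrix(m[, -1])
  }
  eg <- edge_mat("gratitude"); er <- edge_mat("resentment")
  edge_paired <- paired_t(eg, er)
  edge_paired <- dplyr::mutate(
    edge_paired,
    p_fdr = fdr_bh(.data$p, config$fdr_q)$p_adjusted,
    significant = fdr_bh(.data$p, config$fdr_q)$significant
  )
  rests <- c("rest_baseline", "rest_post_gratitude", "rest_post_resentment")
  rest_arr <- array(
    NA_real_,
    c(config$n_subjects, 3L, ncol(eg)),
    dimnames = list(NULL, rests, colnames(eg))
  )
  for (j in seq_along(rests)) rest_arr[, j, ] <- edge_mat(rests[j])
  edge_rm <- rm_anova(rest_arr)
  edge_rm <- dplyr::mutate(
    edge_rm,
    p_fdr = fdr_bh(.data$p, config$fdr_q)$p_adjusted,
    significant = fdr_bh(.data$p, config$fdr_q)$significant
  )
  edge_posthoc <- posthoc_pairwise(rest_arr, targets = which(edge_rm$significant))
  tick("gica")

  ## ---- coupling ----
  sync_edge_rows <- list()
  sync_vox <- list()
  for (cond in intervention_conditions) {
    subj_r <- NULL
    for (s in seq_along(cohort$subjects)) {
      tc <- gica$dual[[s]]$session_timecourses[[cond]][, matched$component, drop = FALSE]
      colnames(tc) <- matched$template
      whr <- hr_windows[
        hr_windows$subject == cohort$subjects[[s]]$subject_id &
          hr_windows$condition == cond,
      ]
      pairs <- utils::combn(matched$template, 2)
      rr <- vapply(seq_len(ncol(pairs)), function(j) {
        wz <- sliding_fc(tc[, pairs[1, j]], tc[, pairs[2, j]], grid)
        fc_hr_sync(wz, whr)$sync_r
      }, numeric(1))
      names(rr) <- paste(pairs[1, ], pairs[2, ], sep = "~")
      subj_r <- rbind(subj_r, rr)
    }
    gs <- group_sync(subj_r, q = config$fdr_q)
    sync_edge_rows[[cond]] <- dplyr::mutate(gs, condition = cond)

    vox_sync <- matrix(
      NA_real_, length(cohort$subjects), length(mask_idx)
    )
    for (nm in config$sync_seeds) {
      for (s in seq_along(cohort$subjects)) {
        img <- pre[[s]][[cond]]
        seed_series <- roi_timeseries(img, rois[[nm]])
        wz <- sliding_fc(
          seed_series, t(as_voxel_matrix(img))[, mask_idx, drop = FALSE], grid
        )
        whr <- hr_windows[
          hr_windows$subject == cohort$subjects[[s]]$subject_id &
            hr_windows$condition == cond,
        ]
        vox_sync[s, ] <- fc_hr_sync(wz, whr)$sync_r
      }
      zz <- fisher_z(vox_sync)
      zz[is.na(zz)] <- 0
      sync_vox[[paste(nm, cond, sep = ".")]] <- cluster_inference(
        zz, atlas$grid_shape,
        scheme = "sign_flip", mask_idx = mask_idx,
        cdt_p = config$cdt_sync, alpha = config$fwe_alpha,
        n_perm = config$n_perm, seed = derive_seed(config$master_seed, 5L),
        affine = atlas$affine
      )
    }
  }
  sync_edges <- dplyr::bind_rows(sync_edge_rows)
  tick("coupling")

  ## ---- behaviour ----
  beh <- cohort$behaviors
  seed_scores <- list(
    amyg_l = c("hads_anxiety", "hads_depression"),
    amyg_r = c("hads_anxiety", "hads_depression"),
    nacc_l = c("sdt_autonomy", "sdt_competence", "sdt_relatedness"),
    nacc_r = c("sdt_autonomy", "sdt_competence", "sdt_relatedness")
  )
  behavior_vox <- list()
  for (nm in names(seed_scores)) {
    for (cond in c("rest_post_gratitude", "rest_post_resentment")) {
      m <- t(sapply(zmaps[[nm]], function(mm) mm[, cond]))
      m[is.na(m)] <- 0
      for (sc in seed_scores[[nm]]) {
        behavior_vox[[paste(nm, cond, sc, sep = ".")]] <- cluster_inference(
          m, atlas$grid_shape,
          scheme = "score_permute", score = beh[[sc]], mask_idx = mask_idx,
          cdt_p = config$cdt_sync, alpha = config$fwe_alpha,
          n_perm = config$n_perm, seed = derive_seed(config$master_seed, 6L),
          affine = atlas$affine
        )
      }
    }
  }
  # edge-level behaviour correlations
  behavior_edges <- list()
  for (cond in c("rest_post_gratitude", "rest_post_resentment")) {
    em <- edge_mat(cond)
    for (sc in setdiff(names(beh), "subject")) {
      r <- suppressWarnings(stats::cor(beh[[sc]], em))
      n <- nrow(em)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      behavior_edges[[length(behavior_edges) + 1L]] <- tibble::tibble(
        condition = cond, score = sc, edge = colnames(em),
        r = as.numeric(r), t = as.numeric(tt), df = n - 2,
        p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
      )
    }
  }
  behavior_edges <- dplyr::bind_rows(behavior_edges)
  tick("behavior")

  manifest <- list(
    package_version = as.character(utils::packageVersion("brainheart")),
    master_seed = config$master_seed,
    derived_seeds = list(
      atlas = derive_seed(config$master_seed, 1L),
      cohort = derive_seed(config$master_seed, 2L),
      seedfc_perm = derive_seed(config$master_seed, 3L),
      ica = derive_seed(config$master_seed, 4L),
      sync_perm = derive_seed(config$master_seed, 5L),
      behavior_perm = derive_seed(config$master_seed, 6L)
    ),
    config = config[setdiff(names(config), "spec")],
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t_start, 2)
  )
  structure(
    list(
      atlas = atlas, grid = grid,
      hr = list(
        means = hr_means, paired_test = hr_test,
        window_tests = hr_window_tests, windows = hr_windows
      ),
      seedfc = list(rois = rois, contrasts = seed_contrasts),
      networks = list(
        matched = matched, edges = net_edges, paired = edge_paired,
        rm_anova = edge_rm, posthoc = edge_posthoc,
        variance_explained = vapply(
          gica$subject_pcs, `[[`, numeric(1), "variance_explained"
        )
      ),
      sync = list(edges = sync_edges, voxel = sync_vox),
      behavior = list(voxel = behavior_vox, edges = behavior_edges),
      manifest = manifest
    ),
    class = "bh_results"
  )
}

#' @export
print.bh_results <- function(x, ...) {
  cat("<bh_results>\n")
  cat(sprintf("  subjects: %d\n", x$manifest$config$n_subjects))
  cat(sprintf("  total runtime: %.1f s\n", x$manifest$total_s))
  cat(sprintf(
    "  HR gratitude vs resentment: t = %.2f (df %d), p = %.3g\n",
    x$hr$paired_test$t, x$hr$paired_test$df, x$hr$paired_test$p
  ))
  cat(sprintf(
    "  network edges FDR-significant (paired): %d of %d\n",
    sum(x$networks$paired$significant), nrow(x$networks$paired)
  ))
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Formats cluster tables the conventional way (peak coordinate in mm,
#' cluster extent, peak statistic, corrected p; a single "not significant"
#' row when a contrast yields nothing), the per-window HR test table, and
#' the inter-network FC summary.
#'
#' @param results A `bh_results` from [run_pipeline()].
#' @return A list of tibbles: `seed_clusters`, `sync_clusters`,
#'   `behavior_clusters`, `hr_windows`, `network_edges`.
#' @export
report <- function(results) {
  stopifnot(inherits(results, "bh_results"))
  fmt_cluster_set <- function(lst) {
    purrr::map_dfr(names(lst), function(nm) {
      ct <- lst[[nm]]
      sig <- ct[!is.na(ct$p_fwe) & ct$significant, , drop = FALSE]
      if (nrow(sig) == 0) {
        return(tibble::tibble(
          analysis = nm, result = "not significant",
          peak_x = NA_real_, peak_y = NA_real_, peak_z = NA_real_,
          n_voxels = NA_integer_, peak_stat = NA_real_, p_fwe = NA_real_
        ))
      }
      tibble::tibble(
        analysis = nm, result = "cluster",
        peak_x = sig$peak_x, peak_y = sig$peak_y, peak_z = sig$peak_z,
        n_voxels = sig$n_voxels, peak_stat = sig$peak_stat, p_fwe = sig$p_fwe
      )
    })
  }
  list(
    seed_clusters = fmt_cluster_set(results$seedfc$contrasts),
    sync_clusters = fmt_cluster_set(results$sync$voxel),
    behavior_clusters = fmt_cluster_set(results$behavior$voxel),
    hr_windows = results$hr$window_tests,
    network_edges = dplyr::arrange(results$networks$paired, .data$p)
  )
}
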