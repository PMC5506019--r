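test_that("voxels of the same network are perfectly correlated at zero noise", {
  atl <- tiny_atlas()
  spec <- coupling_spec(noise_sd = 0, motion_leak = 0)
  ses <- simulate_session(atl, spec, "rest_baseline", seed = 3)
  vox <- which(atl$labels == 1L)[1:2]
  m <- matrix(ses$img$data, prod(atl$grid_shape))
  expect_equal(cor(m[vox[1], ], m[vox[2], ]), 1, tolerance = 1e-12)
})

test_that("latent network dynamics are band-limited to 0.009-0.08 Hz", {
  atl <- tiny_atlas()
  ses <- simulate_session(atl, coupling_spec(), "rest_baseline", seed = 5)
  for (k in 1:3) {
    sp <- stats::spec.pgram(
      stats::ts(ses$truth$latents[, k], deltat = 2),
      plot = FALSE, taper = 0, detrend = FALSE
    )
    frac <- sum(sp$spec[sp$freq >= 0.009 & sp$freq <= 0.08]) / sum(sp$spec)
    expect_gte(frac, 0.9)
  }
})

test_that("sessions are deterministic given the seed", {
  atl <- tiny_atlas()
  spec <- coupling_spec()
  a <- simulate_session(atl, spec, "gratitude", seed = 7)
  b <- simulate_session(atl, spec, "gratitude", seed = 7)
  expect_identical(a$img$data, b$img$data)
  expect_identical(a$ppg$samples, b$ppg$samples)
  expect_identical(a$motion, b$motion)
})

test_that("strong coupling is realized on the window grid before any noise", {
  atl <- tiny_atlas()
  spec <- coupling_spec(sync_rho = 0.9, noise_sd = 0, ppg_noise = 0)
  ses <- simulate_session(atl, spec, "gratitude", seed = spec$random_seed)
  expect_gte(cor(ses$truth$wfc_z, ses$truth$hr_windows), 0.85)
})

test_that("injected heart-rate means are realized within 1 bpm", {
  atl <- tiny_atlas()
  spec <- coupling_spec(
    hr_baseline_bpm = 70, hr_condition_delta_bpm = -3,
    hr_session_sd = 0, ppg_noise = 0
  )
  for (s in 1:3) {
    ses <- simulate_session(atl, spec, "gratitude", seed = s)
    hr <- beats_to_hr(detect_beats(ses$ppg))
    expect_equal(session_mean_hr(hr), 67, tolerance = 1)
    # resentment keeps the baseline mean
    sr <- simulate_session(atl, spec, "resentment", seed = s + 50)
    expect_equal(
      session_mean_hr(beats_to_hr(detect_beats(sr$ppg))), 70,
      tolerance = 1
    )
  }
})

test_that("coupling requested on networks absent from the atlas errors", {
  atl <- tiny_atlas()
  spec <- coupling_spec(sync_edge = c("temporolimbic", "nonexistent"))
  expect_error(
    simulate_session(atl, spec, "gratitude"),
    class = "brainheart_config_error"
  )
})

test_that("cohorts counterbalance the intervention order and inventory", {
  atl <- tiny_atlas()
  coh <- simulate_cohort(8, coupling_spec(), atl, seed = 2)
  orders <- vapply(coh$subjects, function(s) s$order_set, character(1))
  expect_equal(sum(orders == "I"), 4L)
  expect_equal(sum(orders == "II"), 4L)
  expect_equal(length(coh$subjects) * 5L, 40L)
  for (sub in coh$subjects) {
    expect_length(sub$sessions, 5L)
    ppg_present <- !vapply(sub$sessions, function(x) is.null(x$ppg), logical(1))
    expect_equal(sum(ppg_present), 2L)
    expect_setequal(
      names(sub$sessions)[ppg_present], c("gratitude", "resentment")
    )
    for (ses in sub$sessions) expect_equal(dim(ses$img)[4], 155L)
  }
})

test_that("a zero behaviour slope leaves scores uncorrelated with the edge", {
  # Monte-Carlo null of the generator itself: with slope 0, the sample
  # correlation between scores and the target edge z (computed from the
  # generated latents, the brute-force path) stays within null bounds.
  atl <- tiny_atlas()
  spec <- coupling_spec(
    behavior_effects = tibble::tibble(
      score = "sdt_autonomy", condition = "rest_post_gratitude",
      net_a = "dmn", net_b = "fp_right", slope = 0
    ),
    fc_effects = tibble::tibble(
      condition = character(), net_a = character(), net_b = character(),
      delta_r = numeric()
    )
  )
  n_rep <- 20L
  rs <- vapply(seq_len(n_rep), function(rep) {
    coh <- simulate_cohort(32, spec, atl, seed = 1000 + rep)
    z <- vapply(coh$subjects, function(sub) {
      lat <- sub$sessions[["rest_post_gratitude"]]$truth$latents
      fisher_z(cor(lat[, 1], lat[, 5]))
    }, numeric(1))
    cor(coh$behaviors$sdt_autonomy, z)
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.35), 0.9)
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("a non-zero behaviour slope is recovered by covariate regression", {
  atl <- tiny_atlas()
  spec <- coupling_spec(
    behavior_base = tibble::tibble(
      score = "sdt_autonomy", mean = 5, sd = 0.4, integer = FALSE
    ),
    behavior_effects = tibble::tibble(
      score = "sdt_autonomy", condition = "rest_post_gratitude",
      net_a = "dmn", net_b = "fp_right", slope = 0.5
    ),
    fc_effects = tibble::tibble(
      condition = character(), net_a = character(), net_b = character(),
      delta_r = numeric()
    )
  )
  coh <- simulate_cohort(32, spec, atl, seed = 41)
  z <- vapply(coh$subjects, function(sub) {
    lat <- sub$sessions[["rest_post_gratitude"]]$truth$latents
    fisher_z(cor(lat[, 1], lat[, 5]))
  }, numeric(1))
  fit <- regress_covariate(matrix(z, ncol = 1), coh$behaviors$sdt_autonomy)
  expect_equal(fit$slope, 0.5, tolerance = 0.2)
})
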