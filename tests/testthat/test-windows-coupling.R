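test_that("window counts follow the floor formula and match brute force", {
  expect_equal(window_grid(150, 2, 60, 10)$n_windows, 25L)
  expect_equal(window_grid(150, 2, 300, 10)$n_windows, 1L)
  expect_equal(window_grid(150, 2, 60, 60)$n_windows, 5L)
  # brute-force enumeration of valid placements over a parameter sweep
  for (nv in c(40, 150, 155)) {
    for (win in c(30, 60, 100)) {
      for (st in c(5, 10, 30)) {
        dur <- nv * 2
        if (win > dur) next # precondition: session holds at least one window
        brute <- sum((seq(0, dur, by = st) + win) <= dur + 1e-9)
        expect_equal(window_grid(nv, 2, win, st)$n_windows, brute)
      }
    }
  }
  expect_error(window_grid(10, 2, 60, 10), class = "brainheart_config_error")
  expect_error(window_grid(150, 2, 60, 0), class = "brainheart_config_error")
})

test_that("each window holds exactly window_s / tr_s volumes", {
  grid <- window_grid(150, 2, 60, 10, t0_s = 10)
  idx <- brainheart:::window_volume_index(grid, 150)
  expect_true(all(vapply(idx, length, integer(1)) == 30L))
  expect_equal(idx[[1]], 1:30)
  expect_equal(idx[[25]], 121:150)
})

test_that("sliding FC tracks identical, switching and generated series", {
  grid <- window_grid(150, 2, 60, 10)
  x <- rnorm(150)
  same <- sliding_fc(x, x, grid)
  expect_true(all(same$z == fisher_z(1)))
  # identical first half, independent second half -> z drops
  set.seed(20)
  y <- x
  y[76:150] <- rnorm(75)
  sw <- sliding_fc(x, y, grid)
  expect_lt(sw$z[25], sw$z[1])
  expect_equal(sw$z[1], fisher_z(1))
  # generator truth: windowed z of the designated edge from raw latents
  atl <- tiny_atlas()
  ses <- simulate_session(
    atl, coupling_spec(noise_sd = 0, motion_leak = 0), "gratitude",
    seed = 23
  )
  kept <- 6:155
  wz <- sliding_fc(
    ses$truth$latents[kept, 2], ses$truth$latents[kept, 3], ses$truth$grid
  )
  expect_lt(mean(abs(wz$z - ses$truth$wfc_z)), 0.15)
})

test_that("constant in-window series are flagged per window, not fatal", {
  grid <- window_grid(150, 2, 60, 10)
  x <- rnorm(150)
  y <- x
  y[1:30] <- 7 # first window constant
  out <- sliding_fc(y, x, grid)
  expect_true(out$flagged[1])
  expect_true(is.na(out$z[1]))
  expect_false(any(out$flagged[-1]))
})

test_that("FC-HR synchronization handles exact, missing and degenerate input", {
  grid <- window_grid(150, 2, 60, 10)
  set.seed(30)
  z <- rnorm(25)
  expect_equal(fc_hr_sync(z, 70 + 2 * z)$sync_r, 1, tolerance = 1e-12)
  cst <- fc_hr_sync(z, rep(70, 25))
  expect_true(is.na(cst$sync_r))
  expect_match(cst$reason, "zero-variance heart rate")
  few <- fc_hr_sync(c(1, 2, NA, NA), c(1, NA, 3, 4))
  expect_true(is.na(few$sync_r))
  expect_match(few$reason, "fewer than 3")
  # invariance to affine rescaling of either series
  hr <- 70 + 2 * rnorm(25)
  expect_equal(
    fc_hr_sync(z, hr)$sync_r,
    fc_hr_sync(10 * z + 3, hr / 60)$sync_r,
    tolerance = 1e-12
  )
  # dropping a few windows changes r continuously (pairwise deletion)
  full <- fc_hr_sync(z, hr)$sync_r
  z2 <- z; z2[c(3, 11)] <- NA
  dropped <- fc_hr_sync(z2, hr)$sync_r
  expect_equal(dropped, cor(z[-c(3, 11)], hr[-c(3, 11)]), tolerance = 1e-12)
  expect_lt(abs(dropped - full), 0.3)
})

test_that("group synchronization tests edges with FDR control", {
  set.seed(31)
  r <- matrix(rnorm(29 * 10, sd = 0.1), 29, 10)
  r[, 4] <- r[, 4] + 0.5
  colnames(r) <- paste0("e", 1:10)
  gs <- group_sync(r, q = 0.05)
  expect_true(gs$significant[gs$target == "e4"])
  expect_equal(sum(gs$significant), 1L)
  expect_equal(gs$df, rep(28L, 10))
  # symmetric-about-zero input gives t = 0
  sym <- matrix(rep(c(-0.2, 0.2), each = 2), 4, 1)
  colnames(sym) <- "e"
  expect_equal(group_sync(sym)$t, 0, ignore_attr = TRUE)
})

test_that("per-subject sync recovers the generator coupling end to end", {
  atl <- tiny_atlas()
  spec <- coupling_spec(sync_rho = 0.6)
  rs <- vapply(1:6, function(s) {
    ses <- simulate_session(atl, spec, "gratitude", seed = 400 + s)
    img <- preprocess_session(ses)
    n1 <- roi_timeseries(img, atlas_mask(atl, spec$sync_edge[1]))
    n2 <- roi_timeseries(img, atlas_mask(atl, spec$sync_edge[2]))
    wz <- sliding_fc(n1, n2, ses$truth$grid)
    whr <- windowed_hr(beats_to_hr(detect_beats(ses$ppg)), ses$truth$grid)
    fc_hr_sync(wz, whr)$sync_r
  }, numeric(1))
  expect_gt(mean(rs), 0.3)
  expect_true(all(rs > 0))
})
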