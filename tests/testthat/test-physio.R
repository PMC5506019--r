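test_that("beats at exactly 1000 ms spacing are detected within one sample", {
  truth_ms <- seq(1000, 309000, by = 1000)
  trace <- synth_ppg(truth_ms)
  beats <- detect_beats(trace)
  expect_equal(nrow(beats), length(truth_ms))
  expect_lte(max(abs(beats$beat_time_ms - truth_ms)), 20)
})

test_that("constant or near-empty traces raise an insufficient-signal error", {
  flat <- structure(
    list(samples = rep(1, 5000), rate_hz = 50, start_time_s = 0),
    class = "ppg_trace"
  )
  expect_error(detect_beats(flat), class = "brainheart_insufficient_signal")
  two <- synth_ppg(c(1000, 2000), dur_s = 5)
  expect_error(detect_beats(two), class = "brainheart_insufficient_signal")
})

test_that("a dropped beat flags the long interval and keeps its neighbours", {
  truth_ms <- seq(1000, 100000, by = 1100)
  trace <- synth_ppg(setdiff(truth_ms, truth_ms[40]), dur_s = 105)
  beats <- detect_beats(trace)
  ibi <- attr(beats, "ibi")
  # the doubled interval (2200 ms) is physiologically implausible -> flagged
  expect_equal(sum(ibi$artifact), 1L)
  expect_equal(sum(!ibi$artifact), nrow(beats) - 2L)
  expect_equal(ibi$ibi_ms[ibi$artifact], 2200, tolerance = 25)
  # neighbours survive into the HR series
  hr <- beats_to_hr(beats)
  expect_equal(nrow(hr), nrow(beats) - 2L)
})

test_that("inter-beat intervals convert to bpm element-wise", {
  mk_beats <- function(ibi_ms) {
    bt <- cumsum(c(1000, ibi_ms))
    out <- tibble::tibble(beat_time_ms = bt)
    attr(out, "ibi") <- tibble::tibble(
      onset_ms = bt[-length(bt)], ibi_ms = ibi_ms,
      artifact = !(ibi_ms > 250 & ibi_ms < 2000)
    )
    class(out) <- c("beat_series", class(out))
    out
  }
  expect_equal(beats_to_hr(mk_beats(1000))$hr_bpm, 60)
  expect_equal(beats_to_hr(mk_beats(500))$hr_bpm, 120)
  expect_equal(beats_to_hr(mk_beats(c(1000, 750)))$hr_bpm, c(60, 80))
  expect_equal(session_mean_hr(beats_to_hr(mk_beats(c(1000, 750)))), 70)
  # artifact intervals are dropped before conversion
  expect_equal(nrow(beats_to_hr(mk_beats(c(1000, 2500, 800)))), 2L)
})

test_that("windowed HR averages beats by window and flags sparse windows", {
  grid <- window_grid(150, 2, 60, 10, t0_s = 10)
  hr60 <- tibble::tibble(
    time_ms = seq(10500, 309500, by = 1000), hr_bpm = 60
  )
  class(hr60) <- c("hr_series", class(hr60))
  w <- windowed_hr(hr60, grid)
  expect_equal(nrow(w), 25L)
  expect_true(all(w$hr_bpm == 60))
  expect_false(any(w$flagged))
  # a linear ramp gives strictly increasing windowed values
  ramp <- tibble::tibble(
    time_ms = seq(10500, 309500, by = 1000),
    hr_bpm = seq(60, 85, length.out = 300)
  )
  class(ramp) <- c("hr_series", class(ramp))
  wr <- windowed_hr(ramp, grid)
  expect_true(all(diff(wr$hr_bpm) > 0))
  # empty windows yield NA with a flag, not silent zeros
  sparse <- tibble::tibble(time_ms = c(15000, 16000, 200000), hr_bpm = 60)
  class(sparse) <- c("hr_series", class(sparse))
  ws <- windowed_hr(sparse, grid)
  expect_true(any(is.na(ws$hr_bpm)))
  expect_true(all(ws$flagged[is.na(ws$hr_bpm)]))
})

test_that("windowed HR recovers the generator's per-window truth", {
  atl <- tiny_atlas()
  spec <- coupling_spec(ppg_noise = 0.02)
  ses <- simulate_session(atl, spec, "gratitude", seed = 9)
  grid <- ses$truth$grid
  w <- windowed_hr(beats_to_hr(detect_beats(ses$ppg)), grid)
  expect_lte(max(abs(w$hr_bpm - ses$truth$hr_windows)), 0.5)
})

test_that("the PPG pipeline is invariant to amplitude rescaling", {
  truth_ms <- seq(1000, 200000, by = 850)
  a <- detect_beats(synth_ppg(truth_ms, dur_s = 205))
  b <- detect_beats(synth_ppg(truth_ms, dur_s = 205, amplitude = 37.5))
  expect_identical(a$beat_time_ms, b$beat_time_ms)
})

test_that("detection plus conversion recovers generator HR beat by beat", {
  atl <- tiny_atlas()
  ses <- simulate_session(
    atl, coupling_spec(ppg_noise = 0), "resentment",
    seed = 13
  )
  est <- beats_to_hr(detect_beats(ses$ppg))
  truth_hr <- 60000 / diff(ses$truth$beat_times_ms)
  expect_equal(nrow(est), length(truth_hr))
  expect_lte(max(abs(est$hr_bpm - truth_hr)), 1)
})
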