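# PPG -> beats -> instantaneous heart rate -> windowed heart rate.

#' Detect heartbeats in a PPG trace
#'
#' Local-maxima peak detection with a refractory distance and a relative
#' prominence criterion: a sample is a beat if it is a local maximum, its
#' topographic prominence is at least `prominence_frac` times the trace
#' amplitude range, and it lies at least `min_distance_ms` from any taller
#' accepted peak. Beat-to-beat intervals outside the physiologically
#' plausible (250, 2000) ms range are flagged as artifacts and excluded.
#'
#' @param trace A `ppg_trace` (samples, `rate_hz`, `start_time_s`).
#' @param min_distance_ms Minimum distance between beats (>= 250 ms).
#' @param prominence_frac Prominence threshold as a fraction of the trace
#'   amplitude range (default 0.3). Detection is therefore invariant to
#'   rescaling of the waveform.
#' @return A `beat_series` tibble with columns `beat_time_ms` (strictly
#'   increasing, includes `start_time_s`), and attributes `ibi` - a tibble
#'   of intervals (`onset_ms`, `ibi_ms`, `artifact`) - and `rate_hz`.
#' @export
detect_beats <- function(trace, min_distance_ms = 300, prominence_frac = 0.3) {
  stopifnot(inherits(trace, "ppg_trace"))
  if (min_distance_ms < 250) {
    abort_bh("`min_distance_ms` must be at least 250 ms.", "config_error")
  }
  x <- trace$samples
  n <- length(x)
  rng <- diff(range(x))
  if (rng == 0) {
    abort_bh("PPG trace is constant: no beats detectable.", "insufficient_signal")
  }
  # local maxima (plateau-left convention)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) > 0) {
    # topographic prominence: peak height minus the higher of the two
    # valley minima separating it from the nearest taller sample
    prom <- vapply(cand, function(i) {
      h <- x[i]
      left <- i; lmin <- h
      while (left > 1 && x[left] <= h) {
        left <- left - 1L
        if (x[left] < lmin) lmin <- x[left]
      }
      if (x[left] <= h) lmin <- min(lmin, x[left])
      right <- i; rmin <- h
      while (right < n && x[right] <= h) {
        right <- right + 1L
        if (x[right] < rmin) rmin <- x[right]
      }
      if (x[right] <= h) rmin <- min(rmin, x[right])
      h - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= prominence_frac * rng]
  }
  # greedy refractory enforcement, tallest first
  min_gap <- min_distance_ms / 1000 * trace$rate_hz
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  accepted <- numeric(0)
  for (i in ord) {
    if (all(abs(cand[i] - accepted) >= min_gap)) {
      keep[i] <- TRUE
      accepted <- c(accepted, cand[i])
    }
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 3) {
    abort_bh(
      sprintf("Only %d beats detected: insufficient signal.", length(peaks)),
      "insufficient_signal"
    )
  }
  # sub-sample refinement: quadratic interpolation through the peak and its
  # neighbours (a 50 Hz grid alone quantizes IBIs to 20 ms, i.e. >1 bpm)
  frac <- vapply(peaks, function(i) {
    if (i <= 1L || i >= n) return(0)
    den <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (den >= 0) return(0)
    d <- 0.5 * (x[i - 1] - x[i + 1]) / den
    max(min(d, 0.5), -0.5)
  }, numeric(1))
  beat_ms <- trace$start_time_s * 1000 +
    (peaks - 1 + frac) / trace$rate_hz * 1000
  ibi <- diff(beat_ms)
  out <- tibble::tibble(beat_time_ms = beat_ms)
  attr(out, "ibi") <- tibble::tibble(
    onset_ms = beat_ms[-length(beat_ms)],
    ibi_ms = ibi,
    artifact = !(ibi > 250 & ibi < 2000)
  )
  attr(out, "rate_hz") <- trace$rate_hz
  class(out) <- c("beat_series", class(out))
  out
}

#' Convert beat-to-beat intervals to instantaneous heart rate
#'
#' Each valid inter-beat interval (IBI) becomes one heart-rate sample
#' `hr_bpm = 60000 / ibi_ms`, timestamped at the interval midpoint.
#' Artifact-flagged intervals are dropped.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @return An `hr_series` tibble with `time_ms` (interval midpoints) and
#'   `hr_bpm`.
#' @examples
#' # an IBI of 1000 ms is 60 bpm; 500 ms is 120 bpm
#' @export
beats_to_hr <- function(beats) {
  ibi <- attr(beats, "ibi")
  if (is.null(ibi)) abort_bh("`beats` must come from detect_beats().", "data_error")
  ok <- !ibi$artifact
  if (!any(ok)) abort_bh("No valid inter-beat intervals.", "empty_series")
  out <- tibble::tibble(
    time_ms = ibi$onset_ms[ok] + ibi$ibi_ms[ok] / 2,
    hr_bpm = 60000 / ibi$ibi_ms[ok]
  )
  class(out) <- c("hr_series", class(out))
  out
}

#' Windowed heart rate on the fMRI sliding-window grid
#'
#' One value per window: the mean instantaneous heart rate over the beats
#' whose interval midpoints fall inside the window (same absolute-time grid
#' as the imaging windows, so brain and heart fluctuations are directly
#' comparable). Windows with no beats yield `NA`; windows with fewer than
#' `min_beats` are flagged.
#'
#' @param hr An `hr_series` from [beats_to_hr()].
#' @param grid A [window_grid()].
#' @param min_beats Minimum beats per window before flagging (default 10).
#' @return A tibble with `window`, `start_s`, `hr_bpm`, `n_beats`,
#'   `flagged`.
#' @export
windowed_hr <- function(hr, grid, min_beats = 10L) {
  stopifnot(inherits(grid, "window_grid"))
  t_s <- hr$time_ms / 1000
  vals <- numeric(grid$n_windows)
  nb <- integer(grid$n_windows)
  for (w in seq_len(grid$n_windows)) {
    inw <- t_s >= grid$starts_s[w] & t_s < grid$starts_s[w] + grid$window_s
    nb[w] <- sum(inw)
    vals[w] <- if (nb[w] == 0) NA_real_ else mean(hr$hr_bpm[inw])
  }
  tibble::tibble(
    window = seq_len(grid$n_windows),
    start_s = grid$starts_s,
    hr_bpm = vals,
    n_beats = nb,
    flagged = nb < min_beats
  )
}

#' Session mean heart rate
#'
#' @param hr An `hr_series`.
#' @return Mean of `hr_bpm` (scalar, bpm).
#' @export
session_mean_hr <- function(hr) {
  if (nrow(hr) == 0) abort_bh("Empty heart-rate series.", "empty_series")
  mean(hr$hr_bpm)
}

# Convenience: PPG trace -> windowed HR + session mean, via the full path.
ppg_to_hr <- function(trace, grid = NULL, ...) {
  hr <- beats_to_hr(detect_beats(trace, ...))
  list(
    hr = hr,
    mean_bpm = session_mean_hr(hr),
    windows = if (is.null(grid)) NULL else windowed_hr(hr, grid)
  )
}
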