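#' Sliding-window scheme over an fMRI session
#'
#' Defines the window grid used for dynamic connectivity and windowed heart
#' rate: windows of `window_s` seconds advanced in steps of `step_s`
#' seconds, all lying fully inside the session. With 150 retained volumes
#' at TR 2 s (300 s), 60 s windows and 10 s steps give 25 windows.
#'
#' @param n_volumes Number of (retained) volumes.
#' @param tr_s Repetition time in seconds.
#' @param window_s Window length in seconds (default 60).
#' @param step_s Step between successive window onsets in seconds
#'   (default 10).
#' @param t0_s Acquisition time of the first retained volume relative to
#'   the session start (seconds); volume trimming makes this non-zero.
#' @return A `window_grid`: list with `n_windows`, `window_s`, `step_s`,
#'   `tr_s`, `t0_s`, `starts_s` (absolute window onsets), and
#'   `vols_per_window`.
#' @examples
#' window_grid(150, 2)$n_windows  # 25
#' @export
window_grid <- function(n_volumes, tr_s, window_s = 60, step_s = 10,
                        t0_s = 0) {
  if (step_s <= 0) abort_bh("`step_s` must be positive.", "config_error")
  dur <- n_volumes * tr_s
  if (dur < window_s) {
    abort_bh(
      sprintf("Session (%g s) is shorter than one window (%g s).", dur, window_s),
      "config_error"
    )
  }
  n_windows <- floor((dur - window_s) / step_s) + 1L
  structure(
    list(
      n_windows = as.integer(n_windows), window_s = window_s,
      step_s = step_s, tr_s = tr_s, t0_s = t0_s,
      starts_s = t0_s + (seq_len(n_windows) - 1) * step_s,
      vols_per_window = as.integer(floor(window_s / tr_s))
    ),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "<window_grid> %d windows of %g s, step %g s, TR %g s, t0 %g s\n",
    x$n_windows, x$window_s, x$step_s, x$tr_s, x$t0_s
  ))
  invisible(x)
}

# Volume indices (1-based, relative to the retained series) falling in each
# window: volume i is acquired at t0 + (i - 1) * tr and belongs to windows
# whose [start, start + window) interval contains that time.
window_volume_index <- function(grid, n_volumes) {
  lapply(seq_len(grid$n_windows), function(w) {
    t <- grid$t0_s + (seq_len(n_volumes) - 1) * grid$tr_s
    which(t >= grid$starts_s[w] & t < grid$starts_s[w] + grid$window_s)
  })
}

# Per-window Pearson correlation between two series on a window grid.
sliding_cor_series <- function(x, y, grid) {
  stopifnot(length(x) == length(y))
  idx <- window_volume_index(grid, length(x))
  vapply(idx, function(i) {
    xs <- x[i]; ys <- y[i]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_ else stats::cor(xs, ys)
  }, numeric(1))
}
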