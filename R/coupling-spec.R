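#' Specification of injectable ground-truth effects for synthetic cohorts
#'
#' Collects every dial of the synthetic generator: heart-rate means and
#' variabilities, the designated network edge carrying brain-heart coupling
#' and its target correlation, per-condition functional-connectivity edge
#' changes, behaviour-connectivity slopes, and noise scales. The defaults
#' describe the study design the package emulates: five sessions per
#' subject (baseline rest, two counterbalanced 5-minute interventions, a
#' rest after each), 155 volumes at TR 2 s per session, PPG at 50 Hz during
#' the interventions, heart rate about 3 bpm lower during the gratitude
#' intervention than during resentment, brain-heart coupling present during
#' gratitude only, and a connectivity change after the gratitude
#' intervention.
#'
#' Network latent time courses are generated mutually independent unless an
#' effect explicitly correlates them, so that every dependence recovered
#' downstream is attributable to an injected effect.
#'
#' @param hr_baseline_bpm Population mean heart rate (bpm), in `[30, 200]`.
#' @param hr_subject_sd Between-subject SD of mean heart rate (bpm).
#' @param hr_session_sd Within-subject, between-session SD of mean heart
#'   rate (bpm); paired condition differences then have SD
#'   `sqrt(2) * hr_session_sd`.
#' @param hr_condition_delta_bpm Signed mean HR shift for `delta_condition`
#'   relative to the other intervention.
#' @param delta_condition Condition receiving the HR shift.
#' @param hr_window_sd SD of windowed HR fluctuations around the session
#'   mean (bpm).
#' @param sync_edge Character vector of two network names: the edge whose
#'   windowed connectivity co-fluctuates with windowed heart rate.
#' @param sync_rho Target Pearson correlation between windowed FC of
#'   `sync_edge` and windowed HR, in `[-1, 1]`. When non-zero the coupling
#'   is exact by construction on the analysis window grid; when zero the
#'   windowed HR fluctuations are independent noise (an honest null).
#' @param sync_condition Conditions in which the coupling is injected.
#' @param base_r Baseline correlation between any two network latents
#'   (default 0).
#' @param fc_effects Data frame with columns `condition`, `net_a`, `net_b`,
#'   `delta_r`: additive correlation changes on named edges in named
#'   conditions.
#' @param behavior_effects Data frame with columns `score`, `condition`,
#'   `net_a`, `net_b`, `slope`: per-subject edge z offset equal to
#'   `slope * (score - population mean)` in the named condition.
#' @param behavior_base Data frame with columns `score`, `mean`, `sd`,
#'   `integer`: population distribution of each behavioural score. Defaults
#'   cover HADS anxiety/depression (integer 0-21) and continuous SDT
#'   autonomy/competence/relatedness subscales.
#' @param noise_sd Voxelwise Gaussian noise SD relative to unit-variance
#'   network latents.
#' @param motion_leak SD of a smooth drift leaked into every voxel (removed
#'   by nuisance regression on real pipelines).
#' @param ppg_noise SD of additive noise on the PPG waveform (pulse
#'   amplitude is 1).
#' @param ppg_rate_hz PPG sampling rate (Hz).
#' @param n_sinusoids Number of random-phase sinusoids per network latent.
#' @param ar_frac Fraction of latent variance contributed by AR(1) jitter.
#' @param ar_phi AR(1) coefficient of the jitter.
#' @param band Pass band (Hz) of the latent dynamics.
#' @param random_seed Integer master seed of the generator.
#' @return A `coupling_spec` object (validated list).
#' @examples
#' spec <- coupling_spec(sync_rho = 0.9, noise_sd = 0)
#' spec$sync_edge
#' @export
coupling_spec <- function(hr_baseline_bpm = 70,
                          hr_subject_sd = 7,
                          hr_session_sd = 4.2,
                          hr_condition_delta_bpm = -3,
                          delta_condition = "gratitude",
                          hr_window_sd = 2,
                          sync_edge = c("temporolimbic", "salience"),
                          sync_rho = 0.6,
                          sync_condition = "gratitude",
                          base_r = 0,
                          fc_effects = default_fc_effects(),
                          behavior_effects = default_behavior_effects(),
                          behavior_base = default_behavior_base(),
                          noise_sd = 0.5,
                          motion_leak = 0.1,
                          ppg_noise = 0.02,
                          ppg_rate_hz = 50,
                          n_sinusoids = 8,
                          ar_frac = 0.02,
                          ar_phi = 0.5,
                          band = c(0.009, 0.08),
                          random_seed = 1L) {
  if (abs(sync_rho) > 1) {
    abort_bh("`sync_rho` must lie in [-1, 1].", "config_error")
  }
  if (noise_sd < 0) {
    abort_bh("`noise_sd` must be non-negative.", "config_error")
  }
  if (hr_baseline_bpm < 30 || hr_baseline_bpm > 200) {
    abort_bh("`hr_baseline_bpm` must lie in [30, 200] bpm.", "config_error")
  }
  stopifnot(length(sync_edge) == 2L, length(band) == 2L, band[1] < band[2])
  fc_effects <- tibble::as_tibble(fc_effects)
  behavior_effects <- tibble::as_tibble(behavior_effects)
  behavior_base <- tibble::as_tibble(behavior_base)
  structure(
    list(
      hr_baseline_bpm = hr_baseline_bpm, hr_subject_sd = hr_subject_sd,
      hr_session_sd = hr_session_sd,
      hr_condition_delta_bpm = hr_condition_delta_bpm,
      delta_condition = delta_condition, hr_window_sd = hr_window_sd,
      sync_edge = sync_edge, sync_rho = sync_rho,
      sync_condition = sync_condition, base_r = base_r,
      fc_effects = fc_effects, behavior_effects = behavior_effects,
      behavior_base = behavior_base, noise_sd = noise_sd,
      motion_leak = motion_leak, ppg_noise = ppg_noise,
      ppg_rate_hz = ppg_rate_hz, n_sinusoids = n_sinusoids,
      ar_frac = ar_frac, ar_phi = ar_phi, band = band,
      random_seed = as.integer(random_seed)
    ),
    class = "coupling_spec"
  )
}

#' @rdname coupling_spec
#' @export
default_fc_effects <- function() {
  tibble::tibble(
    condition = "rest_post_gratitude",
    net_a = "dmn", net_b = "salience", delta_r = 0.3
  )
}

#' @rdname coupling_spec
#' @export
default_behavior_effects <- function() {
  tibble::tibble(
    score = "hads_anxiety", condition = "rest_post_gratitude",
    net_a = "temporolimbic", net_b = "fp_right", slope = -0.05
  )
}

#' @rdname coupling_spec
#' @export
default_behavior_base <- function() {
  tibble::tibble(
    score = c(
      "hads_anxiety", "hads_depression",
      "sdt_autonomy", "sdt_competence", "sdt_relatedness"
    ),
    mean = c(6, 5, 5, 5, 5),
    sd = c(3, 3, 1, 1, 1),
    integer = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<coupling_spec> HR %g bpm (delta %+g bpm in %s), sync %s~%s rho=%g",
      " in %s, noise_sd=%g, seed=%d\n"
    ),
    x$hr_baseline_bpm, x$hr_condition_delta_bpm, x$delta_condition,
    x$sync_edge[1], x$sync_edge[2], x$sync_rho,
    paste(x$sync_condition, collapse = "/"), x$noise_sd, x$random_seed
  ))
  invisible(x)
}
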