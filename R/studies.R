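#' Replicate-cohort recovery study for a planted power-behavior effect
#'
#' Generates `n_cohorts` independent synthetic cohorts with a single
#' planted Pearson effect between an eyes-closed band-power feature and a
#' behavioral measure, runs each cohort through preprocessing, Welch band
#' power and the correlation map, and returns the recovered coefficients
#' at the planted cell. Cohorts are eyes-closed only and artifact-free:
#' the study measures the calibration of the correlation pipeline itself,
#' while artifact robustness is validated separately by the preprocessing
#' tests. Recording duration defaults to 24 s, at which Welch estimation
#' noise is a negligible fraction of the between-subject feature variance
#' even for the narrow delta band.
#'
#' @param channel,band,measure,rho the planted effect, see
#'   [planted_effect()].
#' @param n_cohorts number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param duration_s recording duration per subject in seconds.
#' @param seed integer seed; per-cohort master seeds are derived from it.
#' @return Numeric vector of length `n_cohorts`: the recovered Pearson
#'   coefficient at the planted (band, channel) cell of each cohort map.
#' @export
recovery_study <- function(channel, band, measure, rho, n_cohorts = 200,
                           n_subjects = 43, duration_s = 24, seed = 1) {
  pe <- list(planted_effect(channel, band, measure, rho))
  vapply(seq_len(n_cohorts), function(i) {
    cfg <- cohort_config(
      n_subjects = n_subjects, duration_s = duration_s,
      planted_effects = pe, conditions = "eyes_closed",
      artifact_spec = list(blink_per_min = 0, muscle_per_min = 0,
                           flat_prob = 0),
      master_seed = derive_seed(seed, i, 41))
    cohort <- generate_cohort(cfg)
    cleaned <- lapply(cohort$recordings, function(r)
      preprocess_recording(r, min_s = 0)$recording)
    bp <- band_power_table(cleaned)
    cm <- correlation_map(bp, cohort$behavior, measure)
    cm$rho[cm$band == band & cm$channel == channel]
  }, numeric(1))
}

#' Eyes-closed occipital alpha recovery study
#'
#' Generates one full default cohort (43 subjects, 60-s eyes-closed and
#' eyes-open recordings, artifacts injected), preprocesses every
#' recording, and returns the eyes-closed/eyes-open occipital (O1, O2)
#' alpha contrast. With the default configuration the generator targets
#' the eyes-closed occipital alpha group level of 38.80 uV^2/Hz.
#'
#' @param seed integer master seed.
#' @param n_subjects cohort size.
#' @return The [ec_eo_alpha_contrast()] result.
#' @export
occipital_alpha_study <- function(seed = 1, n_subjects = 43) {
  cfg <- cohort_config(n_subjects = n_subjects, master_seed = seed)
  cohort <- generate_cohort(cfg)
  cleaned <- lapply(cohort$recordings, function(r)
    preprocess_recording(r)$recording)
  bp <- band_power_table(cleaned)
  ec_eo_alpha_contrast(bp)
}

#' Replicate behavioral simulation study
#'
#' Simulates `n_reps` cohorts of full task sessions (16 trials x 12 items
#' per subject), scores every log, and returns the cohort means of target
#' accuracy and correct-target reaction time per replicate.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param params behavioral parameters, see [behavior_params()].
#' @param seed integer seed.
#' @return Data frame with one row per replicate: `accuracy_target_pct`,
#'   `mean_rt_correct_target_ms`.
#' @export
behavior_study <- function(n_reps = 200, n_subjects = 43,
                           params = behavior_params(), seed = 1) {
  rows <- vapply(seq_len(n_reps), function(i) {
    s <- simulate_behavior_cohort(n_subjects, params,
                                  seed = derive_seed(seed, i, 61))
    c(mean(s$accuracy_target_pct), mean(s$mean_rt_correct_target_ms))
  }, numeric(2))
  data.frame(accuracy_target_pct = rows[1, ],
             mean_rt_correct_target_ms = rows[2, ])
}
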