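# Shared fixtures and oracles, all built in code.

no_artifacts <- list(blink_per_min = 0, muscle_per_min = 0, flat_prob = 0)

# A small, fast cohort configuration for property tests.
quick_cfg <- function(n_subjects = 5, duration_s = 12, ...) {
  cohort_config(n_subjects = n_subjects, duration_s = duration_s,
                artifact_spec = no_artifacts, ...)
}

# A deterministic flat-spectrum test recording (white noise, all channels).
white_recording <- function(duration_s = 60, fs = 128, sd = 1, seed = 1,
                            montage = builtin_montage()) {
  set.seed(seed)
  n <- duration_s * fs
  data <- matrix(rnorm(length(montage$channel_names) * n, sd = sd),
                 nrow = length(montage$channel_names),
                 dimnames = list(montage$channel_names, NULL))
  new_recording(data, fs, "white", "eyes_closed", montage)
}

# Brute-force Pearson correlation: two-pass covariance / SD formula.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Brute-force Kruskal-Wallis H with midrank ties correction.
kw_oracle <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)                       # midranks
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

run_ec_map <- function(cfg, measure) {
  cohort <- generate_cohort(cfg)
  cleaned <- lapply(cohort$recordings, function(r)
    preprocess_recording(r, min_s = 0)$recording)
  bp <- band_power_table(cleaned)
  correlation_map(bp, cohort$behavior, measure)
}
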