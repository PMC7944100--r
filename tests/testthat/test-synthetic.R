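test_that("cohort generation is bit-deterministic given the master seed", {
  cfg <- quick_cfg(n_subjects = 3, master_seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$behavior, b$behavior)
  expect_equal(length(a$recordings), 3 * 2)    # subjects x {EC, EO}
})

test_that("default configuration simulates the full study cohort layout", {
  cfg <- cohort_config()
  expect_equal(cfg$n_subjects, 43)
  expect_equal(cfg$duration_s, 60)
  expect_equal(cfg$sample_rate, 128)
  # 43 subjects x two resting conditions = 86 recordings
  expect_equal(cfg$n_subjects * length(cfg$conditions), 86)
})

test_that("subjects have independent streams anchored to their own seeds", {
  cfg <- quick_cfg(n_subjects = 4, master_seed = 5)
  a <- generate_cohort(cfg)
  lat2 <- draw_subject_latents(cfg, resteeg:::derive_seed(5, 2, 1))
  rec2 <- generate_subject_signal(cfg, lat2, "eyes_closed",
                                  seed = resteeg:::derive_seed(5, 2, 2),
                                  subject_id = "S02")
  expect_identical(a$recordings[["S02.eyes_closed"]]$data, rec2$data)
  # distinct subjects do not share signals
  expect_false(identical(a$recordings[["S01.eyes_closed"]]$data,
                         a$recordings[["S02.eyes_closed"]]$data))
})

test_that("minimum cohort of three subjects still supports the map stage", {
  cfg <- quick_cfg(n_subjects = 3, master_seed = 2)
  cm <- run_ec_map(cfg, "mean_rt_ms")
  expect_equal(nrow(cm), 70)
  expect_true(all(cm$n <= 3))
  expect_true(any(cm$n == 3))
})

test_that("Welch round trip recovers configured occipital alpha density", {
  # group-level Monte Carlo: mean estimate within a few percent of target
  # targets are defined post-average-reference; measure the raw generator
  # output with the compensation off
  cfg <- cohort_config(n_subjects = 3, duration_s = 60, subject_sd_log = 0,
                       artifact_spec = no_artifacts,
                       reference_compensation = FALSE)
  est <- vapply(1:25, function(s) {
    rec <- generate_subject_signal(cfg, condition = "eyes_closed",
                                   seed = 1000 + s)
    bp <- band_power(welch_psd(rec))
    mean(bp$absolute_density[bp$channel %in% c("O1", "O2") &
                               bp$band == "alpha"])
  }, numeric(1))
  expect_equal(mean(est), 38.80, tolerance = 0.05)
  # eyes-open occipital alpha sits at the unboosted baseline
  est_eo <- vapply(1:25, function(s) {
    rec <- generate_subject_signal(cfg, condition = "eyes_open",
                                   seed = 2000 + s)
    bp <- band_power(welch_psd(rec))
    mean(bp$absolute_density[bp$channel %in% c("O1", "O2") &
                               bp$band == "alpha"])
  }, numeric(1))
  expect_equal(mean(est_eo), 35.65, tolerance = 0.05)
})

test_that("unit eyes-closed boost makes EC and EO alpha equal in expectation", {
  cfg <- quick_cfg(n_subjects = 3, ec_alpha_boost = 1, subject_sd_log = 0.3)
  lat <- draw_subject_latents(cfg, 4)
  ec <- resteeg:::subject_target_density(cfg, lat, "eyes_closed")
  eo <- resteeg:::subject_target_density(cfg, lat, "eyes_open")
  expect_identical(ec, eo)
})

test_that("planted coherence edge realizes its closed-form coherence", {
  # shared source with weight for target gamma: Coh = gamma by construction
  cfg <- cohort_config(n_subjects = 3, duration_s = 60,
                       subject_sd_log = 0, coh_base = 0.8, coh_sd_logit = 0,
                       planted_effects = list(
                         planted_effect(c("F3", "P7"), "alpha",
                                        "mean_rt_ms", 0.3)),
                       artifact_spec = no_artifacts,
                       reference_compensation = FALSE)
  est <- vapply(1:20, function(s) {
    rec <- generate_subject_signal(cfg, condition = "eyes_open",
                                   seed = 3000 + s)
    coh <- ms_coherence(rec, c("F3", "P7"))
    mean(coh$coherence[coh$frequencies >= 8 & coh$frequencies < 13])
  }, numeric(1))
  expect_equal(mean(est), 0.8, tolerance = 0.1 / 0.8)
})

test_that("artifact injection with zero rates is the identity", {
  rec <- white_recording(duration_s = 2, seed = 9)
  out <- inject_artifacts(rec, no_artifacts, seed = 1)
  expect_identical(out$data, rec$data)
  expect_equal(nrow(out$annotations), 0)
})

test_that("blink counts are Poisson around the configured rate", {
  rec <- white_recording(duration_s = 60, seed = 10)
  counts <- vapply(1:120, function(s) {
    out <- inject_artifacts(rec, list(blink_per_min = 6,
                                      muscle_per_min = 0, flat_prob = 0),
                            seed = s)
    sum(out$annotations$label == "blink")
  }, numeric(1))
  expect_equal(mean(counts), 6, tolerance = 0.12)   # Poisson mean 6
  expect_gt(var(counts), 3)                          # over-dispersed vs fixed
})

test_that("a drawn flat channel is exactly zero for the flat interval", {
  rec <- white_recording(duration_s = 10, seed = 11)
  out <- inject_artifacts(rec, list(blink_per_min = 0, muscle_per_min = 0,
                                    flat_prob = 1), seed = 2)
  ann <- out$annotations[out$annotations$label == "flat", ]
  expect_equal(nrow(ann), 1)
  expect_gte(ann$duration, 5)
  idx <- round(ann$onset * 128) + seq_len(round(ann$duration * 128))
  flat_ptp <- apply(out$data[, idx], 1, function(x) diff(range(x)))
  expect_equal(min(flat_ptp), 0)                     # exactly one flat channel
  expect_equal(sum(flat_ptp == 0), 1)
})

test_that("independent covariates decorrelate from any feature", {
  set.seed(30)
  r <- vapply(1:200, function(s) {
    f <- matrix(rlnorm(43), ncol = 1)
    y <- generate_behavior_covariates(f, list(
      planted_effect("P8", "beta", "accuracy_pct", 0)), seed = s)
    cor(f[, 1], y$mean_rt_ms)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.015)
})

test_that("covariates land on the printed behavioral scales", {
  y <- generate_behavior_covariates(NULL, list(), seed = 3,
                                    n_subjects = 5000)
  expect_equal(mean(y$mean_rt_ms), 673, tolerance = 0.01)
  expect_equal(sd(y$mean_rt_ms), 51, tolerance = 0.05)
  expect_equal(mean(y$accuracy_pct), 91.56, tolerance = 0.01)
  expect_true(all(y$accuracy_pct <= 100 & y$accuracy_pct >= 0))
})

test_that("jointly infeasible planted effects raise a configuration error", {
  set.seed(44)
  z <- rnorm(43)
  f <- cbind(z, -z + rnorm(43, sd = 0.05))   # nearly opposite features
  pes <- list(planted_effect("P8", "beta", "accuracy_pct", 0.8),
              planted_effect("P8", "alpha", "accuracy_pct", 0.8))
  expect_error(generate_behavior_covariates(f, pes, seed = 1),
               "jointly infeasible")
})

test_that("planted correlations are recovered on the latent scale", {
  # cheap recovery check at the covariate level (full pipeline recovery is
  # exercised by the acceptance suite)
  set.seed(77)
  r <- vapply(1:300, function(s) {
    f <- matrix(rlnorm(43, sdlog = 0.8), ncol = 1)
    y <- generate_behavior_covariates(f, list(
      planted_effect("P7", "delta", "mean_rt_ms", -0.31)), seed = 7000 + s)
    cor(f[, 1], y$mean_rt_ms)
  }, numeric(1))
  expect_equal(mean(r), -0.31, tolerance = 0.03 / 0.31)
})
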