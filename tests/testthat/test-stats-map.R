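test_that("pearson_r equals the brute-force two-pass oracle", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 5)), -0.5)
  set.seed(100)
  for (i in 1:25) {
    x <- rnorm(sample(3:40, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("pearson_p reproduces the printed worked example", {
  expect_equal(pearson_p(0, 43), 1)
  # rho = -0.42, n = 43: t = 2.963 on 41 df -> p ~ 0.0051
  expect_equal(pearson_p(-0.42, 43), 0.0051, tolerance = 0.02)
  # independent oracle: cor.test on data constructed to have r = -0.42
  set.seed(101)
  x <- rnorm(43)
  e <- rnorm(43)
  e <- residuals(lm(e ~ x))
  y <- -0.42 * scale(x)[, 1] + sqrt(1 - 0.42^2) * scale(e)[, 1]
  ct <- cor.test(x, y)
  expect_equal(pearson_p(unname(ct$estimate), 43), ct$p.value,
               tolerance = 1e-10)
  # the printed table pair (-0.42, 0.0054) is consistent with rho rounded
  # to two decimals: p spans the printed value over the rounding interval
  expect_lt(pearson_p(-0.425, 43), 0.0054)
  expect_gt(pearson_p(-0.415, 43), 0.0051)
})

test_that("pearson_p is monotone in |rho| and in n", {
  rhos <- seq(0.05, 0.95, by = 0.05)
  p_rho <- vapply(rhos, pearson_p, numeric(1), n = 43)
  expect_true(all(diff(p_rho) < 0))
  ns <- seq(5, 100, by = 5)
  p_n <- vapply(ns, function(n) pearson_p(0.3, n), numeric(1))
  expect_true(all(diff(p_n) < 0))
  expect_warning(p1 <- pearson_p(1, 10), "limiting")
  expect_equal(p1, 0)
})

test_that("the correlation map covers the 5 x 14 grid", {
  cfg <- quick_cfg(n_subjects = 5, master_seed = 3)
  cm <- run_ec_map(cfg, "accuracy_pct")
  expect_equal(nrow(cm), 70)
  expect_true(all(cm$rho >= -1 & cm$rho <= 1, na.rm = TRUE))
  expect_true(all(cm$p > 0 & cm$p <= 1, na.rm = TRUE))
  # subjects that lose a rejected channel are dropped pairwise
  expect_true(all(cm$n >= 3 & cm$n <= 5))
})

test_that("a constant behavioral column is an undefined correlation", {
  cfg <- quick_cfg(n_subjects = 4, master_seed = 5)
  cohort <- generate_cohort(cfg)
  bp <- band_power_table(lapply(cohort$recordings, identity))
  beh <- cohort$behavior
  beh$mean_rt_ms <- 673
  expect_error(correlation_map(bp, beh, "mean_rt_ms"), "zero variance")
  expect_error(correlation_map(bp, beh, "nope"), "no column")
})

test_that("a strongly planted effect localizes to its own cell", {
  hits <- vapply(1:15, function(s) {
    cfg <- cohort_config(n_subjects = 43, duration_s = 12,
                         conditions = "eyes_closed",
                         planted_effects = list(
                           planted_effect("P7", "delta", "mean_rt_ms",
                                          -0.6)),
                         artifact_spec = no_artifacts,
                         master_seed = 900 + s)
    cm <- run_ec_map(cfg, "mean_rt_ms")
    top <- cm[which.max(abs(cm$rho)), ]
    top$band == "delta" && top$channel == "P7"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("edge networks cover 455 edges and respect the alpha level", {
  cfg <- quick_cfg(n_subjects = 4, master_seed = 7)
  cohort <- generate_cohort(cfg)
  edges <- coherence_edge_table(cohort$recordings)
  en <- edge_correlation_network(edges, cohort$behavior, "mean_rt_ms")
  expect_equal(nrow(en), 455)
  expect_true(all(en$p >= 0 & en$p <= 1, na.rm = TRUE))
  en0 <- edge_correlation_network(edges, cohort$behavior, "mean_rt_ms",
                                  alpha = 0)
  expect_equal(sum(en0$significant), 0)
})

test_that("a planted coherence-behavior edge is detected; null edges stay calibrated", {
  flags <- vapply(1:10, function(s) {
    cfg <- cohort_config(n_subjects = 30, duration_s = 20,
                         conditions = "eyes_closed",
                         coh_base = 0.4, coh_sd_logit = 0.8,
                         planted_effects = list(
                           planted_effect(c("F3", "P7"), "alpha",
                                          "mean_rt_ms", 0.6)),
                         artifact_spec = no_artifacts,
                         master_seed = 1200 + s)
    cohort <- generate_cohort(cfg)
    edges <- coherence_edge_table(cohort$recordings)
    en <- edge_correlation_network(edges, cohort$behavior, "mean_rt_ms")
    hit <- en$significant[en$band == "alpha" &
                            ((en$ch_i == "F3" & en$ch_j == "P7") |
                               (en$ch_i == "P7" & en$ch_j == "F3"))]
    null_rate <- mean(en$significant[en$band != "alpha"])
    c(hit, null_rate < 0.12)
  }, logical(2))
  expect_gte(mean(flags[1, ]), 0.7)
  expect_gte(mean(flags[2, ]), 0.8)
})

test_that("the EC/EO occipital alpha contrast summarizes both conditions", {
  cfg <- cohort_config(n_subjects = 12, duration_s = 12,
                       subject_sd_log = 0.1,
                       artifact_spec = no_artifacts, master_seed = 31)
  cohort <- generate_cohort(cfg)
  bp <- band_power_table(cohort$recordings)
  ct <- ec_eo_alpha_contrast(bp)
  expect_identical(ct$summary$condition, c("eyes_closed", "eyes_open"))
  expect_gt(ct$summary$mean[1], ct$summary$mean[2])
  expect_true(ct$test$p > 0 && ct$test$p <= 1)
  # missing condition is a pairing error
  bp_ec <- bp[bp$condition == "eyes_closed", ]
  expect_error(ec_eo_alpha_contrast(bp_ec), "required")
})

test_that("a doubled eyes-closed boost is detected nearly always", {
  p <- vapply(1:15, function(s) {
    cfg <- cohort_config(n_subjects = 20, duration_s = 12,
                         subject_sd_log = 0.1, ec_alpha_boost = 2,
                         artifact_spec = no_artifacts,
                         master_seed = 1500 + s)
    cohort <- generate_cohort(cfg)
    bp <- band_power_table(cohort$recordings)
    ec_eo_alpha_contrast(bp)$test$p
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.95)
})

test_that("null-boost contrast p-values are calibrated (uniform)", {
  # subject trait variance is shared between the paired EC/EO recordings,
  # so calibration is assessed with measurement noise only
  p <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_subjects = 10, duration_s = 12,
                         subject_sd_log = 0, ec_alpha_boost = 1,
                         artifact_spec = no_artifacts,
                         master_seed = 2500 + s)
    cohort <- generate_cohort(cfg)
    bp <- band_power_table(cohort$recordings)
    ec_eo_alpha_contrast(bp)$test$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
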