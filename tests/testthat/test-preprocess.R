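make_sine_recording <- function(freq, amplitude = 1, duration_s = 16,
                                fs = 128) {
  m <- builtin_montage()
  tt <- (0:(duration_s * fs - 1)) / fs
  data <- matrix(rep(amplitude * sin(2 * pi * freq * tt), 14),
                 nrow = 14, byrow = TRUE,
                 dimnames = list(m$channel_names, NULL))
  new_recording(data, fs, "sine", "eyes_closed", m)
}

test_that("band-pass keeps 10 Hz, removes DC and suppresses slow drift", {
  ten <- bandpass_filter(make_sine_recording(10))
  ratio <- sqrt(mean(ten$data[1, ]^2)) / sqrt(0.5)
  expect_gte(ratio, 0.95)

  m <- builtin_montage()
  dc <- new_recording(matrix(100, 14, 1024,
                             dimnames = list(m$channel_names, NULL)),
                      128, "dc", "eyes_closed", m)
  expect_lt(max(abs(bandpass_filter(dc)$data)), 1e-9)

  drift <- bandpass_filter(make_sine_recording(0.1, amplitude = 100))
  expect_lte(sqrt(2) * sqrt(mean(drift$data[1, ]^2)), 10)
})

test_that("band-pass rejects corners at or above Nyquist", {
  rec <- white_recording(duration_s = 1)
  expect_error(bandpass_filter(rec, high = 64), "Nyquist")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  rec <- white_recording(duration_s = 2, sd = 10, seed = 21)
  ref <- rereference_average(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-10)
  again <- rereference_average(ref)
  expect_equal(again$data, ref$data, tolerance = 1e-12)
})

test_that("a zero-mean channel pair passes through the average reference", {
  m <- subset_montage(builtin_montage(), c("O1", "O2"))
  x <- sin(2 * pi * 5 * (0:255) / 128)
  data <- rbind(O1 = x, O2 = -x)
  rec <- new_recording(data, 128, "s", "eyes_closed", m)
  expect_equal(rereference_average(rec)$data, data,
               tolerance = 1e-12, ignore_attr = TRUE)
  one <- new_recording(data[1, , drop = FALSE], 128, "s", "eyes_closed",
                       subset_montage(builtin_montage(), "O1"))
  expect_error(rereference_average(one), "2 channels")
})

test_that("flat and peaky channels are flagged, clean channels are not", {
  rec <- white_recording(duration_s = 20, sd = 20, seed = 22)
  flat <- rec
  flat$data["T8", 300:(300 + 6 * 128)] <- 0
  found <- detect_bad_channels(flat)
  expect_true(any(found$channel == "T8" & found$reason == "flat"))

  peaky <- rec
  peaky$data["F3", ] <- peaky$data["F3", ] * 50
  found <- detect_bad_channels(peaky)
  # brute-force robust z of the whole-recording peak-to-peak
  ptp <- apply(peaky$data, 1, function(x) diff(range(x)))
  z <- (ptp - median(ptp)) / mad(ptp)
  expect_true(all(names(which(abs(z) > 5)) %in% found$channel))
  expect_true("F3" %in% found$channel)
})

test_that("clean synthetic recordings rarely trigger bad-channel flags", {
  cfg <- quick_cfg(duration_s = 20)
  flags <- vapply(1:40, function(s) {
    rec <- generate_subject_signal(cfg, draw_subject_latents(cfg, s),
                                   "eyes_closed", seed = 400 + s)
    nrow(detect_bad_channels(rec))
  }, numeric(1))
  expect_lt(mean(flags > 0), 0.05)
})

test_that("ASR calibration picks the cleanest windows and mirrors stationary covariance", {
  rec <- white_recording(duration_s = 30, sd = 15, seed = 23)
  model <- asr_calibrate(rec)
  full_cov <- cov(t(rec$data))
  rel <- norm(model$calibration_covariance - full_cov, "F") /
    norm(full_cov, "F")
  expect_lt(rel, 0.1)
  # basis is orthonormal
  expect_equal(crossprod(model$component_basis), diag(14),
               tolerance = 1e-10, ignore_attr = TRUE)

  # a huge 2-s artifact must not enter the calibration set: statistics
  # stay close to those calibrated on the clean data alone
  dirty <- rec
  dirty$data[, 1000:1255] <- dirty$data[, 1000:1255] + 500
  model_dirty <- asr_calibrate(dirty)
  expect_equal(model_dirty$component_variance_mean,
               model$component_variance_mean, tolerance = 0.15)

  expect_error(asr_calibrate(white_recording(duration_s = 5)), "short")
})

test_that("a constant repeated signal yields near-zero variance spread", {
  m <- builtin_montage()
  block <- matrix(sin(2 * pi * (1:64) / 64), 14, 64, byrow = TRUE)
  data <- matrix(rep(block, 40), 14, 64 * 40,
                 dimnames = list(m$channel_names, NULL))
  rec <- new_recording(data, 128, "s", "eyes_closed", m)
  model <- asr_calibrate(rec)
  expect_lt(max(model$component_variance_sd), 1e-8)
})

test_that("ASR is the identity on artifact-free data and at infinite cutoff", {
  cfg <- quick_cfg(duration_s = 20)
  rec <- generate_subject_signal(cfg, NULL, "eyes_closed", seed = 31)
  model <- asr_calibrate(rec)
  out <- asr_clean(rec, model)
  expect_equal(out$recording$data, rec$data, tolerance = 1e-6)

  blinked <- inject_artifacts(rec, list(blink_per_min = 10,
                                        muscle_per_min = 0, flat_prob = 0),
                              seed = 5)
  inf_out <- asr_clean(blinked, model, cutoff_k = Inf)
  expect_equal(inf_out$report$windows_reconstructed, 0)
  expect_identical(inf_out$recording$data, blinked$data)
})

test_that("ASR caps offending component variances and spares clean windows", {
  cfg <- quick_cfg(duration_s = 30)
  rec <- generate_subject_signal(cfg, NULL, "eyes_closed", seed = 32)
  model <- asr_calibrate(rec)
  thr <- model$component_variance_mean + 20 * model$component_variance_sd
  blinked <- inject_artifacts(rec, list(blink_per_min = 6,
                                        muscle_per_min = 0, flat_prob = 0),
                              seed = 6)
  out <- asr_clean(blinked, model)
  expect_gt(out$report$windows_reconstructed, 0)
  # total energy never increases
  expect_lte(sum(out$recording$data^2), sum(blinked$data^2))
  # windows far away from any blink are essentially untouched
  ann <- blinked$annotations
  far <- rep(TRUE, n_samples(rec))
  for (i in seq_len(nrow(ann))) {
    lo <- max(1, round((ann$onset[i] - 1) * 128))
    hi <- min(n_samples(rec), round((ann$onset[i] + ann$duration[i] + 1) * 128))
    far[lo:hi] <- FALSE
  }
  expect_lt(max(abs(out$recording$data[, far] - blinked$data[, far])) /
              max(abs(blinked$data[, far])), 0.01)
  # blink-window variance is pulled down toward the cap
  idx <- round(ann$onset[1] * 128) + seq_len(51)
  vb <- mean(blinked$data[, idx]^2)
  va <- mean(out$recording$data[, idx]^2)
  expect_lt(va, vb)
  expect_lt(va, 1.5 * max(thr))
})

test_that("the minimum-duration guard names subject and condition", {
  rec <- white_recording(duration_s = 60)
  expect_identical(ensure_min_duration(rec, 60), rec)
  expect_identical(ensure_min_duration(white_recording(duration_s = 90), 60),
                   white_recording(duration_s = 90))
  short <- white_recording(duration_s = 59)
  short$subject_id <- "S17"
  expect_error(ensure_min_duration(short, 60), "S17")
  expect_error(ensure_min_duration(short, 60), "eyes_closed")
})

test_that("cleaning moves band powers toward the ground truth", {
  cfg <- cohort_config(n_subjects = 3, duration_s = 60,
                       artifact_spec = list(blink_per_min = 8,
                                            muscle_per_min = 4,
                                            flat_prob = 0))
  err <- function(rec, truth) {
    bp <- band_power(welch_psd(rec))
    keep <- bp$channel %in% rownames(truth)
    measured <- matrix(bp$absolute_density[keep], ncol = 5,
                       dimnames = list(unique(bp$channel[keep]), NULL))
    mean(abs(log(measured / truth[rownames(measured), ])))
  }
  improved <- vapply(1:20, function(s) {
    lat <- draw_subject_latents(cfg, 600 + s)
    rec <- generate_subject_signal(cfg, lat, "eyes_closed", seed = 700 + s)
    truth <- attr(rec, "true_density")
    dirty <- inject_artifacts(rec, cfg$artifact_spec, seed = 800 + s)
    clean <- preprocess_recording(dirty)$recording
    err(clean, truth) < err(dirty, truth)
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})
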