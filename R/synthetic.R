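#' Synthetic cohort configuration
#'
#' Defines the simulated study: a cohort of older adults, each with
#' eyes-closed and eyes-open resting recordings from the 14-channel montage
#' and two behavioral covariates (mean reaction time, accuracy). Signals
#' are sums of band-limited Gaussian noise processes, one per canonical
#' band, so power spectra are flat within bands and coherence has a clean
#' closed form.
#'
#' Band densities are one-sided spectral densities in uV^2/Hz and are
#' interpreted as *post-average-reference* expectations: because the
#' preprocessing chain re-references to the channel average, the generator
#' pre-compensates per band and subject so that the density the analysis
#' pipeline sees matches the configured target (disable with
#' `reference_compensation = FALSE`). Per-subject heterogeneity is a
#' mean-normalized lognormal multiplier on each (channel, band) density
#' with log-scale SD `subject_sd_log`.
#'
#' @param n_subjects number of subjects (>= 3); default 43.
#' @param duration_s seconds per resting condition; default 60.
#' @param sample_rate sampling rate in Hz; default 128.
#' @param band_density named numeric, baseline one-sided density per band
#'   (uV^2/Hz, same for every channel). The default alpha level equals the
#'   eyes-open occipital alpha group mean (35.65 uV^2/Hz).
#' @param ec_alpha_boost multiplicative occipital (O1, O2) alpha factor for
#'   the eyes-closed condition (>= 1). The default, 38.80 / 35.65, raises
#'   eyes-closed occipital alpha to the eyes-closed group level.
#' @param subject_sd_log SD of the per-subject, per-channel, per-band
#'   log-density latents.
#' @param planted_effects list of [planted_effect()] objects.
#' @param artifact_spec list with `blink_per_min`, `muscle_per_min`,
#'   `flat_prob` (see [inject_artifacts()]).
#' @param master_seed integer; the whole cohort is a deterministic function
#'   of the configuration and this seed.
#' @param conditions which resting conditions to generate.
#' @param reference_compensation logical, see above.
#' @param leakage_compensation logical; pre-scale generated band densities
#'   by the inverse of the Welch taper's expected band response (the Hann
#'   taper smears just under half a grid bin of density out of each band
#'   edge), so a configured density is what the spectral stage reports.
#' @param coh_base baseline coherence level at which planted coherence
#'   edges are centered.
#' @param coh_sd_logit SD of the per-subject logit-coherence latent for
#'   planted edges.
#' @param scheme a [band_scheme()].
#' @param montage an `eeg_montage`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 43, duration_s = 60,
                          sample_rate = 128,
                          band_density = c(delta = 20, theta = 15,
                                           alpha = 35.65, beta = 6,
                                           gamma = 2),
                          ec_alpha_boost = 38.80 / 35.65,
                          subject_sd_log = 0.4,
                          planted_effects = list(),
                          artifact_spec = list(blink_per_min = 6,
                                               muscle_per_min = 2,
                                               flat_prob = 0.01),
                          master_seed = 1L,
                          conditions = c("eyes_closed", "eyes_open"),
                          reference_compensation = TRUE,
                          leakage_compensation = TRUE,
                          coh_base = 0.4, coh_sd_logit = 0.5,
                          scheme = band_scheme(),
                          montage = builtin_montage()) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (!all(names(scheme$bands) %in% names(band_density)))
    stop("band_density must name every band in the scheme")
  if (any(band_density <= 0)) stop("all band densities must be > 0")
  if (ec_alpha_boost < 1) stop("ec_alpha_boost must be >= 1")
  conditions <- match.arg(conditions, c("eyes_closed", "eyes_open"),
                          several.ok = TRUE)
  for (pe in planted_effects) {
    if (!inherits(pe, "planted_effect"))
      stop("planted_effects must be a list of planted_effect objects")
    chs <- if (pe$type == "power") pe$channel else pe$channels
    if (!all(chs %in% montage$channel_names))
      stop("planted effect names a channel missing from the montage")
    if (!pe$band %in% names(scheme$bands))
      stop("planted effect names an unknown band")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_s = duration_s, sample_rate = sample_rate,
                 band_density = band_density[names(scheme$bands)],
                 ec_alpha_boost = ec_alpha_boost,
                 subject_sd_log = subject_sd_log,
                 planted_effects = planted_effects,
                 artifact_spec = artifact_spec,
                 master_seed = as.integer(master_seed),
                 conditions = conditions,
                 reference_compensation = reference_compensation,
                 leakage_compensation = leakage_compensation,
                 coh_base = coh_base, coh_sd_logit = coh_sd_logit,
                 scheme = scheme, montage = montage),
            class = "cohort_config")
}

#' Planted ground-truth effect
#'
#' Declares a known Pearson correlation between a resting-EEG feature and a
#' behavioral measure, to be planted in a synthetic cohort and recovered by
#' the correlation-mapping stage. A power feature is a (channel, band)
#' cell; a coherence feature is a (channel_i, channel_j, band) edge.
#'
#' @param channel single channel label for a power effect, or length-2
#'   vector of channel labels for a coherence-edge effect.
#' @param band band name.
#' @param measure `"mean_rt_ms"` or `"accuracy_pct"`.
#' @param rho target Pearson correlation, |rho| < 1.
#' @return An object of class `planted_effect`.
#' @examples
#' planted_effect("P8", "beta", "accuracy_pct", -0.42)
#' planted_effect(c("F3", "P7"), "alpha", "mean_rt_ms", 0.35)
#' @export
planted_effect <- function(channel, band, measure, rho) {
  measure <- match.arg(measure, c("mean_rt_ms", "accuracy_pct"))
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (length(channel) == 1) {
    structure(list(type = "power", channel = channel, band = band,
                   measure = measure, rho = rho),
              class = "planted_effect")
  } else if (length(channel) == 2) {
    structure(list(type = "coherence", channels = channel, band = band,
                   measure = measure, rho = rho),
              class = "planted_effect")
  } else stop("channel must name one channel (power) or two (coherence)")
}

# Deterministic per-subject, per-purpose seed streams below 2^31.
derive_seed <- function(master_seed, subject, purpose) {
  (as.double(master_seed) * 1000003 + subject * 10007 + purpose * 499) %%
    2147483647
}

#' Draw per-subject latents
#'
#' One standard-normal latent per (channel, band) cell driving the
#' subject's lognormal density multipliers, plus one latent per planted
#' coherence edge driving the subject's edge coherence on the logit scale.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return List with `z` (channel x band matrix) and `edge_z` (numeric,
#'   one per planted coherence effect).
#' @export
draw_subject_latents <- function(config, seed) {
  set.seed(seed)
  chans <- config$montage$channel_names
  bands <- names(config$scheme$bands)
  z <- matrix(stats::rnorm(length(chans) * length(bands)),
              nrow = length(chans), dimnames = list(chans, bands))
  n_edge <- sum(vapply(config$planted_effects,
                       function(e) e$type == "coherence", logical(1)))
  list(z = z, edge_z = stats::rnorm(n_edge))
}

# Post-reference target densities for one subject/condition:
# baseline density x mean-normalized lognormal multiplier, with the
# eyes-closed occipital alpha boost applied on top.
subject_target_density <- function(config, latents, condition) {
  chans <- config$montage$channel_names
  bands <- names(config$scheme$bands)
  s <- config$subject_sd_log
  base <- matrix(rep(config$band_density, each = length(chans)),
                 nrow = length(chans), dimnames = list(chans, bands))
  tgt <- base * exp(s * latents$z - s^2 / 2)
  if (condition == "eyes_closed" && "alpha" %in% bands) {
    occ <- intersect(c("O1", "O2"), chans)
    tgt[occ, "alpha"] <- tgt[occ, "alpha"] * config$ec_alpha_boost
  }
  tgt
}

# Expected Welch band-response matrix A: A[b, b'] is the mean density the
# spectral stage reports in measurement band b per unit generated density
# in brick-wall band b'. The Hann taper smears energy across ~2 grid bins,
# so each band loses a little under half a bin of density at each edge -
# and a strong band (occipital alpha) leaks measurably into a weak
# neighbor (beta). R(k) sums the squared taper kernel over the generated
# fine-frequency support; R_inf is the flat-spectrum (Parseval-calibrated)
# response. The generator pre-multiplies densities by solve(A) so that a
# configured density is what Welch reports.
.response_cache <- new.env(parent = emptyenv())

welch_band_response <- function(n_total, fs, epoch_s, bands) {
  key <- paste(n_total, fs, epoch_s,
               paste(unlist(bands), collapse = ","), sep = "|")
  hit <- .response_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- round(epoch_s * fs)
  w2 <- Mod(stats::fft(c(hann_window(m), rep(0, n_total - m))))^2
  r_inf <- sum(w2)
  csum <- cumsum(w2)
  wsum <- function(a, b) {           # sum of w2 over circular index range
    a <- round(a) %% n_total; b <- round(b) %% n_total
    if (a <= b) csum[b + 1] - (if (a == 0) 0 else csum[a])
    else r_inf - (csum[a] - csum[b + 1])
  }
  grid <- (0:(m %/% 2)) / epoch_s
  nb <- length(bands)
  a <- matrix(0, nb, nb, dimnames = list(names(bands), names(bands)))
  for (src in seq_len(nb)) {
    j1 <- ceiling(bands[[src]][1] * n_total / fs - 1e-9)  # fine support
    j2 <- ceiling(bands[[src]][2] * n_total / fs - 1e-9) - 1
    for (dst in seq_len(nb)) {
      bins <- band_bins(grid, bands[[dst]][1], bands[[dst]][2])
      resp <- vapply(bins, function(k) {
        kr <- (k - 1) * n_total / m
        wsum(j1 - kr, j2 - kr) / r_inf
      }, numeric(1))
      # mean density reported in dst per unit density generated in src
      a[dst, src] <- mean(resp)
    }
  }
  .response_cache[[key]] <- a
  a
}

# Invert the average-reference power map: find generated densities D such
# that after subtracting the channel mean, each channel's in-band density
# equals the target t. For n independent channels,
# post_c = D_c (1 - 2/n) + sum(D) / n^2.
compensate_reference <- function(tgt) {
  n <- nrow(tgt)
  apply(tgt, 2, function(t_c) {
    s <- sum(t_c) / (1 - 1 / n)
    d <- (t_c - s / n^2) / (1 - 2 / n)
    # extremely unbalanced draws can push the exact solution below zero;
    # floor at a sliver of the target (the correction is a small one)
    bad <- d <= 0
    d[bad] <- 1e-3 * t_c[bad]
    d
  })
}

# Subject edge coherences for planted coherence effects.
subject_edge_coherence <- function(config, latents) {
  idx <- which(vapply(config$planted_effects,
                      function(e) e$type == "coherence", logical(1)))
  if (length(idx) == 0) return(numeric(0))
  stats::plogis(stats::qlogis(config$coh_base) +
                config$coh_sd_logit * latents$edge_z[seq_along(idx)])
}

#' Generate one subject's resting EEG signal
#'
#' Synthesizes a recording as the sum of independent band-limited Gaussian
#' noise processes (frequency-domain synthesis: flat one-sided density
#' within each band, zero outside). The eyes-closed condition multiplies
#' occipital (O1, O2) alpha density by `ec_alpha_boost`. Planted coherence
#' edges are realized by adding a shared band-limited source to both
#' channels with density `sqrt(gamma) * D` per channel, which yields
#' magnitude-squared coherence exactly `gamma` in the limit.
#'
#' @param config a [cohort_config()].
#' @param subject_latents latents from [draw_subject_latents()]; `NULL`
#'   uses zero latents (baseline densities, no subject heterogeneity).
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @param seed integer seed for the signal noise.
#' @param subject_id subject label for the recording.
#' @return An `eeg_recording` (artifact-free; see [inject_artifacts()]).
#' @export
generate_subject_signal <- function(config, subject_latents = NULL,
                                    condition = "eyes_closed", seed = 1,
                                    subject_id = "S01") {
  condition <- match.arg(condition, c("eyes_closed", "eyes_open"))
  chans <- config$montage$channel_names
  bands <- config$scheme$bands
  if (is.null(subject_latents)) {
    subject_latents <- list(
      z = matrix(0, length(chans), length(bands),
                 dimnames = list(chans, names(bands))),
      edge_z = rep(0, length(config$planted_effects)))
  }
  tgt <- subject_target_density(config, subject_latents, condition)
  dens <- if (config$reference_compensation) compensate_reference(tgt)
          else tgt
  gam <- subject_edge_coherence(config, subject_latents)

  fs <- config$sample_rate
  n <- round(config$duration_s * fs)
  if (isTRUE(config$leakage_compensation)) {
    a <- welch_band_response(n, fs, spectral_config()$epoch_s, bands)
    raw <- dens
    dens <- t(apply(dens, 1, function(d) solve(a, d)))
    bad <- dens <= 0                 # same flooring as in the reference map
    dens[bad] <- 1e-3 * raw[bad]
  }
  freqs <- (seq_len(n %/% 2 - 1)) * fs / n     # positive, no DC/Nyquist
  df <- fs / n
  coef_sd <- function(d) n * sqrt(d * df) / 2  # per real/imag part

  set.seed(seed)
  spec <- matrix(complex(real = 0), nrow = n, ncol = length(chans))
  shared_frac <- matrix(0, length(chans), length(bands),
                        dimnames = list(chans, names(bands)))
  ce <- which(vapply(config$planted_effects,
                     function(e) e$type == "coherence", logical(1)))
  for (k in seq_along(ce)) {
    e <- config$planted_effects[[ce[k]]]
    shared_frac[e$channels, e$band] <-
      shared_frac[e$channels, e$band] + sqrt(gam[k])
  }
  if (any(shared_frac >= 1))
    stop("planted coherence edges overlap too strongly on one channel/band")

  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    bins <- which(freqs >= b[1] - 1e-9 & freqs < b[2] - 1e-9)
    if (length(bins) == 0) next
    nb <- length(bins)
    nch <- length(chans)
    own <- dens[, bi] * (1 - shared_frac[, bi])
    z <- matrix(complex(real = stats::rnorm(nb * nch),
                        imaginary = stats::rnorm(nb * nch)), nb, nch)
    spec[bins + 1L, ] <- spec[bins + 1L, ] +
      z * rep(coef_sd(own), each = nb)
    for (k in seq_along(ce)) {
      e <- config$planted_effects[[ce[k]]]
      if (e$band != names(bands)[bi]) next
      zs <- complex(real = stats::rnorm(nb), imaginary = stats::rnorm(nb))
      for (ch in match(e$channels, chans)) {
        sh <- sqrt(gam[k]) * dens[ch, bi]
        spec[bins + 1L, ch] <- spec[bins + 1L, ch] + coef_sd(sh) * zs
      }
    }
  }
  # Hermitian completion, then inverse FFT to a real signal
  spec[n:(n %/% 2 + 2L), ] <- Conj(spec[2:(n %/% 2), ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  data <- t(x)
  rownames(data) <- chans
  rec <- new_recording(data, fs, subject_id, condition, config$montage)
  attr(rec, "true_density") <- tgt
  rec
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds the artifact classes the preprocessing stage must cope with:
#' blinks (0.4-s raised-cosine transients, ~300 uV at AF3/AF4, decaying
#' with distance from the forehead), muscle bursts (0.5-s broadband
#' 20-46 Hz noise on a random channel), and optionally one flat channel
#' (zeroed for >= 5 s). Every injected event is annotated with onset,
#' duration and label (`blink`, `muscle`, `flat`).
#'
#' @param rec an `eeg_recording`.
#' @param spec list with `blink_per_min`, `muscle_per_min` (event rates per
#'   minute) and `flat_prob` (probability that one channel goes flat).
#' @param seed integer seed.
#' @return The recording with artifacts added and events annotated. With
#'   all rates zero the input is returned unchanged.
#' @export
inject_artifacts <- function(rec, spec = list(blink_per_min = 6,
                                              muscle_per_min = 2,
                                              flat_prob = 0.01),
                             seed = 1) {
  rate0 <- function(x) is.null(x) || x == 0
  if (rate0(spec$blink_per_min) && rate0(spec$muscle_per_min) &&
      rate0(spec$flat_prob)) return(rec)
  set.seed(seed)
  fs <- rec$sample_rate
  dur <- duration_s(rec)
  data <- rec$data
  chans <- recording_channels(rec)
  ann <- rec$annotations

  blink_n <- stats::rpois(1, (spec$blink_per_min %||% 0) * dur / 60)
  if (blink_n > 0) {
    # forehead-weighted spatial profile from montage geometry
    front <- c(0, 0.77)
    d2 <- rowSums(sweep(rec$montage$positions, 2, front)^2)
    w <- exp(-d2 / (2 * 0.3^2))
    len <- round(0.4 * fs)
    pulse <- 300 * 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
    for (i in seq_len(blink_n)) {
      onset <- stats::runif(1, 0, dur - 0.4)
      idx <- round(onset * fs) + seq_len(len)
      data[, idx] <- data[, idx] + outer(w, pulse)
      ann <- rbind(ann, data.frame(onset = onset, duration = 0.4,
                                   label = "blink"))
    }
  }
  muscle_n <- stats::rpois(1, (spec$muscle_per_min %||% 0) * dur / 60)
  if (muscle_n > 0) {
    len <- round(0.5 * fs)
    for (i in seq_len(muscle_n)) {
      onset <- stats::runif(1, 0, dur - 0.5)
      ch <- sample(chans, 1)
      burst <- bandlimited_noise(len, fs, 20, min(46, fs / 2 - 1), sd = 60)
      burst <- burst * hann_window(len)
      idx <- round(onset * fs) + seq_len(len)
      data[ch, idx] <- data[ch, idx] + burst
      ann <- rbind(ann, data.frame(onset = onset, duration = 0.5,
                                   label = "muscle"))
    }
  }
  if (!rate0(spec$flat_prob) && stats::runif(1) < spec$flat_prob &&
      dur >= 6) {
    ch <- sample(chans, 1)
    onset <- stats::runif(1, 0, dur - 6)
    idx <- round(onset * fs) + seq_len(round(6 * fs))
    data[ch, idx] <- 0
    ann <- rbind(ann, data.frame(onset = onset, duration = 6,
                                 label = "flat"))
  }
  replace_data(rec, data, annotations = validate_annotations(ann))
}

# White noise restricted to [low, high) Hz with total SD `sd`.
bandlimited_noise <- function(n, fs, low, high, sd = 1) {
  freqs <- seq_len(n %/% 2 - 1) * fs / n
  bins <- which(freqs >= low & freqs < high)
  spec <- complex(real = rep(0, n))
  z <- complex(real = stats::rnorm(length(bins)),
               imaginary = stats::rnorm(length(bins)))
  d <- sd^2 / (length(bins) * fs / n)         # flat density giving Var=sd^2
  spec[bins + 1L] <- (n * sqrt(d * fs / n) / 2) * z
  spec[n:(n %/% 2 + 2L)] <- Conj(spec[2:(n %/% 2)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate behavioral covariates with planted correlations
#'
#' For each behavioral measure, the standardized covariate is
#' `y = sum_k rho_k z_k + sqrt(1 - sum_k rho_k^2) eps`, where `z_k` is the
#' within-cohort standardized true value of the k-th planted feature tied
#' to that measure (true relative band power for power features, true edge
#' coherence for coherence features) and `eps` is independent noise. The
#' covariate is then mapped affinely to the printed behavioral scale:
#' reaction time mean 673 ms, SD 51; accuracy mean 91.56, SD 5.02, clipped
#' to \[0, 100\]. The Pearson correlation between the covariate and the
#' feature equals `rho` in expectation.
#'
#' @param features numeric matrix, subjects x planted effects, giving each
#'   subject's true feature value per effect (column order = effect order);
#'   may be `NULL` when there are no planted effects.
#' @param planted_effects list of [planted_effect()] objects.
#' @param seed integer seed.
#' @param n_subjects required when `features` is `NULL`.
#' @param rt_scale,acc_scale length-2 `c(mean, sd)` of the behavioral
#'   scales.
#' @return Data frame with columns `mean_rt_ms` and `accuracy_pct`.
#' @export
generate_behavior_covariates <- function(features, planted_effects, seed,
                                         n_subjects = NULL,
                                         rt_scale = c(mean = 673, sd = 51),
                                         acc_scale = c(mean = 91.56,
                                                       sd = 5.02)) {
  if (is.null(features)) {
    if (is.null(n_subjects)) stop("n_subjects needed when features is NULL")
    features <- matrix(numeric(0), nrow = n_subjects, ncol = 0)
  }
  features <- as.matrix(features)
  if (ncol(features) != length(planted_effects))
    stop("one feature column per planted effect is required")
  n <- nrow(features)
  set.seed(seed)
  std <- function(y) {
    mu <- mean(y); s <- stats::sd(y)
    if (s == 0) stop("planted feature has zero variance across the cohort")
    (y - mu) / s
  }
  measure_y <- function(measure) {
    idx <- which(vapply(planted_effects, function(e) e$measure == measure,
                        logical(1)))
    rhos <- vapply(planted_effects[idx], `[[`, numeric(1), "rho")
    eps <- stats::rnorm(n)
    if (length(idx) == 0) return(eps)
    z <- vapply(idx, function(j) std(features[, j]), numeric(n))
    # features tied to one measure may be correlated (e.g. relative powers
    # sharing a channel): solve the joint system so that cor(y, z_k) =
    # rho_k for every k, y = z a + c eps with a = S^-1 rho
    s <- stats::cor(z)
    a <- solve(s, rhos)
    c2 <- 1 - sum(rhos * a)
    if (c2 <= 0)
      stop("conflicting planted effects on ", measure,
           ": requested correlations are jointly infeasible")
    drop(z %*% a) + sqrt(c2) * eps
  }
  rt <- rt_scale[["mean"]] + rt_scale[["sd"]] * measure_y("mean_rt_ms")
  acc <- acc_scale[["mean"]] + acc_scale[["sd"]] * measure_y("accuracy_pct")
  data.frame(mean_rt_ms = rt,
             accuracy_pct = pmin(100, pmax(0, acc)))
}

# True feature value (on the measured scale) of one planted effect for one
# subject: relative band power for power effects, edge coherence for
# coherence effects. Power features use the eyes-closed condition, the one
# the correlation maps analyze.
true_feature_value <- function(config, latents, effect, edge_gamma) {
  if (effect$type == "power") {
    tgt <- subject_target_density(config, latents, "eyes_closed")
    widths <- vapply(config$scheme$bands, function(b) b[2] - b[1],
                     numeric(1))
    ip <- tgt[effect$channel, ] * widths
    unname(ip[effect$band] / sum(ip))
  } else {
    ce <- which(vapply(config$planted_effects,
                       function(e) e$type == "coherence", logical(1)))
    k <- match(list(effect[c("channels", "band", "measure", "rho")]),
               lapply(config$planted_effects[ce],
                      function(e) e[c("channels", "band", "measure", "rho")]))
    edge_gamma[k]
  }
}

#' Generate a full synthetic cohort
#'
#' Deterministically expands a [cohort_config()] into per-subject resting
#' recordings (per condition, with artifacts injected), a behavioral
#' covariate table, and the ground truth needed to verify recovery.
#' Per-subject random streams are derived from `master_seed` by stable
#' arithmetic hashing, so regenerating with the same configuration is
#' bit-identical and each subject's signals are independent of the others'.
#'
#' @param config a [cohort_config()].
#' @return List with elements:
#'   `recordings` - list of `eeg_recording` (subjects x conditions);
#'   `behavior` - data frame (subject, mean_rt_ms, accuracy_pct);
#'   `ground_truth` - per-subject latents, true post-reference densities,
#'   true planted-feature values, per-subject seeds and the echoed effects.
#' @examples
#' cfg <- cohort_config(n_subjects = 3, duration_s = 12,
#'                      artifact_spec = list(blink_per_min = 0,
#'                                           muscle_per_min = 0,
#'                                           flat_prob = 0))
#' cohort <- generate_cohort(cfg)
#' length(cohort$recordings)  # 3 subjects x 2 conditions
#' @export
generate_cohort <- function(config) {
  n <- config$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  latents <- vector("list", n)
  recs <- list()
  truth_density <- list()
  feat <- matrix(NA_real_, n, length(config$planted_effects))
  for (i in seq_len(n)) {
    latents[[i]] <- draw_subject_latents(config,
                                         derive_seed(config$master_seed, i, 1))
    gam <- subject_edge_coherence(config, latents[[i]])
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      rec <- generate_subject_signal(config, latents[[i]], cond,
                                     seed = derive_seed(config$master_seed,
                                                        i, 1 + ci),
                                     subject_id = ids[i])
      truth_density[[paste(ids[i], cond, sep = ".")]] <-
        attr(rec, "true_density")
      rec <- inject_artifacts(rec, config$artifact_spec,
                              seed = derive_seed(config$master_seed, i,
                                                 11 + ci))
      recs[[paste(ids[i], cond, sep = ".")]] <- rec
    }
    for (k in seq_along(config$planted_effects))
      feat[i, k] <- true_feature_value(config, latents[[i]],
                                       config$planted_effects[[k]], gam)
  }
  behavior <- generate_behavior_covariates(
    if (length(config$planted_effects)) feat else NULL,
    config$planted_effects,
    seed = derive_seed(config$master_seed, 0, 9),
    n_subjects = n)
  behavior <- cbind(data.frame(subject = ids, stringsAsFactors = FALSE),
                    behavior)
  ground_truth <- list(latents = stats::setNames(latents, ids),
                       true_density = truth_density,
                       planted_features = feat,
                       planted_effects = config$planted_effects,
                       behavior = behavior,
                       master_seed = config$master_seed)
  list(recordings = recs, behavior = behavior, ground_truth = ground_truth)
}
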