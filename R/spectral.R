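#' Welch spectral-estimation configuration
#'
#' Defaults mirror the pipeline's analysis parameters: 4-s epochs with 2-s
#' overlap at 128 Hz give a 0.25 Hz frequency grid over the 1-46 Hz span.
#' The taper is a Hann window (50% overlap satisfies constant-overlap-add);
#' densities are compensated for the taper's power loss.
#'
#' @param epoch_s epoch (segment) length in seconds.
#' @param overlap_s overlap between consecutive epochs in seconds
#'   (must be < `epoch_s`).
#' @param taper taper name; only `"hann"` is implemented.
#' @param span analysis span in Hz, used by band integration.
#' @return An object of class `spectral_config`; `resolution_hz` is the
#'   derived grid spacing `1 / epoch_s`.
#' @export
spectral_config <- function(epoch_s = 4, overlap_s = 2, taper = "hann",
                            span = c(1, 46)) {
  if (overlap_s >= epoch_s) stop("overlap_s must be smaller than epoch_s")
  taper <- match.arg(taper, "hann")
  structure(list(epoch_s = epoch_s, overlap_s = overlap_s, taper = taper,
                 resolution_hz = 1 / epoch_s, span = span),
            class = "spectral_config")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Tapered FFT segments shared by PSD and cross-spectral estimation, so the
# coherence ratio is internally consistent (same segmentation for Gxx, Gyy
# and Gxy). Returns complex array (freq bin x segment x channel) plus the
# one-sided density scale factor.
welch_segments <- function(rec, cfg) {
  fs <- rec$sample_rate
  n_seg <- round(cfg$epoch_s * fs)
  hop <- round((cfg$epoch_s - cfg$overlap_s) * fs)
  n <- n_samples(rec)
  if (n < n_seg)
    stop("insufficient data: recording shorter than one epoch (",
         cfg$epoch_s, " s)")
  starts <- seq(1L, n - n_seg + 1L, by = hop)
  k <- length(starts)
  w <- hann_window(n_seg)
  nfreq <- n_seg %/% 2 + 1L
  chans <- recording_channels(rec)
  seg_idx <- outer(seq_len(n_seg) - 1L, starts, `+`)   # n_seg x k
  # gather all segments of all channels and run one batched FFT
  gath <- t(rec$data[, as.vector(seg_idx), drop = FALSE])
  segs <- array(gath, dim = c(n_seg, k, length(chans))) * w
  sp <- stats::mvfft(matrix(segs, nrow = n_seg))
  out <- array(sp[seq_len(nfreq), , drop = FALSE],
               dim = c(nfreq, k, length(chans)),
               dimnames = list(NULL, NULL, chans))
  list(fft = out, n_segments = k,
       frequencies = (seq_len(nfreq) - 1L) / cfg$epoch_s,
       # one-sided density scale: 2 / (fs * sum(w^2)); DC/Nyquist get half
       scale = 2 / (fs * sum(w^2)))
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered periodograms over overlapping segments, scaled to a
#' one-sided density in uV^2/Hz so the integral over all frequencies equals
#' the (taper-compensated) mean per-segment variance.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [spectral_config()].
#' @return An object of class `psd_result`: `frequencies` (Hz grid at
#'   `resolution_hz` spacing), `density` (channel x frequency matrix,
#'   uV^2/Hz), `n_segments`.
#' @examples
#' rec <- generate_subject_signal(cohort_config(duration_s = 12),
#'                                condition = "eyes_closed", seed = 1)
#' psd <- welch_psd(rec)
#' diff(psd$frequencies)[1]  # 0.25 Hz
#' @export
welch_psd <- function(rec, cfg = spectral_config()) {
  ws <- welch_segments(rec, cfg)
  nfreq <- length(ws$frequencies)
  m2 <- Mod(ws$fft)^2
  dens <- vapply(seq_len(dim(m2)[3]),
                 function(ci) rowMeans(m2[, , ci, drop = FALSE]),
                 numeric(nfreq)) * ws$scale
  colnames(dens) <- dimnames(ws$fft)[[3]]
  dens[1, ] <- dens[1, ] / 2                  # DC is not doubled
  dens[nfreq, ] <- dens[nfreq, ] / 2          # nor is Nyquist
  structure(list(frequencies = ws$frequencies, density = t(dens),
                 n_segments = ws$n_segments, config = cfg),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d channels x %d bins (%g-%g Hz, df = %g Hz), K = %d segments\n",
              nrow(x$density), length(x$frequencies), min(x$frequencies),
              max(x$frequencies), x$frequencies[2] - x$frequencies[1],
              x$n_segments))
  invisible(x)
}

band_bins <- function(frequencies, low, high) {
  which(frequencies >= low - 1e-9 & frequencies < high - 1e-9)
}

#' Band power from a PSD
#'
#' Integrated band power (bin sum times the grid resolution) and mean
#' absolute density (integrated power / bandwidth) per channel and band.
#' Bins are assigned to bands by half-open interval `[low, high)` on the
#' bin center, so shared band edges are counted exactly once.
#'
#' @param psd a `psd_result` from [welch_psd()].
#' @param scheme a [band_scheme()].
#' @return Data frame with columns `channel`, `band`, `absolute_density`
#'   (uV^2/Hz), `integrated_power` (uV^2).
#' @export
band_power <- function(psd, scheme = band_scheme()) {
  df <- psd$frequencies[2] - psd$frequencies[1]
  span <- range(psd$frequencies)
  chans <- rownames(psd$density)
  ip <- vapply(names(scheme$bands), function(bn) {
    b <- scheme$bands[[bn]]
    if (b[1] < span[1] - 1e-9 || b[2] > span[2] + df + 1e-9)
      stop("band ", bn, " lies outside the PSD frequency span")
    bins <- band_bins(psd$frequencies, b[1], b[2])
    rowSums(psd$density[, bins, drop = FALSE]) * df
  }, numeric(length(chans)))
  if (!is.matrix(ip)) ip <- matrix(ip, nrow = length(chans),
                                   dimnames = list(chans, names(scheme$bands)))
  widths <- vapply(scheme$bands, function(b) b[2] - b[1], numeric(1))
  data.frame(channel = rep(chans, times = length(scheme$bands)),
             band = rep(names(scheme$bands), each = length(chans)),
             absolute_density = as.vector(sweep(ip, 2, widths, "/")),
             integrated_power = as.vector(ip),
             stringsAsFactors = FALSE)
}

#' Relative band power
#'
#' Adds (or recomputes) `relative_power`: each band's integrated power as a
#' fraction of the total integrated power over the analysis span, per
#' channel (and per subject/condition when those columns are present).
#' Relative powers over the five bands sum to 1 for each channel.
#'
#' @param table a band-power data frame from [band_power()] (optionally
#'   with `subject` / `condition` columns).
#' @return The table with a `relative_power` column.
#' @export
relative_band_power <- function(table) {
  keys <- intersect(c("subject", "condition", "channel"), names(table))
  key <- do.call(paste, c(table[keys], sep = "\r"))
  tot <- tapply(table$integrated_power, key, sum)
  total <- as.numeric(tot[key])
  if (any(total <= 0))
    stop("relative power undefined: zero total power for some channel")
  table$relative_power <- table$integrated_power / total
  table
}

#' Magnitude-squared coherence spectrum for a channel pair
#'
#' `Coh_xy(f) = |G_xy(f)|^2 / (G_xx(f) G_yy(f))` with auto- and
#' cross-spectral densities averaged over the same Welch segmentation.
#' With a single segment the estimate is identically 1, so at least two
#' segments are required. For independent signals the estimator's known
#' positive bias is about `1/K` for K averaged segments.
#'
#' @param rec an `eeg_recording`.
#' @param pair character length-2, the two channel labels.
#' @param cfg a [spectral_config()].
#' @return List with `frequencies` and `coherence` (values in \[0, 1\]).
#' @export
ms_coherence <- function(rec, pair, cfg = spectral_config()) {
  stopifnot(length(pair) == 2)
  if (!all(pair %in% recording_channels(rec)))
    stop("both channels of the pair must be present in the recording")
  ws <- welch_segments(rec, cfg)
  if (ws$n_segments < 2)
    stop("coherence needs at least 2 Welch segments (K >= 2)")
  x <- ws$fft[, , pair[1]]
  y <- ws$fft[, , pair[2]]
  gxx <- rowMeans(Mod(x)^2)
  gyy <- rowMeans(Mod(y)^2)
  gxy <- rowMeans(x * Conj(y))
  denom <- gxx * gyy
  coh <- numeric(length(denom))
  ok <- denom > 0
  if (!all(ok))
    warning("zero auto-spectrum at ", sum(!ok), " bin(s); coherence set to 0")
  coh[ok] <- Mod(gxy[ok])^2 / denom[ok]
  list(frequencies = ws$frequencies, coherence = coh)
}

#' Band-averaged coherence network
#'
#' Magnitude-squared coherence for every unordered channel pair (91 pairs
#' for the 14-channel montage), averaged over each band's frequency bins.
#' All pairwise spectra come from one shared Welch segmentation.
#'
#' @param rec an `eeg_recording` (cleaned).
#' @param scheme a [band_scheme()].
#' @param cfg a [spectral_config()].
#' @return An object of class `coherence_network`: a named list of symmetric
#'   channel x channel matrices (one per band, diagonal exactly 1) with
#'   attributes `subject` and `condition`.
#' @export
band_coherence_network <- function(rec, scheme = band_scheme(),
                                   cfg = spectral_config()) {
  ws <- welch_segments(rec, cfg)
  if (ws$n_segments < 2)
    stop("coherence needs at least 2 Welch segments (K >= 2)")
  chans <- recording_channels(rec)
  nc <- length(chans)
  nfreq <- length(ws$frequencies)
  coh <- array(0, dim = c(nc, nc, nfreq))
  for (fi in seq_len(nfreq)) {
    m <- ws$fft[fi, , ]                      # segments x channels
    g <- crossprod(Conj(m), m) / ws$n_segments
    auto <- Re(diag(g))
    denom <- outer(auto, auto)
    cm <- matrix(0, nc, nc)
    ok <- denom > 0
    cm[ok] <- Mod(g[ok])^2 / denom[ok]
    diag(cm)[auto > 0] <- 1
    coh[, , fi] <- cm
  }
  nets <- lapply(names(scheme$bands), function(bn) {
    b <- scheme$bands[[bn]]
    bins <- band_bins(ws$frequencies, b[1], b[2])
    m <- apply(coh[, , bins, drop = FALSE], c(1, 2), mean)
    m <- (m + t(m)) / 2          # estimator is symmetric; make it exact
    diag(m) <- 1
    dimnames(m) <- list(chans, chans)
    m
  })
  names(nets) <- names(scheme$bands)
  structure(nets, class = "coherence_network",
            subject = rec$subject_id, condition = rec$condition)
}

#' Long-format band-power table for a set of recordings
#'
#' Runs [welch_psd()], [band_power()] and [relative_band_power()] on each
#' recording and stacks the results with `subject` and `condition` columns
#' - the `BandPowerTable` consumed by the correlation-mapping stage.
#'
#' @param recordings list of `eeg_recording` objects.
#' @param scheme a [band_scheme()].
#' @param cfg a [spectral_config()].
#' @return Data frame with columns `subject`, `condition`, `channel`,
#'   `band`, `absolute_density`, `integrated_power`, `relative_power`.
#' @export
band_power_table <- function(recordings, scheme = band_scheme(),
                             cfg = spectral_config()) {
  rows <- lapply(recordings, function(rec) {
    bp <- band_power(welch_psd(rec, cfg), scheme)
    cbind(data.frame(subject = rec$subject_id, condition = rec$condition,
                     stringsAsFactors = FALSE), bp)
  })
  relative_band_power(do.call(rbind, rows))
}

#' Coherence edge list for a set of recordings
#'
#' @param recordings list of `eeg_recording` objects.
#' @param scheme a [band_scheme()].
#' @param cfg a [spectral_config()].
#' @return Long data frame (subject, condition, band, ch_i, ch_j,
#'   coherence), one row per unordered off-diagonal pair.
#' @export
coherence_edge_table <- function(recordings, scheme = band_scheme(),
                                 cfg = spectral_config()) {
  rows <- lapply(recordings, function(rec) {
    net <- band_coherence_network(rec, scheme, cfg)
    do.call(rbind, lapply(names(net), function(bn) {
      m <- net[[bn]]
      idx <- which(upper.tri(m), arr.ind = TRUE)
      data.frame(subject = rec$subject_id, condition = rec$condition,
                 band = bn, ch_i = rownames(m)[idx[, 1]],
                 ch_j = colnames(m)[idx[, 2]], coherence = m[idx],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
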