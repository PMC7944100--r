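#' EEG recording container
#'
#' One subject/condition multichannel EEG time series. Data are stored as a
#' channel-by-sample matrix in microvolts; rows are named by and ordered as
#' the montage channels. Time is seconds from recording start; epoch windows
#' throughout the package are half-open `[t0, t0 + T)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz (> 0); the wireless headset the
#'   pipeline models records at 128 Hz.
#' @param subject_id subject identifier string.
#' @param condition one of `"eyes_open"`, `"eyes_closed"`, `"task"`.
#' @param montage an `eeg_montage` whose channels match `rownames(data)`.
#' @param annotations data frame with columns `onset` (s), `duration` (s),
#'   `label`; may have zero rows.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, sample_rate, subject_id, condition,
                          montage, annotations = empty_annotations()) {
  data <- as.matrix(data)
  condition <- match.arg(condition, c("eyes_open", "eyes_closed", "task"))
  if (!inherits(montage, "eeg_montage")) stop("montage must be an eeg_montage")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  if (nrow(data) != length(montage$channel_names))
    stop("data row count must equal montage channel count")
  if (is.null(rownames(data))) rownames(data) <- montage$channel_names
  if (!identical(rownames(data), montage$channel_names))
    stop("data rownames must match montage channel order")
  if (anyNA(data)) stop("recording must not contain missing samples")
  annotations <- validate_annotations(annotations)
  structure(list(data = data, sample_rate = sample_rate,
                 subject_id = as.character(subject_id),
                 condition = condition, montage = montage,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @rdname new_recording
#' @export
empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

validate_annotations <- function(annotations) {
  if (!is.data.frame(annotations) ||
      !all(c("onset", "duration", "label") %in% names(annotations)))
    stop("annotations must be a data frame with onset, duration, label")
  annotations <- annotations[, c("onset", "duration", "label"), drop = FALSE]
  annotations$onset <- as.numeric(annotations$onset)
  annotations$duration <- as.numeric(annotations$duration)
  annotations$label <- as.character(annotations$label)
  rownames(annotations) <- NULL
  annotations
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, %s: %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$sample_rate, n_samples(x) / x$sample_rate,
              nrow(x$annotations)))
  invisible(x)
}

#' Recording helpers
#'
#' `n_samples()` and `duration_s()` return the sample count and duration in
#' seconds; `recording_channels()` returns the channel labels;
#' `drop_channels()` removes channels (e.g. rejected ones) from data and
#' montage rather than padding them.
#'
#' @param rec an `eeg_recording`.
#' @name recording-helpers
NULL

#' @rdname recording-helpers
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording-helpers
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sample_rate

#' @rdname recording-helpers
#' @export
recording_channels <- function(rec) rec$montage$channel_names

#' @rdname recording-helpers
#' @param channels channel labels to remove.
#' @export
drop_channels <- function(rec, channels) {
  keep <- setdiff(recording_channels(rec), channels)
  if (length(keep) == 0) stop("cannot drop all channels")
  montage <- subset_montage(rec$montage, keep)
  new_recording(rec$data[keep, , drop = FALSE], rec$sample_rate,
                rec$subject_id, rec$condition, montage, rec$annotations)
}

#' Replace the data matrix of a recording, keeping metadata
#' @param rec an `eeg_recording`.
#' @param data replacement channels x samples matrix (same channels).
#' @param annotations optional replacement annotations.
#' @keywords internal
replace_data <- function(rec, data, annotations = rec$annotations) {
  rownames(data) <- recording_channels(rec)
  new_recording(data, rec$sample_rate, rec$subject_id, rec$condition,
                rec$montage, annotations)
}
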