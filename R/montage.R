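#' EEG montages
#'
#' A montage is the ordered set of electrode labels together with 2-D
#' head-plane coordinates (unitless, head radius 1, x toward the right ear,
#' y toward the nasion). All downstream tables index channels by name, never
#' by row position, so subsetting a montage is always safe.
#'
#' @param channel_names character vector of unique electrode labels.
#' @param positions numeric matrix with one row per channel and columns
#'   `x`, `y`; every position must lie strictly inside the unit circle.
#' @return An object of class `eeg_montage`: a list with elements
#'   `channel_names` and `positions`.
#' @export
new_montage <- function(channel_names, positions) {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_names) > 0)
    stop("montage channel names must be unique")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 2)
    stop("positions must be a (n_channels x 2) matrix")
  r <- sqrt(rowSums(positions^2))
  if (any(r >= 1))
    stop("all montage positions must lie strictly inside the unit circle")
  rownames(positions) <- channel_names
  colnames(positions) <- c("x", "y")
  structure(list(channel_names = channel_names, positions = positions),
            class = "eeg_montage")
}

#' Built-in 14-channel wireless headset montage
#'
#' The 10-20-subset montage of the 14-channel consumer wireless headset,
#' in its conventional channel order: AF3, F7, F3, FC5, T7, P7, O1, O2,
#' P8, T8, FC6, F4, F8, AF4. Left/right homolog pairs have mirrored
#' x-coordinates.
#'
#' @return An `eeg_montage` with exactly 14 channels.
#' @examples
#' m <- builtin_montage()
#' m$channel_names
#' @export
builtin_montage <- function() {
  pos <- rbind(
    AF3 = c(-0.29,  0.77),
    F7  = c(-0.77,  0.48),
    F3  = c(-0.35,  0.45),
    FC5 = c(-0.62,  0.25),
    T7  = c(-0.95,  0.00),
    P7  = c(-0.77, -0.48),
    O1  = c(-0.29, -0.90),
    O2  = c( 0.29, -0.90),
    P8  = c( 0.77, -0.48),
    T8  = c( 0.95,  0.00),
    FC6 = c( 0.62,  0.25),
    F4  = c( 0.35,  0.45),
    F8  = c( 0.77,  0.48),
    AF4 = c( 0.29,  0.77)
  )
  new_montage(rownames(pos), pos)
}

#' Subset a montage to a set of channels, preserving order
#' @param montage an `eeg_montage`.
#' @param channels character vector of channel labels to keep.
#' @return An `eeg_montage` restricted to `channels` in montage order.
#' @export
subset_montage <- function(montage, channels) {
  keep <- montage$channel_names[montage$channel_names %in% channels]
  if (length(keep) == 0) stop("no channels left after subsetting montage")
  new_montage(keep, montage$positions[keep, , drop = FALSE])
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$channel_names), " channels: ",
      paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Frequency band scheme
#'
#' The canonical EEG band partition of the 1-46 Hz analysis span:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-28, gamma 28-46 Hz. Bands are
#' half-open intervals `[low, high)` so shared edges are counted exactly
#' once, in the upper band. The default scheme must be contiguous,
#' non-overlapping and cover the analysis span.
#'
#' @param bands named list of `c(low, high)` pairs in Hz, in ascending order.
#' @param analysis_span numeric length-2, the full span the bands must tile.
#' @return An object of class `band_scheme` with elements `bands` (named
#'   list) and `analysis_span`.
#' @export
band_scheme <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 28),
                                     gamma = c(28, 46)),
                        analysis_span = c(1, 46)) {
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("bands must be named")
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(highs <= lows)) stop("each band needs low < high")
  if (lows[1] != analysis_span[1] || highs[length(bands)] != analysis_span[2])
    stop("bands must cover the analysis span")
  if (length(bands) > 1 && any(abs(highs[-length(bands)] - lows[-1]) > 1e-12))
    stop("bands must be contiguous and non-overlapping")
  structure(list(bands = bands, analysis_span = analysis_span),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>\n")
  for (nm in names(x$bands))
    cat(sprintf("  %-6s %g-%g Hz\n", nm, x$bands[[nm]][1], x$bands[[nm]][2]))
  invisible(x)
}
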