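#' Write a recording in the internal fixture format
#'
#' The fixture format is one binary matrix file (IEEE-754 doubles,
#' little-endian, channel-major) plus a JSON sidecar (`<path>.json`) with
#' subject, condition, sample rate, channel names, montage positions and
#' annotations. [read_recording()] inverts it bit-exactly, which makes
#' round-trip tests and file diffs trivial.
#'
#' @param rec an `eeg_recording`.
#' @param path output path for the matrix file; the sidecar is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  meta <- list(format = "resteeg-fixture", version = 1L,
               subject_id = rec$subject_id, condition = rec$condition,
               sample_rate = rec$sample_rate,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               channels = recording_channels(rec),
               positions = unname(apply(rec$montage$positions, 1, c,
                                        simplify = FALSE)),
               annotations = rec$annotations)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_fixture <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("fixture sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$format, "resteeg-fixture"))
    stop("not a resteeg fixture: ", path)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("fixture data file truncated: ", path)
  data <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  rownames(data) <- meta$channels
  pos <- if (is.matrix(meta$positions)) meta$positions else
    do.call(rbind, lapply(meta$positions, unlist))
  montage <- new_montage(meta$channels, pos)
  ann <- if (length(meta$annotations) == 0) empty_annotations() else
    as.data.frame(meta$annotations)
  new_recording(data, meta$sample_rate, meta$subject_id, meta$condition,
                montage, ann)
}

#' Read an EEG recording from disk
#'
#' Supported formats: the package's own fixture format (exact round trip
#' of [write_fixture()]), EDF (16-bit European Data Format; physical
#' dimensions are honored and converted to microvolts, unknown units are
#' rejected), and XDF (one regular-rate numeric EEG stream). Channels are
#' matched by label onto `montage` and reordered to montage order;
#' channels the montage does not know are dropped with a warning.
#'
#' @param path file path.
#' @param format `"fixture"`, `"edf"` or `"xdf"`; the default guesses from
#'   the file extension.
#' @param montage montage the channels must map onto (EDF/XDF only; the
#'   fixture format stores its own montage).
#' @param subject_id,condition metadata for formats that do not carry them.
#' @return An `eeg_recording` in microvolts at the file's native sample
#'   rate.
#' @export
read_recording <- function(path, format = c("auto", "fixture", "edf", "xdf"),
                           montage = builtin_montage(),
                           subject_id = "unknown",
                           condition = "eyes_closed") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", xdf = "xdf", "fixture")
  }
  switch(format,
         fixture = read_fixture(path),
         edf = read_edf(path, montage, subject_id, condition),
         xdf = read_xdf(path, montage, subject_id, condition))
}

map_to_montage <- function(data, labels, montage) {
  labels <- trimws(sub("^EEG[ .]*", "", labels))
  known <- labels %in% montage$channel_names
  if (!any(known))
    stop("montage error: no channel labels map onto the montage")
  if (any(!known))
    warning("dropping unknown channel(s): ",
            paste(labels[!known], collapse = ", "))
  data <- data[known, , drop = FALSE]
  labels <- labels[known]
  ord <- montage$channel_names[montage$channel_names %in% labels]
  data <- data[match(ord, labels), , drop = FALSE]
  rownames(data) <- ord
  list(data = data, montage = subset_montage(montage, ord))
}

edf_unit_scale <- function(dim) {
  dim <- trimws(dim)
  if (dim %in% c("uV", "µV", "μV")) return(1)
  if (dim == "mV") return(1e3)
  if (dim == "V") return(1e6)
  stop("unknown EDF physical dimension '", dim,
       "': expected uV, mV or V")
}

# Minimal EDF reader: 16-bit samples, identical sampling rate across the
# mapped signals, physical scaling honored. EDF+ annotation signals are
# ignored.
read_edf <- function(path, montage, subject_id, condition) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) rawToChar(readBin(con, "raw", n))
  hdr <- rd_str(256)
  if (nchar(hdr) < 256) stop("format error: truncated EDF header")
  n_records <- as.integer(substr(hdr, 237, 244))
  record_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1) stop("format error: bad EDF signal count")
  field <- function(width) {
    vapply(seq_len(ns), function(i) rd_str(width), character(1))
  }
  labels <- trimws(field(16))
  field(80)                                   # transducer
  phys_dim <- field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                   # prefiltering
  spr <- as.integer(field(8))                 # samples per record
  field(32)                                   # reserved
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[i]) stop("format error: truncated EDF data")
      sig[[i]][[r]] <- raw
    }
  }
  idx <- which(keep)
  if (length(unique(spr[idx])) != 1)
    stop("format error: EDF signals with differing sampling rates")
  data <- do.call(rbind, lapply(idx, function(i) {
    dig <- unlist(sig[[i]])
    phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
      (dig_max[i] - dig_min[i]) + phys_min[i]
    phys * edf_unit_scale(phys_dim[i])
  }))
  fs <- spr[idx[1]] / record_dur
  m <- map_to_montage(data, labels[idx], montage)
  new_recording(m$data, fs, subject_id, condition, m$montage)
}

# Minimal EDF writer (testing / interchange): one data record per second,
# 16-bit, physical range set from the data.
write_edf <- function(rec, path, phys_dim = "uV") {
  fs <- rec$sample_rate
  if (fs != round(fs)) stop("EDF writer needs an integer sample rate")
  n_rec <- floor(duration_s(rec))
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(data)
  pmin_ <- floor(min(data) - 1)
  pmax_ <- ceiling(max(data) + 1)
  dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad("subject", 80)); wr(pad("recording", 80))
  wr(pad("01.01.20", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 * (1 + ns), 8)); wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad("1", 8)); wr(pad(ns, 4))
  for (lb in rownames(data)) wr(pad(lb, 16))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(phys_dim, 8))
  for (i in seq_len(ns)) wr(pad(pmin_, 8))
  for (i in seq_len(ns)) wr(pad(pmax_, 8))
  for (i in seq_len(ns)) wr(pad(dmin, 8))
  for (i in seq_len(ns)) wr(pad(dmax, 8))
  for (i in seq_len(ns)) wr(pad("", 80))
  for (i in seq_len(ns)) wr(pad(fs, 8))
  for (i in seq_len(ns)) wr(pad("", 32))
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      x <- data[i, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((x - pmin_) * scale + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Write a generated cohort to disk
#'
#' Persists a cohort from [generate_cohort()] as a directory of fixture
#' files (one per recording, named `<subject>.<condition>.eeg`), a
#' `behavior.csv` covariate table, and a `ground_truth.json` with the
#' per-subject latents, true post-reference densities, planted-feature
#' values and the master seed — everything needed to verify recovery
#' against the generated data later.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$recordings))
    write_fixture(cohort$recordings[[nm]], file.path(dir,
                                                     paste0(nm, ".eeg")))
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  gt$planted_effects <- lapply(gt$planted_effects, unclass)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

# --- minimal XDF support -------------------------------------------------

xdf_read_chunks <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 4 || rawToChar(raw[1:4]) != "XDF:")
    stop("format error: missing XDF magic")
  pos <- 5L
  chunks <- list()
  u <- function(bytes) {
    sum(as.double(as.integer(bytes)) * 256^(seq_along(bytes) - 1))
  }
  while (pos <= length(raw)) {
    nb <- as.integer(raw[pos]); pos <- pos + 1L
    if (!nb %in% c(1L, 4L, 8L)) stop("format error: bad XDF length field")
    len <- u(raw[pos:(pos + nb - 1L)]); pos <- pos + nb
    tag <- u(raw[pos:(pos + 1L)])
    content <- raw[(pos + 2L):(pos + len - 1L)]
    pos <- pos + len
    chunks[[length(chunks) + 1L]] <- list(tag = tag, content = content)
  }
  chunks
}

xdf_u32 <- function(bytes) {
  sum(as.double(as.integer(bytes[1:4])) * 256^(0:3))
}

# Minimal XDF reader: one regular-rate numeric stream (float32 or double64)
# is selected - the stream whose type is EEG if present, else the first
# numeric stream. Values are taken to be microvolts.
read_xdf <- function(path, montage, subject_id, condition) {
  chunks <- xdf_read_chunks(path)
  headers <- list()
  for (ch in chunks) {
    if (ch$tag == 2) {
      id <- xdf_u32(ch$content)
      xml <- xml2::read_xml(rawToChar(ch$content[-(1:4)]))
      fmt <- xml2::xml_text(xml2::xml_find_first(xml, ".//channel_format"))
      headers[[as.character(id)]] <- list(
        id = id,
        type = xml2::xml_text(xml2::xml_find_first(xml, ".//type")),
        n_channels = as.integer(xml2::xml_text(
          xml2::xml_find_first(xml, ".//channel_count"))),
        srate = as.numeric(xml2::xml_text(
          xml2::xml_find_first(xml, ".//nominal_srate"))),
        format = fmt,
        labels = xml2::xml_text(xml2::xml_find_all(
          xml, ".//desc//channel/label")))
    }
  }
  if (length(headers) == 0) stop("format error: XDF file has no streams")
  numeric_ok <- vapply(headers, function(h)
    h$format %in% c("float32", "double64"), logical(1))
  eeg <- vapply(headers, function(h)
    identical(toupper(h$type), "EEG"), logical(1))
  pick <- if (any(eeg & numeric_ok)) which(eeg & numeric_ok)[1] else
    if (any(numeric_ok)) which(numeric_ok)[1] else
      stop("format error: no numeric XDF stream")
  h <- headers[[pick]]
  size <- if (h$format == "float32") 4L else 8L
  samples <- list()
  for (ch in chunks) {
    if (ch$tag != 3) next
    if (xdf_u32(ch$content) != h$id) next
    b <- ch$content
    pos <- 5L
    nb <- as.integer(b[pos]); pos <- pos + 1L
    nsamp <- sum(as.double(as.integer(b[pos:(pos + nb - 1L)])) *
                   256^(seq_len(nb) - 1))
    pos <- pos + nb
    vals <- matrix(NA_real_, h$n_channels, nsamp)
    for (k in seq_len(nsamp)) {
      tsb <- as.integer(b[pos]); pos <- pos + 1L
      if (tsb == 8L) pos <- pos + 8L
      else if (tsb != 0L) stop("format error: bad XDF timestamp field")
      nbytes <- size * h$n_channels
      vals[, k] <- readBin(b[pos:(pos + nbytes - 1L)], "double",
                           n = h$n_channels, size = size,
                           endian = "little")
      pos <- pos + nbytes
    }
    samples[[length(samples) + 1L]] <- vals
  }
  if (length(samples) == 0) stop("format error: XDF stream has no samples")
  data <- do.call(cbind, samples)
  labels <- if (length(h$labels) == h$n_channels) h$labels else
    paste0("CH", seq_len(h$n_channels))
  m <- map_to_montage(data, labels, montage)
  new_recording(m$data, h$srate, subject_id, condition, m$montage)
}

# Minimal XDF writer (testing / interchange): one stream, no timestamps
# per sample beyond the required flag bytes.
write_xdf <- function(rec, path, format = c("float32", "double64")) {
  format <- match.arg(format)
  size <- if (format == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("XDF:"), con)
  chunk <- function(tag, content) {
    len <- length(content) + 2L
    writeBin(as.raw(4L), con)
    writeBin(as.integer(len), con, size = 4, endian = "little")
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(content, con)
  }
  chunk(1L, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>"))
  labels <- paste0("<channel><label>", recording_channels(rec),
                   "</label></channel>", collapse = "")
  hdr <- sprintf(paste0(
    "<?xml version=\"1.0\"?><info><name>sim</name><type>EEG</type>",
    "<channel_count>%d</channel_count><nominal_srate>%g</nominal_srate>",
    "<channel_format>%s</channel_format><desc><channels>%s</channels>",
    "</desc></info>"),
    nrow(rec$data), rec$sample_rate, format, labels)
  id <- writeBin(1L, raw(), size = 4, endian = "little")
  chunk(2L, c(id, charToRaw(hdr)))
  n <- n_samples(rec)
  body <- raw(0)
  vals <- writeBin(as.vector(rec$data), raw(), size = size,
                   endian = "little")
  vmat <- matrix(vals, ncol = n)                # bytes per sample column
  flags <- as.raw(rep(0L, n))
  inter <- rbind(matrix(flags, nrow = 1), vmat)
  body <- c(id, as.raw(4L),
            writeBin(as.integer(n), raw(), size = 4, endian = "little"),
            as.vector(inter))
  chunk(3L, body)
  chunk(6L, c(id, charToRaw("<?xml version=\"1.0\"?><info></info>")))
  invisible(path)
}
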