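# Minimal EDF (European Data Format) support: fixed-width ASCII header of
# 256 + 256*ns bytes, then data records of little-endian int16 samples.
# Only uniform sampling rates across signals are supported, which covers
# resting-state EEG exports.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(raw, width, n = 1L) {
  txt <- rawToChar(raw)
  starts <- seq(1L, by = width, length.out = n)
  as.numeric(trimws(substring(txt, starts, starts + width - 1L)))
}

.edf_str <- function(raw, width, n = 1L) {
  txt <- rawToChar(raw)
  starts <- seq(1L, by = width, length.out = n)
  trimws(substring(txt, starts, starts + width - 1L))
}

#' Read an EDF recording
#'
#' Minimal reader for uncompressed EDF files with a uniform sampling rate
#' across all retained signals. Samples are rescaled from digital to
#' physical units using the per-signal calibration in the header.
#'
#' @param path Path to the `.edf` file.
#' @param condition,label Metadata to attach (EDF carries neither).
#' @param subject_id Subject identifier; defaults to the header's local
#'   patient identification field (first token) or the file name.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, condition = "EO", label = NULL, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  patient <- .edf_str(hdr[9:88], 80L)
  n_rec <- .edf_num(hdr[237:244], 8L)
  rec_dur <- .edf_num(hdr[245:252], 8L)
  ns <- as.integer(.edf_num(hdr[253:256], 4L))
  if (!is.finite(ns) || ns < 1L) stop("invalid EDF header: ns", call. = FALSE)
  sig <- readBin(con, "raw", 256L * ns)
  field <- function(off, width) {
    # per-signal fields are stored field-major: all labels, all transducers, ...
    idx <- off + seq_len(width * ns)
    sig[idx]
  }
  labels   <- .edf_str(field(0L, 16L), 16L, ns)
  phys_min <- .edf_num(field(ns * (16L + 80L + 8L), 8L), 8L, ns)
  phys_max <- .edf_num(field(ns * (16L + 80L + 8L + 8L), 8L), 8L, ns)
  dig_min  <- .edf_num(field(ns * (16L + 80L + 8L + 8L + 8L), 8L), 8L, ns)
  dig_max  <- .edf_num(field(ns * (16L + 80L + 8L + 8L + 8L + 8L), 8L), 8L, ns)
  spr      <- as.integer(.edf_num(field(ns * (16L + 80L + 8L * 5L + 80L), 8L), 8L, ns))
  if (length(unique(spr)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported", call. = FALSE)
  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  if (n_rec < 0) stop("EDF header does not declare the record count", call. = FALSE)
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = spr[1L], ncol = ns)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    out[, cols] <- t(block * rep(gain, each = spr[1L]) +
                       rep(phys_min - gain * dig_min, each = spr[1L]))
  }
  rownames(out) <- NULL
  if (is.null(subject_id)) {
    subject_id <- strsplit(patient, " ")[[1L]][1L]
    if (is.na(subject_id) || !nzchar(subject_id))
      subject_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  }
  rec <- eeg_recording(out, fs = fs, subject_id = subject_id,
                       condition = condition, label = label)
  rec$channel_names <- labels
  rec
}

#' Write a recording to EDF
#'
#' Writes an [eeg_recording] as an uncompressed EDF file with one-second
#' data records. Samples are quantized to 16-bit integers over the
#' recording's physical range, so round-tripping is exact only to that
#' quantization.
#'
#' @param rec An [eeg_recording]; `fs` must be a whole number and the sample
#'   count a multiple of `fs` (trailing samples are dropped with a warning).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires a whole-number sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  x <- rec$data
  n_rec <- ncol(x) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)", call. = FALSE)
  if (ncol(x) %% fs != 0L) {
    warning("dropping ", ncol(x) %% fs, " trailing samples to fill whole EDF records")
    x <- x[, seq_len(n_rec * fs), drop = FALSE]
  }
  ns <- nrow(x)
  # physical range is stored as fixed-width ASCII; format first, then parse
  # back, so the gain used for quantization matches the header exactly
  # 5% headroom so rounding to the 2-significant-digit header field can
  # never clip the extremes
  pm_txt <- sprintf("%.1e", 1.05 * max(abs(range(x)), 1e-6))
  pmax_ <- as.numeric(pm_txt)
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768; dig_max <- 32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  chan_names <- rec$channel_names
  if (is.null(chan_names)) chan_names <- sprintf("EEG %03d", seq_len(ns))
  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad(paste(rec$subject_id, "X X X"), 80L),
    .edf_pad(paste("Startdate 01-JAN-2000", rec$condition), 80L),
    .edf_pad("01.01.00", 8L), .edf_pad("00.00.00", 8L),
    .edf_pad(256L + 256L * ns, 8L),
    .edf_pad("", 44L),
    .edf_pad(n_rec, 8L), .edf_pad("1", 8L), .edf_pad(ns, 4L),
    paste(.edf_pad(chan_names, 16L), collapse = ""),
    paste(rep(.edf_pad("", 80L), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8L), ns), collapse = ""),
    paste(rep(.edf_pad(paste0("-", pm_txt), 8L), ns), collapse = ""),
    paste(rep(.edf_pad(pm_txt, 8L), ns), collapse = ""),
    paste(rep(.edf_pad(dig_min, 8L), ns), collapse = ""),
    paste(rep(.edf_pad(dig_max, 8L), ns), collapse = ""),
    paste(rep(.edf_pad("", 80L), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8L), ns), collapse = ""),
    paste(rep(.edf_pad("", 32L), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((t(x[, cols, drop = FALSE]) - phys_min) / gain + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}
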