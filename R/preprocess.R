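#' Preprocessing configuration
#'
#' Parameters of the raw-EEG preparation chain: zero-phase Butterworth
#' band-pass, integer decimation, symmetric edge cropping, per-channel
#' z-scoring, and overlapping epoching.
#'
#' @param band_low_hz Lower band edge in Hz.
#' @param band_high_hz Upper band edge in Hz; with the default 100 Hz target
#'   rate this sits at the post-decimation Nyquist, so the band-pass doubles
#'   as the anti-alias filter.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param target_fs Sampling rate in Hz after decimation; the source rate
#'   must be an integer multiple.
#' @param crop_seconds Seconds removed from each end after decimation.
#' @param window_seconds Epoch length in seconds.
#' @param overlap_seconds Overlap between consecutive epochs in seconds
#'   (stride = window - overlap); may be 0.
#' @param sigma_floor Smallest standard deviation used in z-scoring;
#'   flat channels are divided by this floor instead of 0.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(band_low_hz = 0.5, band_high_hz = 50,
                              filter_order = 5L, target_fs = 100,
                              crop_seconds = 3, window_seconds = 10,
                              overlap_seconds = 2, sigma_floor = 1e-8) {
  cfg <- list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
              filter_order = as.integer(filter_order), target_fs = target_fs,
              crop_seconds = crop_seconds, window_seconds = window_seconds,
              overlap_seconds = overlap_seconds, sigma_floor = sigma_floor)
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz))
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  if (band_high_hz > target_fs / 2)
    stop("band_high_hz exceeds the post-decimation Nyquist (target_fs/2)",
         call. = FALSE)
  if (cfg$filter_order < 1L) stop("filter_order must be >= 1", call. = FALSE)
  if (target_fs <= 0) stop("target_fs must be positive", call. = FALSE)
  if (crop_seconds < 0) stop("crop_seconds must be >= 0", call. = FALSE)
  if (window_seconds <= 0) stop("window_seconds must be positive", call. = FALSE)
  if (overlap_seconds < 0 || overlap_seconds >= window_seconds)
    stop("need 0 <= overlap_seconds < window_seconds", call. = FALSE)
  if (sigma_floor <= 0) stop("sigma_floor must be positive", call. = FALSE)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Zero-phase band-pass filter
#'
#' Applies an order-`filter_order` Butterworth band-pass forward and backward
#' (zero phase) to every channel independently. Shape and sampling rate are
#' unchanged.
#'
#' @param rec An [eeg_recording] with finite samples.
#' @param cfg A [preprocess_config].
#' @return The filtered [eeg_recording].
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite samples; refusing to filter",
         call. = FALSE)
  nyq <- rec$fs / 2
  if (cfg$band_low_hz <= 0 || cfg$band_high_hz >= nyq)
    stop(sprintf("band edges [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                 cfg$band_low_hz, cfg$band_high_hz, nyq), call. = FALSE)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low_hz, cfg$band_high_hz) / nyq,
                       type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  out
}

#' Decimate to the target sampling rate
#'
#' Keeps every `fs/target_fs`-th sample starting from the first (the
#' band-pass stage provides anti-aliasing). The ratio must be a whole number.
#'
#' @inheritParams bandpass_filter
#' @return The decimated [eeg_recording] with `fs = target_fs`.
#' @export
downsample <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ratio <- rec$fs / cfg$target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("sampling rate %g Hz is not an integer multiple of target %g Hz",
                 rec$fs, cfg$target_fs), call. = FALSE)
  ratio <- as.integer(round(ratio))
  out <- rec
  out$data <- rec$data[, seq(1L, ncol(rec$data), by = ratio), drop = FALSE]
  out$fs <- cfg$target_fs
  out
}

#' Crop recording edges
#'
#' Removes `crop_seconds` from both ends of the recording, discarding filter
#' and resampling edge artifacts.
#'
#' @inheritParams bandpass_filter
#' @return The cropped [eeg_recording].
#' @export
crop_edges <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncrop <- as.integer(round(cfg$crop_seconds * rec$fs))
  if (ncrop == 0L) return(rec)
  n <- ncol(rec$data)
  if (n <= 2L * ncrop)
    stop(sprintf("recording has %d samples; cropping %g s from both ends needs more than %d samples",
                 n, cfg$crop_seconds, 2L * ncrop), call. = FALSE)
  out <- rec
  out$data <- rec$data[, (ncrop + 1L):(n - ncrop), drop = FALSE]
  out
}

#' Per-channel z-score normalization
#'
#' Subtracts each channel's temporal mean and divides by its temporal
#' standard deviation (population convention, divisor = sample count),
#' equalizing scale across electrodes. Standard deviations below
#' `sigma_floor` are replaced by the floor, so flat channels map to zeros
#' (with a warning) instead of failing.
#'
#' @inheritParams bandpass_filter
#' @return The normalized [eeg_recording].
#' @export
zscore_normalize <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  mu <- rowMeans(x)
  xc <- x - mu
  sig <- sqrt(rowMeans(xc^2))
  flat <- sig < cfg$sigma_floor
  if (any(flat)) {
    warning(sum(flat), " channel(s) are (near-)constant; z-scoring with the sigma floor")
    sig[flat] <- cfg$sigma_floor
  }
  out <- rec
  out$data <- xc / sig
  out
}

#' Cut a recording into overlapping fixed-length windows
#'
#' Epochs the recording into windows of `window_seconds` with
#' `overlap_seconds` overlap (stride = window - overlap). Windows start at
#' samples 0, stride, 2*stride, ... while they fit; trailing samples that do
#' not fill a window are dropped. Each window is transposed to
#' time-steps x electrodes, the classifier's input layout. A recording
#' shorter than one window yields an empty set with a warning.
#'
#' @inheritParams bandpass_filter
#' @return A [window_set].
#' @export
segment_windows <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- as.integer(round(cfg$window_seconds * rec$fs))
  s <- as.integer(round((cfg$window_seconds - cfg$overlap_seconds) * rec$fs))
  stopifnot(w > 0L, s > 0L)
  L <- ncol(rec$data)
  e <- nrow(rec$data)
  if (L < w) {
    warning(sprintf("recording %s has %d samples < window length %d; producing no windows",
                    rec$subject_id, L, w))
    return(window_set(array(0, dim = c(w, e, 0L)), subject_id = character(0),
                      label = character(0), condition = rec$condition,
                      fs = rec$fs))
  }
  starts <- seq(1L, L - w + 1L, by = s)
  win <- array(0, dim = c(w, e, length(starts)))
  for (i in seq_along(starts))
    win[, , i] <- t(rec$data[, starts[i]:(starts[i] + w - 1L), drop = FALSE])
  window_set(win,
             subject_id = rep(rec$subject_id, length(starts)),
             label = if (is.null(rec$label)) rep(NA_character_, length(starts))
                     else rep(rec$label, length(starts)),
             condition = rec$condition, fs = rec$fs)
}

#' Run the full preprocessing chain
#'
#' Band-pass filter, decimate, crop, z-score, and epoch, in that order.
#' Deterministic: identical recordings and configuration give numerically
#' identical window sets. With the defaults a 120 s, 26-channel, 500 Hz
#' recording yields 14 windows of 1000 time-steps x 26 electrodes.
#'
#' @inheritParams bandpass_filter
#' @return A [window_set].
#' @export
run_preprocessing <- function(rec, cfg = preprocess_config()) {
  rec <- bandpass_filter(rec, cfg)
  rec <- downsample(rec, cfg)
  rec <- crop_edges(rec, cfg)
  rec <- zscore_normalize(rec, cfg)
  segment_windows(rec, cfg)
}

#' Preprocess a list of recordings into one window set
#'
#' @param recs List of [eeg_recording] objects (e.g. a synthetic cohort's
#'   `recordings` element).
#' @param cfg A [preprocess_config].
#' @return A combined [window_set] over all recordings.
#' @export
preprocess_cohort <- function(recs, cfg = preprocess_config()) {
  sets <- lapply(recs, run_preprocessing, cfg = cfg)
  do.call(bind_window_sets, sets)
}
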