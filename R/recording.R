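#' EEG recording container
#'
#' Holds one subject/condition resting-state recording as a channels x samples
#' numeric matrix together with its sampling rate and metadata. This is the
#' unit the preprocessing chain operates on.
#'
#' @param data Numeric matrix, channels (rows) x samples (columns),
#'   microvolt-scale values.
#' @param fs Sampling rate in Hz (source recordings are 500 Hz).
#' @param subject_id Subject identifier string.
#' @param condition Recording condition: `"EO"` (eyes open) or `"EC"`
#'   (eyes closed).
#' @param label Diagnostic label (e.g. `"MDD"`, `"ADHD"`, `"SMC"`, `"OCD"`,
#'   `"Healthy"`), or `NULL` when unknown.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, subject_id = "sub-000",
                          condition = c("EO", "EC"), label = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("recording must have at least one channel and one sample", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(data = data, fs = fs, subject_id = as.character(subject_id),
         condition = condition,
         label = if (is.null(label)) NULL else as.character(label)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition,
              if (is.null(x$label)) "" else paste0(" ", x$label),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec An `eeg_recording`.
#' @return Integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read a recording from a delimited text matrix
#'
#' Reads a plain numeric matrix (CSV/TSV, no header) as an EEG recording.
#' Orientation declares whether channels are stored as rows or columns.
#'
#' @param path Path to the delimited file.
#' @param fs Sampling rate in Hz of the stored signal.
#' @param orientation `"channels_rows"` (default) or `"channels_cols"`.
#' @param sep Field separator; `""` (default) auto-detects comma vs tab.
#' @inheritParams eeg_recording
#' @return An `eeg_recording`.
#' @export
read_eeg_matrix <- function(path, fs, orientation = c("channels_rows", "channels_cols"),
                            sep = "", subject_id = NULL, condition = "EO",
                            label = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (orientation == "channels_cols") m <- t(m)
  if (is.null(subject_id))
    subject_id <- sub("\\.(csv|tsv|txt)$", "", basename(path))
  eeg_recording(m, fs = fs, subject_id = subject_id, condition = condition,
                label = label)
}

#' Read a participants table
#'
#' Reads a BIDS-style tab-separated participants table with (at least)
#' columns `subject_id` and `label`, mapping each subject to a diagnostic
#' class.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with character columns `subject_id` and `label`.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(df)))
    stop("participants table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in participants table", call. = FALSE)
  df
}

#' Write a participants table
#' @param df Data frame with `subject_id` and `label` columns.
#' @param path Output TSV path.
#' @export
write_participants <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
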