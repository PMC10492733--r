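#' Window set container
#'
#' A stack of fixed-size epochs, each `m` time-steps x `e` electrodes, with
#' one subject identifier and one diagnostic label per window. This is the
#' classifier's input unit.
#'
#' @param windows Numeric array of dimension `c(m, e, n)`.
#' @param subject_id Character vector of length `n`.
#' @param label Character vector of length `n` (may be `NA` when unlabeled).
#' @param condition Recording condition tag.
#' @param fs Sampling rate of the windows in Hz.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, subject_id, label, condition = "EO", fs = NA_real_) {
  if (!is.array(windows) || length(dim(windows)) != 3L)
    stop("`windows` must be an m x e x n array", call. = FALSE)
  n <- dim(windows)[3L]
  if (length(subject_id) != n || length(label) != n)
    stop("subject_id and label must have one entry per window", call. = FALSE)
  structure(
    list(windows = windows, subject_id = as.character(subject_id),
         label = as.character(label), condition = condition, fs = fs,
         m = dim(windows)[1L], e = dim(windows)[2L]),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d (time x electrodes), %d subject(s)\n",
              n_windows(x), x$m, x$e, length(unique(x$subject_id))))
  if (!all(is.na(x$label))) {
    tab <- table(x$label, useNA = "no")
    cat("  windows per label:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A [window_set].
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[3L]

#' Combine window sets
#'
#' Stacks several window sets (e.g. one per subject) into one. All sets must
#' share the window shape; empty sets are dropped.
#'
#' @param ... [window_set] objects.
#' @return A single [window_set].
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0L)
  nonempty <- sets[vapply(sets, n_windows, 0L) > 0L]
  if (length(nonempty) == 0L) return(sets[[1L]])
  m <- unique(vapply(nonempty, function(s) s$m, 0L))
  e <- unique(vapply(nonempty, function(s) s$e, 0L))
  if (length(m) != 1L || length(e) != 1L)
    stop("window sets have inconsistent window shapes", call. = FALSE)
  win <- array(0, dim = c(m, e, sum(vapply(nonempty, n_windows, 0L))))
  off <- 0L
  for (s in nonempty) {
    k <- n_windows(s)
    win[, , off + seq_len(k)] <- s$windows
    off <- off + k
  }
  window_set(win,
             subject_id = unlist(lapply(nonempty, `[[`, "subject_id")),
             label = unlist(lapply(nonempty, `[[`, "label")),
             condition = nonempty[[1L]]$condition, fs = nonempty[[1L]]$fs)
}

#' Subset a window set
#' @param ws A [window_set].
#' @param idx Integer or logical index over windows.
#' @return The subsetted [window_set].
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[, , idx, drop = FALSE],
             subject_id = ws$subject_id[idx], label = ws$label[idx],
             condition = ws$condition, fs = ws$fs)
}

#' Keep only windows from the given subjects
#' @param ws A [window_set].
#' @param subjects Character vector of subject IDs.
#' @return The subsetted [window_set].
#' @export
filter_subjects <- function(ws, subjects) {
  subset_windows(ws, ws$subject_id %in% subjects)
}

#' Serialize / load a window set
#'
#' Windows are stored as a flat binary array of doubles with a JSON sidecar
#' carrying shape, subject IDs, labels and metadata, so a saved set can be
#' reloaded without re-running the preprocessing chain.
#'
#' @param ws A [window_set].
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return `path`, invisibly.
#' @export
write_window_set <- function(ws, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(ws$windows), con, size = 8L, endian = "little")
  meta <- list(m = ws$m, e = ws$e, n = n_windows(ws),
               subject_id = ws$subject_id, label = ws$label,
               condition = ws$condition, fs = ws$fs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$m * meta$e * meta$n, size = 8L,
               endian = "little")
  window_set(array(x, dim = c(meta$m, meta$e, meta$n)),
             subject_id = as.character(meta$subject_id),
             label = as.character(meta$label),
             condition = meta$condition, fs = meta$fs)
}
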