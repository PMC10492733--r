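# Classical EEG frequency bands (Hz).
.eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                   alpha = c(8, 13), beta = c(13, 30))

# Fixed per-band spatial patterns ("topographies") over the channel axis:
# smooth profiles peaking at different scalp regions (delta/theta frontal,
# alpha posterior, beta central), RMS-normalized. Classes that differ in
# band power therefore also differ in inter-channel covariance, which
# survives per-channel z-scoring.
.band_topography <- function(channels) {
  u <- seq(0, 1, length.out = channels)
  raw <- rbind(delta = 1 + 0.9 * cos(pi * u),
               theta = 1 + 0.9 * cos(pi * u + 0.6),
               alpha = 1 + 0.9 * cos(pi * (1 - u)),
               beta  = 1 + 0.9 * sin(pi * u))
  raw / sqrt(rowMeans(raw^2))
}

# Default class band-power profiles (relative delta/theta/alpha/beta power,
# each summing to 1): the usual qualitative markers — ADHD theta excess,
# OCD beta excess, healthy posterior alpha dominance, SMC slow-wave shift —
# kept close enough to overlap under the default subject variability.
.default_profiles <- function() {
  p <- rbind(MDD     = c(0.25, 0.20, 0.40, 0.15),
             ADHD    = c(0.25, 0.40, 0.22, 0.13),
             SMC     = c(0.35, 0.25, 0.25, 0.15),
             OCD     = c(0.22, 0.25, 0.28, 0.25),
             Healthy = c(0.20, 0.18, 0.45, 0.17))
  colnames(p) <- names(.eeg_bands)
  p / rowSums(p)
}

#' Synthetic EEG cohort configuration
#'
#' Parameters of the synthetic resting-state EEG generator. Each channel is
#' a sum of band-limited Gaussian noise carriers (delta 0.5-4, theta 4-8,
#' alpha 8-13, beta 13-30 Hz), partially shared across channels through
#' fixed per-band spatial patterns, plus a 1/f background. Class membership
#' sets the relative band powers; subjects draw log-normal multiplicative
#' deviations around their class profile.
#'
#' @param channels Electrode count.
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds per condition.
#' @param class_profiles Matrix of relative band powers
#'   (classes x delta/theta/alpha/beta), rows summing to 1.
#' @param noise_exponent 1/f background spectral slope.
#' @param background_rel Amplitude of the 1/f background relative to the
#'   total band-carrier amplitude.
#' @param subject_sd Standard deviation of the subject-level log-normal
#'   band-amplitude deviations.
#' @param channel_mixing Spatial correlation strength in `[0, 1]`: 0 gives
#'   independent channels, larger values give more shared (topographic)
#'   band signal.
#' @param class_counts Named subjects-per-class vector; the default mirrors
#'   the clinical archive's imbalance (MDD 426 : ADHD 271 : SMC 119 :
#'   OCD 75 : Healthy 47) scaled to a 100-subject cohort.
#' @param ec_alpha_boost Multiplier on alpha amplitude for eyes-closed
#'   recordings (the classical alpha blocking contrast).
#' @param seed Cohort seed; per-subject seeds are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(channels = 26L, fs = 500, duration = 120,
                       class_profiles = .default_profiles(),
                       noise_exponent = 1, background_rel = 0.3,
                       subject_sd = 0.2, channel_mixing = 0.6,
                       class_counts = c(MDD = 45L, ADHD = 29L, SMC = 13L,
                                        OCD = 8L, Healthy = 5L),
                       ec_alpha_boost = 1.5, seed = 1L) {
  cfg <- list(channels = as.integer(channels), fs = fs, duration = duration,
              class_profiles = class_profiles,
              noise_exponent = noise_exponent,
              background_rel = background_rel,
              subject_sd = subject_sd, channel_mixing = channel_mixing,
              class_counts = class_counts, ec_alpha_boost = ec_alpha_boost,
              seed = as.integer(seed))
  if (cfg$channels < 1L || fs <= 0 || duration <= 0)
    stop("channels, fs and duration must be positive", call. = FALSE)
  if (channel_mixing < 0 || channel_mixing > 1)
    stop("channel_mixing must be in [0, 1]", call. = FALSE)
  if (subject_sd < 0) stop("subject_sd must be >= 0", call. = FALSE)
  if (is.null(rownames(class_profiles)))
    stop("class_profiles must have class names as rownames", call. = FALSE)
  if (any(class_counts < 0)) stop("class_counts must be non-negative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Unit-variance Gaussian noise band-limited to [lo, hi] Hz via FFT masking.
.band_noise <- function(n, fs, lo, hi) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- f >= lo & f <= hi
  X <- stats::fft(stats::rnorm(n))
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x / s
}

# Unit-variance 1/f^(slope/2) amplitude-shaped background noise.
.pink_noise <- function(n, fs, slope) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 0.5, 0, f^(-slope / 2))
  X <- stats::fft(stats::rnorm(n)) * shape
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic subject recording
#'
#' Deterministic given `seed`: the subject's band-amplitude deviations and
#' all noise carriers are drawn from the seeded stream.
#'
#' @param class Class name (a row of `cfg$class_profiles`).
#' @param cfg A [sim_config].
#' @param seed Subject seed.
#' @param subject_id Subject identifier.
#' @param condition `"EO"` or `"EC"`; eyes-closed scales alpha by
#'   `cfg$ec_alpha_boost`.
#' @return An [eeg_recording] with the class attached as its label.
#' @export
generate_subject <- function(class, cfg = sim_config(), seed = 1L,
                             subject_id = "sub-000", condition = "EO") {
  if (!class %in% rownames(cfg$class_profiles))
    stop("unknown class: ", class, call. = FALSE)
  profile <- cfg$class_profiles[class, ]
  n <- as.integer(round(cfg$fs * cfg$duration))
  ch <- cfg$channels
  topo <- .band_topography(ch)
  mix <- cfg$channel_mixing
  data <- with_seed(seed, {
    subj_fac <- exp(stats::rnorm(length(profile), 0, cfg$subject_sd))
    amp <- sqrt(profile) * subj_fac
    if (condition == "EC") amp["alpha"] <- amp["alpha"] * cfg$ec_alpha_boost
    out <- matrix(0, ch, n)
    for (b in seq_along(profile)) {
      band <- .eeg_bands[[names(profile)[b]]]
      shared <- .band_noise(n, cfg$fs, band[1L], band[2L])
      for (c in seq_len(ch)) {
        own <- .band_noise(n, cfg$fs, band[1L], band[2L])
        out[c, ] <- out[c, ] + amp[b] *
          (sqrt(1 - mix) * own + sqrt(mix) * topo[b, c] * shared)
      }
    }
    for (c in seq_len(ch))
      out[c, ] <- out[c, ] + cfg$background_rel * .pink_noise(n, cfg$fs, cfg$noise_exponent)
    out * 20   # microvolt-like scale
  })
  eeg_recording(data, fs = cfg$fs, subject_id = subject_id,
                condition = condition, label = class)
}

#' Generate a full synthetic cohort
#'
#' Draws `class_counts` subjects per class, each with a derived per-subject
#' seed, and returns the recordings together with a manifest sufficient to
#' regenerate the cohort bit-identically.
#'
#' @param cfg A [sim_config].
#' @param condition Recording condition tag for all subjects.
#' @return A `synthetic_cohort` list with elements `recordings` (list of
#'   [eeg_recording]), `participants` (subject_id/label data.frame) and
#'   `manifest` (per-subject class and seed).
#' @export
generate_cohort <- function(cfg = sim_config(), condition = "EO") {
  counts <- cfg$class_counts
  classes <- rep(names(counts), counts)
  n <- length(classes)
  seeds <- derive_seeds(cfg$seed, n)
  ids <- sprintf("sub-%03d", seq_len(n))
  recs <- vector("list", n)
  for (i in seq_len(n))
    recs[[i]] <- generate_subject(classes[i], cfg, seed = seeds[i],
                                  subject_id = ids[i], condition = condition)
  manifest <- data.frame(subject_id = ids, label = classes, seed = seeds,
                         condition = condition, stringsAsFactors = FALSE)
  structure(list(recordings = recs,
                 participants = manifest[, c("subject_id", "label")],
                 manifest = manifest, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$participants$label)
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d ch x %.0f s @ %g Hz\n",
              nrow(x$participants),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$channels, x$config$duration, x$config$fs))
  invisible(x)
}

#' Generate a three-class cohort with controlled separability
#'
#' Builds a cohort of three classes whose band-power profiles differ only in
#' the alpha/theta amplitude ratio. `gap` is the distance, in units of the
#' subject-level standard deviation of the log alpha/theta ratio, from each
#' class mean to the decision midpoint between adjacent classes (adjacent
#' class means are `2 * gap` subject-SDs apart). `gap = 0` makes the classes
#' exchangeable, so no classifier can beat chance in expectation; `gap = 3`
#' makes mean band-power features separate subjects almost perfectly.
#'
#' @param n_per_class Subjects per class.
#' @param gap Non-negative separability parameter.
#' @param cfg A [sim_config]; its `class_profiles` and `class_counts` are
#'   replaced by the three constructed classes.
#' @param condition Recording condition tag.
#' @return A `synthetic_cohort` of classes `A`, `B`, `C`.
#' @export
make_separable_cohort <- function(n_per_class = 20L, gap = 3,
                                  cfg = sim_config(), condition = "EO") {
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  # subject-level log alpha and log theta amplitudes each have sd
  # subject_sd, so the log ratio has sd sqrt(2) * subject_sd
  sd_ratio <- sqrt(2) * cfg$subject_sd
  base <- c(delta = 0.25, theta = 0.25, alpha = 0.25, beta = 0.25)
  shift <- function(d) {
    # move log alpha amplitude by +d/2 and log theta by -d/2
    p <- base
    p["alpha"] <- p["alpha"] * exp(d)    # power scales as amplitude^2 = exp(2 * d/2)
    p["theta"] <- p["theta"] * exp(-d)
    p / sum(p)
  }
  offsets <- (c(A = -1, B = 0, C = 1)) * 2 * gap * sd_ratio
  profiles <- do.call(rbind, lapply(offsets, shift))
  rownames(profiles) <- names(offsets)
  colnames(profiles) <- names(base)
  cfg$class_profiles <- profiles
  cfg$class_counts <- c(A = n_per_class, B = n_per_class, C = n_per_class)
  if (n_per_class == 0L) {
    return(structure(list(recordings = list(),
                          participants = data.frame(subject_id = character(0),
                                                    label = character(0)),
                          manifest = data.frame(), config = cfg),
                     class = "synthetic_cohort"))
  }
  generate_cohort(cfg, condition = condition)
}

#' Band power of a signal by periodogram
#'
#' Average periodogram power of a single-channel signal inside each EEG
#' band, used to verify that generated recordings carry the configured
#' spectral profile.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of per-band mean power densities.
#' @export
band_powers <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  vapply(.eeg_bands, function(b) {
    sel <- f >= b[1L] & f <= b[2L]
    mean(P[sel])
  }, numeric(1))
}

#' Write a synthetic cohort to disk
#'
#' Writes one recording file per subject (EDF or headerless CSV matrices,
#' channels as rows) plus a `participants.tsv` and a JSON manifest, matching
#' what the preprocessing readers expect.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    if (format == "edf") {
      write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
    } else {
      utils::write.table(rec$data,
                         file.path(dir, paste0(rec$subject_id, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  write_participants(cohort$participants, file.path(dir, "participants.tsv"))
  man <- cohort$manifest
  man_cfg <- cohort$config
  jsonlite::write_json(
    list(manifest = man,
         config = man_cfg[setdiff(names(man_cfg), "class_profiles")],
         class_profiles = as.data.frame(man_cfg$class_profiles),
         classes = rownames(man_cfg$class_profiles),
         format = format, fs = man_cfg$fs),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
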