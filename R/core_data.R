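# Data model for synchronized multimodal recordings, file I/O, and the
# channel-agnostic preprocessing (FIR resampling, Gaussian smoothing).

CHANNEL_NAMES <- c("EDA", "EMG", "RSP", "BVP", "GRIP")

# Target sampling rates after preprocessing, per channel (Hz).
TARGET_RATES <- c(EDA = 8, EMG = 256, RSP = 8, BVP = 64, GRIP = 75)

#' Construct a single-channel signal
#'
#' A uniformly sampled real-valued series on the shared session clock.
#'
#' @param name Channel identifier, one of `"EDA"`, `"EMG"`, `"RSP"`,
#'   `"BVP"`, `"GRIP"`.
#' @param samples Numeric vector of finite samples (length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds on the session clock.
#' @return An object of class `channel_signal` with fields `name`, `fs`,
#'   `samples`, `t0`.
#' @export
channel_signal <- function(name, samples, fs, t0 = 0) {
  name <- match.arg(name, CHANNEL_NAMES)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("`samples` must have length >= 1")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(
    list(name = name, fs = fs, samples = samples, t0 = as.numeric(t0)),
    class = "channel_signal"
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal %s: %d samples @ %g Hz, %.1f s>\n",
              x$name, length(x$samples), x$fs, signal_duration(x)))
  invisible(x)
}

#' Duration of a channel signal in seconds
#' @param signal A [channel_signal()].
#' @return Duration in seconds (`length / fs`).
#' @export
signal_duration <- function(signal) length(signal$samples) / signal$fs

#' Construct a sparse series of self-reported pain ratings
#'
#' Verbal pain self-reports on the 0-10 numeric scale (0 = no pain,
#' 10 = maximum pain), given at strictly increasing session times.
#'
#' @param times Report times in seconds, strictly increasing.
#' @param ratings Integer ratings in 0-10, same length as `times`.
#' @return An object of class `pain_reports`.
#' @export
pain_reports <- function(times = numeric(0), ratings = integer(0)) {
  times <- as.numeric(times)
  ratings <- as.numeric(ratings)
  if (length(times) != length(ratings))
    stop("`times` and `ratings` must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("report times must be strictly increasing")
  if (length(ratings) && (any(!is.finite(ratings)) ||
                          any(ratings < 0 | ratings > 10) ||
                          any(ratings != round(ratings))))
    stop("ratings must be integers in 0-10")
  structure(list(times = times, ratings = ratings), class = "pain_reports")
}

#' Construct a multimodal recording of one subject session
#'
#' @param subject_id Opaque subject identifier.
#' @param channels Named list with all five [channel_signal()]s
#'   (`EDA`, `EMG`, `RSP`, `BVP`, `GRIP`).
#' @param reports A [pain_reports()] series.
#' @param baseline_end End of the initial no-pain segment in seconds.
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(subject_id, channels, reports,
                                 baseline_end = 30) {
  missing_ch <- setdiff(CHANNEL_NAMES, names(channels))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  for (nm in CHANNEL_NAMES) {
    if (!inherits(channels[[nm]], "channel_signal"))
      stop("channel ", nm, " is not a channel_signal")
  }
  if (!inherits(reports, "pain_reports")) stop("`reports` must be pain_reports")
  dur <- recording_duration_from(channels)
  if (baseline_end < 0 || baseline_end > dur)
    stop("`baseline_end` must lie within the session span")
  structure(
    list(subject_id = as.character(subject_id),
         channels = channels[CHANNEL_NAMES],
         reports = reports,
         baseline_end = as.numeric(baseline_end)),
    class = "multimodal_recording"
  )
}

recording_duration_from <- function(channels) {
  min(vapply(channels, signal_duration, numeric(1)))
}

#' Common session duration of a recording in seconds
#' @param recording A [multimodal_recording()].
#' @return The minimum duration across channels.
#' @export
recording_duration <- function(recording) {
  recording_duration_from(recording$channels)
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording subject %s: %.1f s, %d reports>\n",
              x$subject_id, recording_duration(x), length(x$reports$times)))
  for (ch in x$channels) print(ch)
  invisible(x)
}

#' Load a recording from a directory of CSV files
#'
#' Expects one two-column CSV (`time_s,value`) per channel (`eda.csv`,
#' `emg.csv`, `rsp.csv`, `bvp.csv`, `grip.csv`), a `reports.csv`
#' (`time_s,rating`), and a `session.json` holding `subject_id` and
#' `baseline_end_s`. Channel timestamps must be uniform; the sampling rate
#' is inferred from them.
#'
#' @param directory_path Path to the recording directory.
#' @param uniformity_tol Maximum tolerated relative jitter of the timestamp
#'   grid (default `1e-6` of the sample period).
#' @return A validated [multimodal_recording()].
#' @export
load_recording <- function(directory_path, uniformity_tol = 1e-6) {
  if (!dir.exists(directory_path)) stop("no such directory: ", directory_path)
  meta_path <- file.path(directory_path, "session.json")
  if (!file.exists(meta_path)) stop("missing session metadata file session.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  channels <- list()
  for (nm in CHANNEL_NAMES) {
    path <- file.path(directory_path, paste0(tolower(nm), ".csv"))
    if (!file.exists(path)) stop("missing channel file for channel ", nm)
    tab <- read.csv(path)
    if (!all(c("time_s", "value") %in% names(tab)))
      stop("channel file ", basename(path), " must have columns time_s,value")
    bad <- which(!is.finite(tab$time_s) | !is.finite(tab$value))
    if (length(bad))
      stop("parse error in ", basename(path), " at data line ", bad[1],
           ": non-finite value")
    if (nrow(tab) < 2) stop("channel ", nm, " needs at least 2 samples")
    dt <- diff(tab$time_s)
    period <- median(dt)
    if (period <= 0 || any(abs(dt - period) > uniformity_tol * period + 1e-12)) {
      bad_row <- which(abs(dt - period) > uniformity_tol * period + 1e-12)[1]
      stop("parse error in ", basename(path), " at data line ", bad_row + 1,
           ": non-uniform timestamps")
    }
    channels[[nm]] <- channel_signal(nm, tab$value, fs = 1 / period,
                                     t0 = tab$time_s[1])
  }

  rep_path <- file.path(directory_path, "reports.csv")
  if (!file.exists(rep_path)) stop("missing reports file reports.csv")
  rtab <- read.csv(rep_path)
  if (!all(c("time_s", "rating") %in% names(rtab)))
    stop("reports.csv must have columns time_s,rating")
  reports <- pain_reports(rtab$time_s, rtab$rating)

  multimodal_recording(meta$subject_id, channels, reports,
                       baseline_end = meta$baseline_end_s %||% 30)
}

#' Write a recording to a directory in the standard CSV layout
#'
#' Inverse of [load_recording()].
#'
#' @param recording A [multimodal_recording()].
#' @param directory_path Output directory (created if absent).
#' @return `directory_path`, invisibly.
#' @export
write_recording <- function(recording, directory_path) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in CHANNEL_NAMES) {
    ch <- recording$channels[[nm]]
    tab <- data.frame(
      time_s = ch$t0 + (seq_along(ch$samples) - 1) / ch$fs,
      value = ch$samples
    )
    write.csv(tab, file.path(directory_path, paste0(tolower(nm), ".csv")),
              row.names = FALSE)
  }
  write.csv(
    data.frame(time_s = recording$reports$times,
               rating = recording$reports$ratings),
    file.path(directory_path, "reports.csv"), row.names = FALSE
  )
  jsonlite::write_json(
    list(subject_id = recording$subject_id,
         baseline_end_s = recording$baseline_end,
         native_rates = as.list(vapply(recording$channels, `[[`, numeric(1), "fs"))),
    file.path(directory_path, "session.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(directory_path)
}

#' Resample a channel with an anti-aliasing FIR low-pass filter
#'
#' Polyphase rational resampling: the ratio `target_fs / fs` is reduced to
#' `p/q`, the signal is upsampled by `p`, filtered with a Kaiser-windowed
#' linear-phase FIR low-pass at the minimum of the two Nyquist frequencies,
#' and decimated by `q`. Edges are handled by reflection; each polyphase
#' branch is normalized to unit DC gain so constant signals pass through
#' exactly.
#'
#' @param signal A [channel_signal()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @param taps_per_phase Half-width of the FIR prototype in zero crossings
#'   (default 10).
#' @param beta Kaiser window shape parameter (default 8, ~80 dB stopband).
#' @return A [channel_signal()] at `target_fs` with
#'   `round(length * target_fs / fs)` samples.
#' @export
resample_channel <- function(signal, target_fs, taps_per_phase = 10, beta = 8) {
  stopifnot(inherits(signal, "channel_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 ||
      !is.finite(target_fs) || target_fs <= 0)
    stop("`target_fs` must be a single positive number")
  x <- signal$samples
  pq <- rational_approx(target_fs / signal$fs)
  p <- pq[["p"]]; q <- pq[["q"]]
  n_out <- round(length(x) * p / q)
  if (p == q)
    return(channel_signal(signal$name, x, fs = target_fs, t0 = signal$t0))

  m <- max(p, q)
  half <- taps_per_phase * m                    # half-length in upsampled samples
  L <- 2 * half + 1
  n_taps <- seq(-half, half)
  fc <- 1 / (2 * m)                             # cycles per upsampled sample
  h <- 2 * fc * sinc(2 * fc * n_taps) * as.numeric(signal::kaiser(L, beta))
  # Normalize every polyphase branch to unit DC gain (exact DC invariance).
  for (r in seq_len(p) - 1L) {
    idx <- which((n_taps %% p) == r)
    h[idx] <- h[idx] / sum(h[idx])
  }

  pad <- ceiling(half / p) + 1                  # input samples per side
  pad <- min(pad, length(x))
  xe <- reflect_pad(x, pad)
  # Zero-stuffed upsampling followed by FIR filtering (dense convolution,
  # computed branch-wise to stay O(n * taps)).
  nu <- length(xe) * p
  up <- numeric(nu)
  up[seq(1, nu, by = p)] <- xe
  y_full <- fft_conv_same(up, h)
  # Output sample k (0-based) sits at upsampled index pad*p + k*q (0-based).
  idx0 <- pad * p + seq(0, n_out - 1) * q
  if (max(idx0) + 1 > length(y_full)) {
    need <- max(idx0) + 1 - length(y_full)
    y_full <- c(y_full, rep(y_full[length(y_full)], need))
  }
  channel_signal(signal$name, y_full[idx0 + 1], fs = target_fs, t0 = signal$t0)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Linear convolution truncated to "same" alignment with the center of h
# (h must have odd length). FFT-based for speed.
fft_conv_same <- function(x, h) {
  nh <- length(h)
  half <- (nh - 1) / 2
  n <- length(x) + nh - 1
  nf <- nextn(n, c(2, 3, 5))
  X <- fft(c(x, rep(0, nf - length(x))))
  H <- fft(c(h, rep(0, nf - nh)))
  y <- Re(fft(X * H, inverse = TRUE)) / nf
  y[(half + 1):(half + length(x))]
}

#' Gaussian-weighted moving-average smoothing
#'
#' Convolution with a normalized Gaussian window (weights sum to 1);
#' edges are handled by reflection. Defaults to a 1-second window at the
#' channel's sampling rate with `sigma = window / 5`.
#'
#' @param signal A [channel_signal()].
#' @param window_samples Window length in samples (default: 1 s of samples).
#' @return A smoothed [channel_signal()] of identical length and rate.
#' @export
gaussian_smooth <- function(signal, window_samples = NULL) {
  stopifnot(inherits(signal, "channel_signal"))
  x <- signal$samples
  w <- window_samples %||% max(1, round(signal$fs))
  if (!is_count(w)) stop("`window_samples` must be a positive integer")
  if (w > length(x)) stop("window longer than signal")
  if (w == 1)
    return(signal)
  sigma <- w / 5
  half <- floor(w / 2)
  k <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  k <- k / sum(k)
  xe <- reflect_pad(x, half)
  y <- fft_conv_same(xe, k)[(half + 1):(half + length(x))]
  channel_signal(signal$name, y, fs = signal$fs, t0 = signal$t0)
}
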