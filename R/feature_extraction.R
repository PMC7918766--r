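# Per-frame feature matrix: scattering-layer frame energies, spectral
# entropy, time-domain and first-derivative statistics, the STFT-energy
# variant, and subject-based z-score normalization.

#' Analysis framing specification
#'
#' Half-open frames `[start, start + window_s)` advanced by `hop_s`.
#' Defaults: 4 s windows with 50% overlap, matching the scattering
#' invariance scale.
#'
#' @param window_s Frame width in seconds (default 4).
#' @param hop_s Frame hop in seconds (default 2; `0 < hop_s <= window_s`).
#' @return An object of class `framing_spec`.
#' @export
framing_spec <- function(window_s = 4, hop_s = 2) {
  stopifnot(window_s > 0, hop_s > 0, hop_s <= window_s)
  structure(list(window_s = window_s, hop_s = hop_s), class = "framing_spec")
}

frame_index_list <- function(n, fs, framing) {
  nf <- n_frames(n / fs, framing)
  lapply(seq_len(nf), function(f) {
    s <- (f - 1) * framing$hop_s
    i0 <- floor(s * fs + 1e-9) + 1
    i1 <- min(n, ceiling((s + framing$window_s) * fs - 1e-9))
    i0:i1
  })
}

#' Per-frame energy of aligned scattering matrices
#'
#' For each `S` and `U` matrix of an aligned [scattering_transform()]
#' output, the energy of frame `f` is the sum over paths of the squared
#' coefficient at time point `f`, giving one feature column per matrix
#' (6 for a three-layer transform, 4 for a two-layer one).
#'
#' @param aligned A `scattering_output` whose matrices all have the frame
#'   count as their time dimension (see [align_frames()]).
#' @return Numeric matrix `n_frames x (2 * n_layers)` with columns
#'   `S1, U1, S2, U2, ...`.
#' @export
frame_energy <- function(aligned) {
  stopifnot(inherits(aligned, "scattering_output"))
  nf <- aligned$n_frames
  cols <- list()
  for (l in seq_along(aligned$S)) {
    for (kind in c("S", "U")) {
      M <- aligned[[kind]][[l]]
      if (ncol(M) != nf)
        stop("matrix ", kind, l, " is not aligned to the frame grid")
      cols[[paste0(kind, l)]] <- colSums(M^2)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

# Shannon entropy (bits) of a nonnegative power vector after
# normalization; all-zero input yields 0 by convention.
power_entropy_bits <- function(p) {
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

#' Per-frame spectral entropy in bits
#'
#' For each frame, the one-sided Hann-windowed periodogram is normalized
#' into a probability distribution `P_m = S_m / sum(S)` and the Shannon
#' entropy `H = -sum(P_m log2 P_m)` is returned; zero-power bins
#' contribute 0, and an all-zero frame has entropy 0.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param framing A [framing_spec()].
#' @param window Taper applied before the FFT: `"hann"` (default) or
#'   `"rect"`.
#' @return Numeric vector with one entropy value per frame.
#' @export
spectral_entropy <- function(x, fs, framing = framing_spec(),
                             window = c("hann", "rect")) {
  window <- match.arg(window)
  frames <- frame_index_list(length(x), fs, framing)
  vapply(frames, function(idx) {
    seg <- x[idx]
    L <- length(seg)
    if (L < 2) stop("frame contains fewer than 2 samples")
    w <- if (window == "hann") hann_window(L) else rep(1, L)
    spec <- Mod(fft(seg * w))^2
    half <- spec[1:(floor(L / 2) + 1)]
    power_entropy_bits(half)
  }, numeric(1))
}

hann_window <- function(L) {
  if (L == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Per-frame time-domain statistics
#'
#' Maximum, median, sample standard deviation, and absolute amplitude
#' (peak-to-peak range `max - min`) of each frame.
#'
#' @inheritParams spectral_entropy
#' @param amplitude How to read "absolute amplitude": peak-to-peak
#'   `"range"` (default) or largest magnitude `"max_abs"`.
#' @return Numeric matrix `n_frames x 4` with columns
#'   `max`, `median`, `sd`, `amplitude`.
#' @export
time_domain_stats <- function(x, fs, framing = framing_spec(),
                              amplitude = c("range", "max_abs")) {
  amplitude <- match.arg(amplitude)
  frames <- frame_index_list(length(x), fs, framing)
  out <- t(vapply(frames, function(idx) {
    seg <- x[idx]
    amp <- if (amplitude == "range") max(seg) - min(seg) else max(abs(seg))
    c(max = max(seg), median = median(seg),
      sd = if (length(seg) > 1) sd(seg) else 0, amplitude = amp)
  }, numeric(4)))
  rownames(out) <- NULL
  out
}

#' Per-frame first-derivative statistics
#'
#' Maximum, mean, and sample standard deviation of the first difference
#' scaled by the sampling rate (units per second).
#'
#' @inheritParams spectral_entropy
#' @return Numeric matrix `n_frames x 3` with columns `max`, `mean`, `sd`.
#' @export
derivative_stats <- function(x, fs, framing = framing_spec()) {
  frames <- frame_index_list(length(x), fs, framing)
  out <- t(vapply(frames, function(idx) {
    if (length(idx) < 2) stop("frame must contain at least 2 samples")
    d <- diff(x[idx]) * fs
    c(max = max(d), mean = mean(d), sd = if (length(d) > 1) sd(d) else 0)
  }, numeric(3)))
  rownames(out) <- NULL
  out
}

#' Per-frame STFT spectrogram energy
#'
#' Energy of each 4 s frame as the sum over frequency bins of the squared
#' magnitude of its Hann-windowed Fourier transform, scaled by `1/L` so
#' that (by Parseval) it equals the energy of the windowed frame.
#'
#' @inheritParams spectral_entropy
#' @return Numeric vector with one energy per frame.
#' @export
stft_frame_energy <- function(x, fs, framing = framing_spec()) {
  frames <- frame_index_list(length(x), fs, framing)
  vapply(frames, function(idx) {
    seg <- x[idx]
    L <- length(seg)
    sum(Mod(fft(seg * hann_window(L)))^2) / L
  }, numeric(1))
}

# Per-modality scattering configurations: three layers for the
# high-frequency channels, two for the low-frequency ones. f_min reflects
# each channel's physiological band (corrugator EMG has no content below
# ~1 Hz; pulse rate stays above 0.5 Hz).
modality_scattering_q <- list(
  EMG = c(8, 4, 1), BVP = c(8, 4, 1), EDA = c(8, 1), RSP = c(8, 1)
)
modality_f_min <- list(EMG = 1, BVP = 0.5, EDA = NULL, RSP = NULL)

#' Preprocess a recording for feature extraction
#'
#' Resamples every channel to its target rate (EMG 256, BVP 64, EDA 8,
#' RSP 8, GRIP 75 Hz), applies Gaussian smoothing to EDA, decomposes the
#' smoothed EDA by convex optimization, and replaces the EDA samples with
#' the phasic component (the tonic drift and noise are discarded for
#' further analysis). The full decomposition is attached as attribute
#' `"eda_decomposition"`.
#'
#' @param recording A [multimodal_recording()].
#' @param targets Named target rates in Hz.
#' @param ... Passed to [decompose_eda()].
#' @return The preprocessed `multimodal_recording` with an
#'   `eda_decomposition` attribute and `preprocessed = TRUE`.
#' @export
preprocess_recording <- function(recording, targets = TARGET_RATES, ...) {
  stopifnot(inherits(recording, "multimodal_recording"))
  for (nm in names(recording$channels)) {
    recording$channels[[nm]] <-
      resample_channel(recording$channels[[nm]], targets[[nm]])
  }
  eda <- gaussian_smooth(recording$channels$EDA)
  dec <- decompose_eda(eda, ...)
  recording$channels$EDA <- channel_signal("EDA", dec$phasic,
                                           fs = eda$fs, t0 = eda$t0)
  attr(recording, "eda_decomposition") <- dec
  attr(recording, "preprocessed") <- TRUE
  recording
}

#' Extract the per-frame feature matrix of one recording
#'
#' In `"scattering"` mode (default): 20 scattering-energy columns (6 each
#' for EMG and BVP, three-layer banks; 4 each for the phasic EDA and RSP,
#' two-layer banks), 2 spectral-entropy columns (EMG, RSP), 4 time-domain
#' statistics for each of phasic EDA and RSP, and 3 first-derivative
#' statistics for phasic EDA - 33 features. In `"stft"` mode the 20
#' scattering energies are replaced by 4 STFT frame energies (EMG, BVP,
#' EDA, RSP) - 17 features. GRIP carries no default features. All
#' modalities share one frame grid.
#'
#' @param recording A preprocessed [multimodal_recording()] (see
#'   [preprocess_recording()]); the EDA channel must already be the phasic
#'   component.
#' @param mode `"scattering"` or `"stft"`.
#' @param framing A [framing_spec()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (frames x features), `feature_names`, `subject_id`, `frame_start_s`.
#' @export
extract_features <- function(recording, mode = c("scattering", "stft"),
                             framing = framing_spec()) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "multimodal_recording"))
  if (!isTRUE(attr(recording, "preprocessed")))
    warning("recording does not appear to be preprocessed; ",
            "call preprocess_recording() first")
  dur <- recording_duration(recording)
  nf <- n_frames(dur, framing)   # errors if shorter than one frame

  cols <- list()
  nms <- character(0)
  add <- function(values, names) {
    cols[[length(cols) + 1]] <<- values
    nms <<- c(nms, names)
  }

  spectral_modalities <- c("EMG", "BVP", "EDA", "RSP")
  if (mode == "scattering") {
    for (nm in spectral_modalities) {
      ch <- recording$channels[[nm]]
      cfg <- scattering_config(ch$fs, q = modality_scattering_q[[nm]],
                               invariance_scale_s = framing$window_s,
                               hop_fraction = framing$hop_s / framing$window_s,
                               f_min = modality_f_min[[nm]])
      sc <- scattering_transform(trim_to_duration(ch, dur), cfg,
                                 u_frames = nf)
      sc <- align_frames(sc, nf)
      en <- frame_energy(sc)
      add(en, paste0(nm, "_", colnames(en), "_energy"))
    }
  } else {
    for (nm in spectral_modalities) {
      ch <- trim_to_duration(recording$channels[[nm]], dur)
      add(matrix(stft_frame_energy(ch$samples, ch$fs, framing), ncol = 1),
          paste0(nm, "_stft_energy"))
    }
  }

  for (nm in c("EMG", "RSP")) {
    ch <- trim_to_duration(recording$channels[[nm]], dur)
    add(matrix(spectral_entropy(ch$samples, ch$fs, framing), ncol = 1),
        paste0(nm, "_spec_entropy"))
  }
  for (nm in c("EDA", "RSP")) {
    ch <- trim_to_duration(recording$channels[[nm]], dur)
    st <- time_domain_stats(ch$samples, ch$fs, framing)
    add(st, paste0(nm, "_", colnames(st)))
  }
  ch <- trim_to_duration(recording$channels$EDA, dur)
  dv <- derivative_stats(ch$samples, ch$fs, framing)
  add(dv, paste0("EDA_d1_", colnames(dv)))

  values <- do.call(cbind, cols)
  colnames(values) <- nms
  stopifnot(nrow(values) == nf, !anyNA(values), all(is.finite(values)))
  structure(
    list(values = values, feature_names = nms,
         subject_id = recording$subject_id,
         frame_start_s = (seq_len(nf) - 1) * framing$hop_s,
         framing = framing, mode = mode),
    class = "feature_matrix"
  )
}

trim_to_duration <- function(ch, dur) {
  n <- min(length(ch$samples), floor(dur * ch$fs + 1e-9))
  channel_signal(ch$name, ch$samples[seq_len(n)], ch$fs, ch$t0)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix subject %s: %d frames x %d features (%s)>\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(subject_id = x$subject_id, frame_start_s = x$frame_start_s,
             x$values, check.names = FALSE)
}

#' Subject-based z-score normalization
#'
#' Per subject and per feature column, subtracts that subject's column
#' mean and divides by that subject's sample standard deviation;
#' zero-variance columns become all zeros.
#'
#' @param x A [extract_features()] result (one subject) or a list of them
#'   (normalized independently per subject).
#' @return Object(s) of the same shape with normalized `values`.
#' @export
zscore_by_subject <- function(x) {
  if (is.list(x) && !inherits(x, "feature_matrix"))
    return(lapply(x, zscore_by_subject))
  stopifnot(inherits(x, "feature_matrix"))
  if (nrow(x$values) < 2)
    stop("subject ", x$subject_id, " has fewer than 2 frames")
  mu <- colMeans(x$values)
  sigma <- apply(x$values, 2, sd)
  z <- sweep(x$values, 2, mu)
  nz <- sigma > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sigma[nz], `/`)
  z[, !nz] <- 0
  x$values <- z
  x
}
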