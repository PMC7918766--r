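# Synthetic multimodal cohorts with known ground truth. The generator
# emulates the structure of a fascial-therapy session: a no-pain baseline
# followed by 2-3 minutes of therapy during which pain episodes jointly
# modulate all five channels, and the subject verbalizes delayed, discretized
# 0-10 ratings.

#' Simulation configuration
#'
#' Defines the study conditions emulated by the simulator. Defaults follow
#' the session protocol (30 s baseline, 2.5-3.5 min sessions) with
#' conservative physiological parameter choices; see the package vignette
#' for the rationale behind each value.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param session_s Session length range in seconds; each subject's length
#'   is drawn uniformly from it (default `c(150, 210)`).
#' @param baseline_s No-pain baseline length in seconds (default 30).
#' @param episode_rate Pain episodes per minute of therapy (default 2).
#' @param reactivity_ranges Named list of per-channel multiplicative gain
#'   intervals for subject-specific responsiveness; gains are drawn
#'   log-uniformly per subject.
#' @param report_delay_s Mean self-report latency in seconds (default 2).
#' @param report_jitter_s Standard deviation of the latency jitter
#'   (default 0.5; latencies are floored at 0).
#' @param noise_levels Named list of per-channel additive noise standard
#'   deviations.
#' @param pain_decay_s Time constant of the latent pain decay between
#'   episodes (default 90 s; fascial pressure is sustained, so the latent
#'   level decays slowly rather than returning to zero between reports).
#' @param tau0,tau1 Bateman kernel time constants of simulated skin
#'   conductance responses in seconds (defaults 0.7 and 2.0).
#' @param native_rates Named list of device sampling rates before
#'   resampling.
#' @param seed Integer seed controlling the whole cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 34,
                       session_s = c(150, 210),
                       baseline_s = 30,
                       episode_rate = 2,
                       reactivity_ranges = list(
                         EDA = c(0.5, 2), EMG = c(0.5, 2), RSP = c(0.5, 2),
                         BVP = c(0.5, 2), GRIP = c(0.5, 2)
                       ),
                       report_delay_s = 2,
                       report_jitter_s = 0.5,
                       noise_levels = list(
                         EDA = 0.01, EMG = 0.05, RSP = 0.02,
                         BVP = 0.02, GRIP = 0.02
                       ),
                       pain_decay_s = 90,
                       tau0 = 0.7, tau1 = 2.0,
                       native_rates = list(
                         EDA = 16, EMG = 512, RSP = 16, BVP = 128, GRIP = 150
                       ),
                       seed = 1) {
  if (length(session_s) == 1) session_s <- c(session_s, session_s)
  stopifnot(
    is_count(n_subjects),
    all(session_s > 0), session_s[2] >= session_s[1],
    baseline_s > 0, baseline_s < session_s[1],
    episode_rate >= 0, report_delay_s >= 0, report_jitter_s >= 0,
    pain_decay_s > 0, tau0 > 0, tau1 > tau0
  )
  structure(
    list(n_subjects = n_subjects, session_s = session_s,
         baseline_s = baseline_s, episode_rate = episode_rate,
         reactivity_ranges = reactivity_ranges,
         report_delay_s = report_delay_s, report_jitter_s = report_jitter_s,
         noise_levels = noise_levels, pain_decay_s = pain_decay_s,
         tau0 = tau0, tau1 = tau1, native_rates = native_rates,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Bateman impulse response of a skin conductance response
#'
#' `h(t) = exp(-t / tau1) - exp(-t / tau0)` for `t >= 0`, normalized to unit
#' peak. `tau0` is the rise and `tau1` the recovery time constant.
#'
#' @param tau0 Rise time constant in seconds (`0 < tau0 < tau1`).
#' @param tau1 Recovery time constant in seconds.
#' @param fs Sampling rate in Hz.
#' @param duration_s Length of the returned response in seconds.
#' @return Numeric vector of `floor(duration_s * fs) + 1` samples.
#' @export
bateman_kernel <- function(tau0, tau1, fs, duration_s) {
  if (!(tau0 > 0 && tau1 > tau0)) stop("need 0 < tau0 < tau1")
  stopifnot(fs > 0, duration_s > 0)
  t <- seq(0, duration_s, by = 1 / fs)
  h <- exp(-t / tau1) - exp(-t / tau0)
  h / max(h)
}

# Latent pain trace on a time grid: each episode resets the level to its
# intensity, which then decays exponentially with pain_decay_s.
latent_pain_trace <- function(t, episode_times, episode_intensities, decay_s) {
  level <- numeric(length(t))
  if (!length(episode_times)) return(level)
  idx <- findInterval(t, episode_times)
  has <- idx >= 1
  level[has] <- episode_intensities[idx[has]] *
    exp(-(t[has] - episode_times[idx[has]]) / decay_s)
  level
}

#' Simulate one subject session
#'
#' Generates all five channels at their native device rates plus delayed,
#' discretized self-reports, jointly driven by a latent 0-10 pain trace:
#' EDA receives Bateman-kernel SCR bursts at episode onsets over a slow
#' tonic drift; EMG is an amplitude-modulated corrugator burst signal; RSP
#' a breathing oscillation whose rate and amplitude shift with pain; BVP a
#' pulse waveform with pain-linked heart-rate increase and amplitude
#' attenuation; GRIP a baseline force with smooth squeeze transients during
#' intense episodes. Deterministic for fixed `(config$seed, subject_index)`.
#'
#' @param config A [sim_config()].
#' @param subject_index Subject number within the cohort (1-based).
#' @return A list with elements `recording` (a [multimodal_recording()])
#'   and `truth` (ground truth: episode times/intensities, per-channel
#'   reactivity gains, the noise-free injected EDA phasic component, SCR
#'   amplitudes, and the latent pain trace sampled at 8 Hz).
#' @export
simulate_subject <- function(config, subject_index = 1) {
  stopifnot(inherits(config, "sim_config"), is_count(subject_index))
  with_seed(child_seed(config$seed, subject_index), {
    dur <- round(runif(1, config$session_s[1], config$session_s[2]))
    b0 <- config$baseline_s

    gains <- lapply(config$reactivity_ranges, function(rg) {
      exp(runif(1, log(rg[1]), log(rg[2])))
    })

    # Pain episodes: Poisson count over the therapy span, uniform times.
    n_ep <- rpois(1, config$episode_rate * (dur - b0) / 60)
    ep_t <- sort(runif(n_ep, b0 + 2, dur - 5))
    # Enforce a minimal 4 s separation so episodes stay distinguishable.
    if (n_ep > 1) {
      keep <- c(TRUE, diff(ep_t) > 4)
      ep_t <- ep_t[keep]
      n_ep <- length(ep_t)
    }
    ep_i <- runif(n_ep, 1, 10)

    lat_fs <- 8
    t_lat <- seq(0, dur - 1 / lat_fs, by = 1 / lat_fs)
    latent <- latent_pain_trace(t_lat, ep_t, ep_i, config$pain_decay_s)

    channels <- list()

    ## EDA: tonic drift + Bateman SCRs scaled by intensity + noise
    fs <- config$native_rates$EDA
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    tonic <- 2 + 0.3 * sin(2 * pi * t / dur * runif(1, 0.5, 1.5) +
                             runif(1, 0, 2 * pi)) + 0.001 * t
    driver <- numeric(n)
    scr_amp <- gains$EDA * 0.08 * ep_i
    driver[pmin(n, floor(ep_t * fs) + 1)] <- scr_amp
    kern <- bateman_kernel(config$tau0, config$tau1, fs,
                           duration_s = 10 * config$tau1)
    phasic_clean <- fft_conv_full(driver, kern)[seq_len(n)]
    channels$EDA <- channel_signal(
      "EDA", tonic + phasic_clean + rnorm(n, 0, config$noise_levels$EDA), fs)

    ## EMG: baseline tone + amplitude-modulated white-noise bursts
    fs <- config$native_rates$EMG
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    lat_emg <- approx(t_lat, latent, t, rule = 2)$y
    envelope <- 0.05 + gains$EMG * 0.06 * lat_emg
    carrier <- rnorm(n)
    channels$EMG <- channel_signal(
      "EMG", envelope * carrier + rnorm(n, 0, config$noise_levels$EMG), fs)

    ## RSP: breathing oscillation, rate and amplitude shift with pain
    fs <- config$native_rates$RSP
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    lat_rsp <- approx(t_lat, latent, t, rule = 2)$y
    f_breath <- 0.25 * (1 + gains$RSP * 0.06 * lat_rsp)
    phase <- 2 * pi * cumsum(f_breath) / fs
    amp <- 1 + gains$RSP * 0.05 * lat_rsp
    channels$RSP <- channel_signal(
      "RSP", amp * sin(phase) + rnorm(n, 0, config$noise_levels$RSP), fs)

    ## BVP: pulse waveform with harmonics; HR rises, amplitude dips with pain
    fs <- config$native_rates$BVP
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    lat_bvp <- approx(t_lat, latent, t, rule = 2)$y
    hr <- (70 + gains$BVP * 2.5 * lat_bvp) / 60
    phase <- 2 * pi * cumsum(hr) / fs
    amp <- 1 - gains$BVP * 0.04 * lat_bvp
    pulse <- sin(phase) + 0.4 * sin(2 * phase + 0.8) + 0.15 * sin(3 * phase + 1.6)
    channels$BVP <- channel_signal(
      "BVP", amp * pulse + rnorm(n, 0, config$noise_levels$BVP), fs)

    ## GRIP: baseline force + smooth squeezes during intense episodes
    fs <- config$native_rates$GRIP
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    n <- length(t)
    grip <- rep(0.2, n)
    for (k in seq_len(n_ep)) {
      if (ep_i[k] >= 5) {
        w <- 1.5 + 0.2 * ep_i[k]
        grip <- grip + gains$GRIP * 0.05 * ep_i[k] *
          exp(-0.5 * ((t - ep_t[k] - w / 2) / (w / 2))^2)
      }
    }
    channels$GRIP <- channel_signal(
      "GRIP", grip + rnorm(n, 0, config$noise_levels$GRIP), fs)

    ## Reports: rounded latent intensity at episodes, delayed with jitter;
    ## one explicit zero during the baseline.
    delays <- pmax(0, config$report_delay_s +
                     rnorm(n_ep, 0, config$report_jitter_s))
    rep_t <- ep_t + delays
    rep_r <- pmin(10, pmax(0, round(ep_i)))
    ord <- order(rep_t)
    rep_t <- rep_t[ord]; rep_r <- rep_r[ord]
    if (length(rep_t) > 1) {
      keep <- c(TRUE, diff(rep_t) > 0.5)   # drop near-simultaneous reports
      rep_t <- rep_t[keep]; rep_r <- rep_r[keep]
    }
    rep_t <- c(b0 / 2, rep_t)
    rep_r <- c(0, rep_r)
    reports <- pain_reports(round(rep_t, 2), rep_r)

    recording <- multimodal_recording(
      subject_id = sprintf("S%02d", subject_index),
      channels = channels, reports = reports, baseline_end = b0
    )
    truth <- list(
      episode_times = ep_t,
      episode_intensities = ep_i,
      report_delays = if (n_ep) delays else numeric(0),
      gains = gains,
      scr_amplitudes = scr_amp,
      eda_phasic_clean = phasic_clean,
      eda_fs = config$native_rates$EDA,
      latent_fs = lat_fs,
      latent = latent
    )
    list(recording = recording, truth = truth)
  })
}

fft_conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- nextn(n, c(2, 3, 5))
  X <- fft(c(x, rep(0, nf - length(x))))
  H <- fft(c(h, rep(0, nf - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

#' Simulate a cohort of subjects
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, each subject is written
#'   in the standard recording layout under `out_dir/S01`, ... together
#'   with a `ground_truth.json`.
#' @return A list of `n_subjects` elements, each as returned by
#'   [simulate_subject()].
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- lapply(seq_len(config$n_subjects),
                   function(i) simulate_subject(config, i))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sub in cohort) {
      write_recording(sub$recording,
                      file.path(out_dir, sub$recording$subject_id))
    }
    gt <- lapply(cohort, function(sub) {
      tr <- sub$truth
      list(subject_id = sub$recording$subject_id,
           episode_times = tr$episode_times,
           episode_intensities = tr$episode_intensities,
           gains = tr$gains)
    })
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cohort
}

#' Ground-truth per-frame pain classes for a simulated subject
#'
#' Applies the same double-threshold rule as [label_frames()] to the latent
#' pain trace (maximum latent value per frame).
#'
#' @param truth The `truth` element returned by [simulate_subject()].
#' @param framing A [framing_spec()].
#' @param config A [labeling_config()] providing the two thresholds.
#' @return Factor of per-frame latent classes.
#' @export
latent_frame_classes <- function(truth, framing = framing_spec(),
                                 config = labeling_config()) {
  dur <- length(truth$latent) / truth$latent_fs
  nf <- n_frames(dur, framing)
  starts <- (seq_len(nf) - 1) * framing$hop_s
  cls <- vapply(starts, function(s) {
    idx <- which((seq_along(truth$latent) - 1) / truth$latent_fs >= s &
                   (seq_along(truth$latent) - 1) / truth$latent_fs < s + framing$window_s)
    m <- max(truth$latent[idx])
    if (m < config$t_low) "no_pain"
    else if (m >= config$t_high) "severe_pain" else "moderate_pain"
  }, character(1))
  factor(cls, levels = PAIN_CLASSES)
}
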