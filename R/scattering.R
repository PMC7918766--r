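# Deep 1-D wavelet scattering transform.
#
# Layer n computes U_n = |U_{n-1} * psi| over a Morlet filter bank and
# S_n = U_n * phi sampled on the frame grid; the modulus recovers the
# high-frequency content that the averaging removes, and the cascade
# repeats along frequency-decreasing paths only. Filters are defined in
# the frequency domain; each layer's bank is Littlewood-Paley normalized
# to a frame bound of 1, which makes the transform nonexpansive.

#' Scattering filter bank configuration
#'
#' @param fs Sampling rate of the analyzed signal in Hz.
#' @param q Ordered integer vector of voices per octave, one entry per
#'   layer (e.g. `c(8, 4, 1)` for a three-layer transform on
#'   high-frequency channels, `c(8, 1)` for the low-frequency ones).
#' @param invariance_scale_s Averaging window of the low-pass `phi` in
#'   seconds (default 4).
#' @param hop_fraction Frame hop as a fraction of the window (default 0.5,
#'   i.e. 50% overlap).
#' @param f_min Lowest wavelet center frequency in Hz. Defaults to the
#'   half-power cutoff of `phi`; frequencies below it are captured by the
#'   averaging itself.
#' @return An object of class `scattering_config`.
#' @export
scattering_config <- function(fs, q = c(8, 4, 1), invariance_scale_s = 4,
                              hop_fraction = 0.5, f_min = NULL) {
  stopifnot(fs > 0, invariance_scale_s > 0,
            hop_fraction > 0, hop_fraction <= 1)
  q <- as.integer(q)
  if (!length(q) || any(q < 1)) stop("`q` must be positive integers")
  if (invariance_scale_s * fs < 2)
    stop("invariance scale must span at least 2 samples")
  sigma_t <- invariance_scale_s / 4
  phi_cut <- sqrt(log(2) / 2) / (pi * sigma_t)   # half-power frequency of phi
  structure(
    list(fs = fs, q = q, invariance_scale_s = invariance_scale_s,
         hop_fraction = hop_fraction,
         hop_s = invariance_scale_s * hop_fraction,
         sigma_t = sigma_t,
         f_min = f_min %||% phi_cut),
    class = "scattering_config"
  )
}

#' Build the Morlet filter banks of a scattering transform
#'
#' Center frequencies descend geometrically from just below Nyquist by
#' `2^(1/Q)` per filter until `f_min`. Each wavelet is a frequency-domain
#' Gaussian with an admissibility correction term enforcing zero mean; the
#' low-pass `phi` is a Gaussian matched to the invariance scale. Every
#' layer is normalized so its Littlewood-Paley sum
#' `|phi|^2 + sum_j |psi_j|^2` peaks at exactly 1.
#'
#' @param config A [scattering_config()].
#' @return An object of class `scattering_filterbank`: per layer, the
#'   wavelet center frequencies `xi`, bandwidths `sigma`, and the common
#'   normalization; evaluate on a grid with [filter_response()].
#' @export
build_filterbank <- function(config) {
  stopifnot(inherits(config, "scattering_config"))
  fs <- config$fs
  layers <- lapply(config$q, function(Q) {
    xi_max <- fs / 2 * 2^(-1 / Q)
    if (xi_max <= config$f_min)
      stop("no wavelet fits between f_min and Nyquist for Q = ", Q)
    n_filt <- floor(log2(xi_max / config$f_min) * Q) + 1
    xi <- xi_max * 2^(-(seq_len(n_filt) - 1) / Q)
    sigma <- xi * (2^(1 / Q) - 1) / sqrt(2 * log(2))
    bank <- list(Q = Q, xi = xi, sigma = sigma, sigma_t = config$sigma_t,
                 norm = 1)
    # Littlewood-Paley normalization: linear plus octave-spaced grids,
    # refined around every filter peak (low-frequency filters are far
    # narrower than any practical uniform grid).
    grid <- sort(unique(c(
      seq(0, fs / 2, length.out = 4096),
      min(xi) * 2^seq(-4, log2(fs / 2 / min(xi)), length.out = 8192),
      unlist(lapply(seq_len(n_filt), function(j)
        xi[j] + sigma[j] * seq(-6, 6, length.out = 97)))
    )))
    grid <- grid[grid >= 0 & grid <= fs / 2]
    lp <- lp_sum_raw(bank, grid)
    bank$norm <- sqrt(max(lp))
    bank
  })
  structure(list(config = config, layers = layers),
            class = "scattering_filterbank")
}

# Unnormalized Littlewood-Paley sum of one layer on a frequency grid.
lp_sum_raw <- function(bank, freqs) {
  a <- phi_hat_raw(freqs, bank$sigma_t)^2
  for (j in seq_along(bank$xi)) {
    a <- a + psi_hat_raw(freqs, bank$xi[j], bank$sigma[j])^2
  }
  a
}

#' Littlewood-Paley sum of one filter-bank layer
#'
#' @param filterbank A [build_filterbank()] result.
#' @param layer Layer index.
#' @param freqs Frequencies in Hz at which to evaluate.
#' @return `|phi|^2 + sum_j |psi_j|^2` at `freqs` (normalized layer).
#' @export
lp_sum <- function(filterbank, layer, freqs) {
  bank <- filterbank$layers[[layer]]
  lp_sum_raw(bank, freqs) / bank$norm^2
}

# Morlet wavelet in the frequency domain: Gaussian at xi with an
# admissibility correction so that psi_hat(0) = 0 (zero mean in time).
psi_hat_raw <- function(f, xi, sigma) {
  g <- exp(-(f - xi)^2 / (2 * sigma^2))
  corr <- exp(-xi^2 / (2 * sigma^2)) * exp(-f^2 / (2 * sigma^2))
  g - corr
}

phi_hat_raw <- function(f, sigma_t) exp(-2 * pi^2 * sigma_t^2 * f^2)

#' Evaluate one filter of a bank on a frequency grid
#'
#' @param filterbank A [build_filterbank()] result.
#' @param layer Layer index.
#' @param index Wavelet index within the layer, or `0` for `phi`.
#' @param freqs Frequencies in Hz.
#' @return The (normalized) frequency response.
#' @export
filter_response <- function(filterbank, layer, index, freqs) {
  bank <- filterbank$layers[[layer]]
  if (index == 0) return(phi_hat_raw(freqs, bank$sigma_t) / bank$norm)
  psi_hat_raw(freqs, bank$xi[index], bank$sigma[index]) / bank$norm
}

#' Number of analysis frames for a given duration
#'
#' Half-open frames `[start, start + window)` with the configured hop:
#' `floor((D - window) / hop) + 1`.
#'
#' @param duration_s Signal duration in seconds.
#' @param framing A [framing_spec()].
#' @return Integer frame count.
#' @export
n_frames <- function(duration_s, framing = framing_spec()) {
  if (duration_s < framing$window_s) stop("signal shorter than one window")
  floor((duration_s - framing$window_s) / framing$hop_s + 1e-9) + 1
}

#' Deep wavelet scattering transform of a 1-D signal
#'
#' Computes scalograms `U_n` (wavelet modulus coefficients) and
#' scattergrams `S_n` (`U_n` averaged by `phi` and subsampled to the frame
#' grid) for every layer of the configuration, retaining only
#' frequency-decreasing paths. Boundaries are handled by reflection
#' padding of one invariance window per side.
#'
#' @param x Numeric signal (or a [channel_signal()], whose rate overrides
#'   `config$fs` check).
#' @param config A [scattering_config()].
#' @param filterbank Optional pre-built [build_filterbank()].
#' @param u_frames If not `NULL`, the returned `U` matrices are
#'   Fourier-resampled to this many time points (memory-friendly for long
#'   high-rate signals); `NULL` keeps the native sampling.
#' @return An object of class `scattering_output` with lists `S` and `U`
#'   of per-layer matrices (paths x time), `path_metadata` (a data frame
#'   with layer, path index, and the center-frequency chain), `n_frames`,
#'   and `frame_times` (frame start times in seconds).
#' @export
scattering_transform <- function(x, config, filterbank = NULL,
                                 u_frames = NULL) {
  if (inherits(x, "channel_signal")) {
    if (abs(x$fs - config$fs) > 1e-9)
      stop("signal rate does not match the filter bank configuration")
    x <- x$samples
  }
  stopifnot(inherits(config, "scattering_config"), is.numeric(x))
  fs <- config$fs
  N <- length(x)
  T_s <- config$invariance_scale_s
  if (N / fs < T_s) stop("signal shorter than one invariance window")
  fb <- filterbank %||% build_filterbank(config)
  nf <- n_frames(N / fs, framing_spec(T_s, config$hop_s))

  w <- round(T_s * fs)
  xe <- reflect_pad(x, min(w, N))
  w <- min(w, N)
  Nf <- nextn(length(xe), c(2, 3, 5))
  xe <- c(xe, rep(0, Nf - length(xe)))

  # Frequency grid of the padded FFT (wrapped to +/- Nyquist).
  k <- 0:(Nf - 1)
  fgrid <- k * fs / Nf
  fgrid[fgrid >= fs / 2] <- fgrid[fgrid >= fs / 2] - fs

  banks <- lapply(fb$layers, function(bank) {
    psi <- lapply(seq_along(bank$xi), function(j) {
      psi_hat_raw(fgrid, bank$xi[j], bank$sigma[j]) / bank$norm
    })
    list(psi = psi, xi = bank$xi,
         phi = phi_hat_raw(fgrid, bank$sigma_t) / bank$norm)
  })

  # Frame-center sample indices inside the padded series (1-based).
  frame_centers <- w + round(((seq_len(nf) - 1) * config$hop_s + T_s / 2) * fs) + 1
  frame_centers <- pmin(frame_centers, w + N)
  crop <- (w + 1):(w + N)

  n_layers <- length(config$q)
  acc <- new.env(parent = emptyenv())
  acc$S <- vector("list", n_layers)
  acc$U <- vector("list", n_layers)
  acc$meta <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    acc$S[[l]] <- list(); acc$U[[l]] <- list(); acc$meta[[l]] <- list()
  }

  store_path <- function(layer, u, u_fft, xi_chain) {
    # S row: phi-average sampled at frame centers.
    s_full <- Re(fft(u_fft * banks[[layer]]$phi, inverse = TRUE)) / Nf
    s_row <- pmax(0, s_full[frame_centers])
    u_time <- u[crop]
    if (!is.null(u_frames) && u_frames != N) {
      u_time <- pmax(0, fft_resample(u_time, u_frames))
    }
    i <- length(acc$S[[layer]]) + 1
    acc$S[[layer]][[i]] <- s_row
    acc$U[[layer]][[i]] <- u_time
    acc$meta[[layer]][[i]] <- xi_chain
    invisible(NULL)
  }

  descend <- function(parent_fft, layer, xi_parent, xi_chain) {
    bank <- banks[[layer]]
    for (j in seq_along(bank$psi)) {
      # strictly frequency-decreasing paths (relative tolerance guards
      # floating-point ties between layers sharing dyadic frequencies)
      if (!is.null(xi_parent) && bank$xi[j] >= xi_parent * (1 - 1e-9)) next
      u <- Mod(fft(parent_fft * bank$psi[[j]], inverse = TRUE)) / Nf
      u_fft <- fft(u)
      store_path(layer, u, u_fft, c(xi_chain, bank$xi[j]))
      if (layer < n_layers) {
        descend(u_fft, layer + 1, bank$xi[j], c(xi_chain, bank$xi[j]))
      }
    }
  }

  descend(fft(xe), 1, NULL, numeric(0))

  S <- lapply(acc$S, function(rows) do.call(rbind, rows))
  U <- lapply(acc$U, function(rows) do.call(rbind, rows))
  meta <- do.call(rbind, lapply(seq_len(n_layers), function(l) {
    chains <- acc$meta[[l]]
    data.frame(
      layer = rep(l, length(chains)),
      path = seq_along(chains),
      xi = vapply(chains, function(ch) ch[length(ch)], numeric(1)),
      xi_chain = vapply(chains, function(ch)
        paste(signif(ch, 6), collapse = ">"), character(1))
    )
  }))
  structure(
    list(S = S, U = U, path_metadata = meta, n_frames = nf,
         frame_times = (seq_len(nf) - 1) * config$hop_s,
         fs = fs, config = config),
    class = "scattering_output"
  )
}

#' @export
print.scattering_output <- function(x, ...) {
  paths <- vapply(x$S, nrow, integer(1))
  cat(sprintf("<scattering_output: %d layers (%s paths), %d frames>\n",
              length(x$S), paste(paths, collapse = "+"), x$n_frames))
  invisible(x)
}

#' Align all scattering matrices to a common number of time points
#'
#' Every `S` and `U` matrix is resampled along time with Fourier-domain
#' interpolation; rows already at `n_frames` points pass through
#' unchanged. Mean-square energy per path is preserved for band-limited
#' rows.
#'
#' @param output A [scattering_transform()] result.
#' @param n_frames Target number of time points (>= 1).
#' @return The aligned `scattering_output`.
#' @export
align_frames <- function(output, n_frames) {
  stopifnot(inherits(output, "scattering_output"), is_count(n_frames))
  resample_mat <- function(M) {
    if (is.null(M) || ncol(M) == n_frames) return(M)
    out <- t(apply(M, 1, fft_resample, n_out = n_frames))
    pmax(out, 0)   # interpolation ringing may dip below the modulus floor
  }
  output$S <- lapply(output$S, resample_mat)
  output$U <- lapply(output$U, resample_mat)
  output$n_frames <- n_frames
  output
}
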