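# Convex tonic/phasic decomposition of skin conductance.
#
# The signal y is modeled as tonic + phasic + noise, with the phasic part
# generated by a sparse nonnegative sudomotor driver p convolved with the
# Bateman kernel: minimize
#     0.5 * ||y - M p - B l||^2 + alpha * ||p||_1 + 0.5 * lambda_t * ||l_s||^2
#     subject to p >= 0,
# where M applies the Bateman convolution (discrete ARMA filter obtained by
# bilinear mapping of the kernel's Laplace-domain transfer function), B is a
# coarse cubic B-spline tonic basis extended with an offset and linear
# drift, and the ridge penalty acts on the spline coefficients l_s only.
# Solved with monotone FISTA (deterministic).

#' Decompose an EDA signal into tonic, phasic, and noise components
#'
#' @param signal A [channel_signal()] named `EDA` (typically at 8 Hz after
#'   resampling and Gaussian smoothing).
#' @param tau0 Bateman rise time constant in seconds (default 0.7).
#' @param tau1 Bateman recovery time constant in seconds (default 2.0;
#'   must exceed `tau0`).
#' @param alpha Sparsity weight on the driver (default `8e-4`).
#' @param lambda_t Ridge weight on the tonic spline coefficients
#'   (default `1e-2`).
#' @param knot_s Tonic spline knot spacing in seconds (default 10).
#' @param max_iter,tol FISTA iteration cap and relative-change stopping
#'   tolerance.
#' @return An object of class `eda_decomposition` with numeric fields
#'   `tonic`, `phasic`, `noise` (elementwise `tonic + phasic + noise`
#'   equals the input), and the nonnegative sparse `driver`, plus the
#'   solver's `iterations` and `converged` flag.
#' @export
decompose_eda <- function(signal, tau0 = 0.7, tau1 = 2.0,
                          alpha = 8e-4, lambda_t = 1e-2,
                          knot_s = 10, max_iter = 3000, tol = 1e-10) {
  stopifnot(inherits(signal, "channel_signal"))
  if (!(tau0 > 0 && tau1 > tau0)) stop("need 0 < tau0 < tau1")
  y <- signal$samples
  if (!all(is.finite(y))) stop("non-finite input")
  fs <- signal$fs
  n <- length(y)

  ba <- bateman_arma(tau0, tau1, fs)
  M_apply <- function(p) as.numeric(signal::filter(ba$b, ba$a, p))
  Mt_apply <- function(v) rev(as.numeric(signal::filter(ba$b, ba$a, rev(v))))

  B <- tonic_basis(n, fs, knot_s)
  n_spline <- attr(B, "n_spline")
  pen <- c(rep(lambda_t, n_spline), 0, 0)   # no penalty on offset / drift

  # Lipschitz constant of the smooth part via power iteration on
  # [M B]^T [M B] + diag(pen).
  v_p <- rep(1, n); v_l <- rep(1, ncol(B))
  L <- 1
  for (it in 1:30) {
    r <- M_apply(v_p) + as.numeric(B %*% v_l)
    w_p <- Mt_apply(r)
    w_l <- as.numeric(crossprod(B, r)) + pen * v_l
    L <- sqrt(sum(w_p^2) + sum(w_l^2)) / sqrt(sum(v_p^2) + sum(v_l^2) + 1e-30)
    nrm <- sqrt(sum(w_p^2) + sum(w_l^2))
    if (nrm < 1e-30) break
    v_p <- w_p / nrm; v_l <- w_l / nrm
  }
  step <- 1 / (1.02 * max(L, 1e-12))

  objective <- function(p, l) {
    r <- y - M_apply(p) - as.numeric(B %*% l)
    0.5 * sum(r^2) + alpha * sum(p) + 0.5 * sum(pen * l^2)
  }

  p <- numeric(n); l <- numeric(ncol(B))
  zp <- p; zl <- l
  tk <- 1
  obj_prev <- objective(p, l)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    r <- M_apply(zp) + as.numeric(B %*% zl) - y
    g_p <- Mt_apply(r)
    g_l <- as.numeric(crossprod(B, r)) + pen * zl
    p_new <- pmax(0, zp - step * (g_p + alpha))
    l_new <- zl - step * g_l
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zp <- p_new + (tk - 1) / t_new * (p_new - p)
    zl <- l_new + (tk - 1) / t_new * (l_new - l)
    dx <- sqrt(sum((p_new - p)^2) + sum((l_new - l)^2))
    xn <- sqrt(sum(p_new^2) + sum(l_new^2))
    p <- p_new; l <- l_new; tk <- t_new
    if (iter %% 50 == 0) {
      obj <- objective(p, l)
      if (obj > obj_prev) {            # monotone restart
        zp <- p; zl <- l; tk <- 1
      }
      obj_prev <- obj
    }
    if (dx <= tol * (xn + 1e-12)) { converged <- TRUE; break }
  }

  phasic <- M_apply(p)
  tonic <- as.numeric(B %*% l)
  structure(
    list(tonic = tonic, phasic = phasic, noise = y - tonic - phasic,
         driver = p, fs = fs, iterations = iter, converged = converged,
         alpha = alpha, lambda_t = lambda_t, tau0 = tau0, tau1 = tau1),
    class = "eda_decomposition"
  )
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf(
    "<eda_decomposition: %d samples @ %g Hz, %d driver impulses, %s in %d iter>\n",
    length(x$phasic), x$fs, sum(x$driver > 1e-6 * max(x$driver, 1e-12)),
    if (x$converged) "converged" else "iteration cap reached", x$iterations))
  invisible(x)
}

# Discrete ARMA realization of the Bateman kernel: the Laplace transfer
# function of exp(-t/tau1) - exp(-t/tau0) has poles -1/tau0 and -1/tau1;
# the bilinear transform maps it to a second-order IIR filter, scaled so
# that the discrete impulse response has unit peak (matching
# bateman_kernel()).
bateman_arma <- function(tau0, tau1, fs) {
  flt <- signal::as.Arma(
    signal::bilinear(Sz = numeric(0), Sp = c(-1 / tau0, -1 / tau1),
                     Sg = 1 / tau0 - 1 / tau1, T = 1 / fs))
  b <- Re(flt$b); a <- Re(flt$a)
  imp <- c(1, numeric(ceiling(20 * tau1 * fs)))
  h <- as.numeric(signal::filter(b, a, imp))
  list(b = b / max(h), a = a)
}

# Tonic basis: cubic B-splines with knots every knot_s seconds, plus an
# unpenalized offset and linear drift column.
tonic_basis <- function(n, fs, knot_s) {
  t <- (seq_len(n) - 1) / fs
  dur <- t[n]
  inner <- seq(knot_s, dur - knot_s / 2, by = knot_s)
  inner <- inner[inner > 0 & inner < dur]
  if (length(inner)) {
    Bs <- splines::bs(t, knots = inner, degree = 3, intercept = FALSE)
  } else {
    Bs <- splines::bs(t, df = 3, degree = 3, intercept = FALSE)
  }
  B <- cbind(unclass(Bs), 1, t / max(dur, 1))
  attr(B, "n_spline") <- ncol(Bs)
  B
}
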