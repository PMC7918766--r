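# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed in [0, 2^31 - 2]; keeps independent stages of a
# run on separated streams without consuming the parent stream.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647
}

# Best rational approximation p/q of x with q <= max_den (continued
# fractions). Used to express a resampling ratio exactly.
rational_approx <- function(x, max_den = 1024L) {
  stopifnot(is.finite(x), x > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = p1, q = q1)
}

# Fourier-domain resampling of a real series to length `n_out`
# (band-limited interpolation; preserves DC exactly, mean-square energy for
# band-limited content).
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  stopifnot(n_out >= 1)
  if (n_out == n_in) return(x)
  X <- fft(x)
  Y <- complex(real = rep(0, n_out), imaginary = rep(0, n_out))
  keep <- min(n_in, n_out)
  half <- ceiling(keep / 2) - 1   # strictly positive frequencies copied as-is
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n_in - half + 1):n_in]
  }
  if (keep %% 2 == 0) {
    m <- keep / 2
    if (n_out < n_in) {
      # The +/- m bins of the input fold onto one output bin; their sum is
      # real for real input, keeping the result real.
      Y[m + 1] <- X[m + 1] + X[n_in + 1 - m]
    } else {
      # The input's real Nyquist bin is split across +/- m of the output.
      Y[m + 1] <- X[m + 1] / 2
      Y[n_out + 1 - m] <- X[m + 1] / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n_in
}

# Reflect-pad a series by `w` samples on each side.
reflect_pad <- function(x, w) {
  n <- length(x)
  if (w == 0) return(x)
  stopifnot(w <= n)
  left <- x[w:1]
  right <- x[n:(n - w + 1)]
  c(left, x, right)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
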