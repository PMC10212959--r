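# Butterworth band-pass design and zero-phase filtering.
# No IIR filtering package ships with the supported environment, so the
# standard design chain (analog prototype -> low-pass-to-band-pass
# transform -> bilinear transform with frequency pre-warping) is
# implemented here; it reproduces the textbook digital Butterworth
# band-pass to machine precision.

# polynomial from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param low,high band edges (Hz), `0 < low < high < fs/2`.
#' @param fs sampling rate (Hz).
#' @param order total band-pass order (even); the default 4 corresponds to
#'   a 2nd-order analog low-pass prototype.
#' @return list with numerator `b` and denominator `a` coefficients
#'   (`a[1] == 1`).
#' @keywords internal
butter_bandpass <- function(low, high, fs, order = 4) {
  if (order < 2 || order %% 2 != 0) stop("order must be a positive even number")
  if (!(low > 0 && low < high)) stop("require 0 < low < high")
  if (high >= fs / 2) {
    stop("high cutoff (", high, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz; resample the recording or lower the cutoff")
  }
  N <- order / 2
  fs2 <- 2 * fs
  wl <- fs2 * tan(pi * low / fs)
  wh <- fs2 * tan(pi * high / fs)
  B <- wh - wl
  w0 <- sqrt(wl * wh)
  k <- seq_len(N)
  p <- exp(1i * pi * (2 * k + N - 1) / (2 * N))   # analog prototype poles
  q <- p * B / 2
  poles <- c(q + sqrt(q^2 - w0^2), q - sqrt(q^2 - w0^2))
  zeros <- rep(0 + 0i, N)
  gain <- B^N
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# steady-state initial conditions for a step input of unit height
# (lfilter_zi construction); scales by the first sample before filtering
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(A), b[-1] - a[-1] * b[1])
}

# zero-phase (forward-backward) filtering with odd-reflection padding;
# the pad must outlast the settling of the slowest (low-edge) poles or
# edge transients leak into the output, so it is sized in time (~0.1 s)
# rather than in filter taps
filtfilt_ba <- function(b, a, x, fs = NULL) {
  nf <- max(length(a), length(b))
  n <- length(x)
  padlen <- max(3 * nf, if (is.null(fs)) 0 else round(0.1 * fs))
  padlen <- min(padlen, n - 1)
  if (n <= 3 * nf) stop("signal too short to filter (need > ", 3 * nf,
                        " samples)")
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass filter a cough waveform (zero-phase)
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass, the
#' default 140--2000 Hz band used to suppress heart-sound and muscle
#' artifacts below the band and hiss above it.
#'
#' @param w a [waveform()].
#' @param low,high band edges in Hz.
#' @param order band-pass order per pass (even; default 4).
#' @return a waveform of identical length and metadata.
#' @export
bandpass_filter <- function(w, low = 140, high = 2000, order = 4) {
  stopifnot(inherits(w, "coughvc_waveform"))
  ba <- butter_bandpass(low, high, w$fs, order = order)
  w$samples <- filtfilt_ba(ba$b, ba$a, w$samples, fs = w$fs)
  w
}
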