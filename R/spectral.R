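#' Zero-phase band-pass filtering
#'
#' Filters each region's signal with a Butterworth band-pass applied forward
#' and backward (zero phase, no group delay). The default order-4 design
#' (8 poles) attenuates by well over 20 dB one octave outside the band edges
#' while leaving the passband flat (monotone Butterworth response).
#'
#' @param ts numeric matrix, regions x samples (a vector is treated as one
#'   region).
#' @param fs sampling rate in Hz.
#' @param band a [band_spec()] or canonical band name.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered matrix of the same shape.
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 10 * (0:(2 * fs - 1)) / fs)
#' y <- bandpass(x, fs, "alpha")
#' @export
bandpass <- function(ts, fs, band, order = 4) {
  band <- as_band(band)
  ts <- as_ts_matrix(ts)
  check_scalar(fs, "fs", lower = 1e-12)
  if (band$hi >= fs / 2)
    stop_envdyn("band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
                band$lo, band$hi, fs / 2)
  flt <- signal::butter(order, c(band$lo, band$hi) / (fs / 2), type = "pass")
  zero_phase_filter(ts, flt)
}

#' Hilbert envelope extraction
#'
#' Computes the analytic signal of each (band-limited) region series by the
#' FFT method and returns the magnitude as the power envelope. The first and
#' last `edge_s` seconds are flagged for downstream exclusion because both
#' the band-pass filter and the Hilbert transform distort the signal edges.
#'
#' @param ts regions x samples matrix of band-limited signals.
#' @param fs sampling rate in Hz.
#' @param band optional [band_spec()] carried as metadata.
#' @param subject optional subject identifier carried as metadata.
#' @param edge_s edge margin in seconds flagged for exclusion (default 1).
#' @return An `envelope_set`: list with `values` (regions x samples,
#'   non-negative), `fs`, `band`, `subject` and `edge_s`.
#' @examples
#' fs <- 250
#' x <- cos(2 * pi * 10 * (0:(5 * fs - 1)) / fs)
#' env <- envelope(x, fs)
#' range(env$values[, keep_idx(env)])
#' @export
envelope <- function(ts, fs, band = NULL, subject = NULL, edge_s = 1) {
  ts <- as_ts_matrix(ts)
  check_scalar(fs, "fs", lower = 1e-12)
  if (ncol(ts) < 2 * fs)
    stop_envdyn("need at least 2 s of data (%d samples at %g Hz), got %d",
                ceiling(2 * fs), fs, ncol(ts))
  a <- analytic_signal(ts)
  envelope_set(Mod(a), fs, band = band, subject = subject, edge_s = edge_s)
}

#' Analytic signal (FFT-based Hilbert transform)
#'
#' @param ts regions x samples real matrix.
#' @return Complex matrix of the same shape; `Re()` reproduces the input and
#'   `Im()` is its Hilbert transform.
#' @export
analytic_signal <- function(ts) {
  ts <- as_ts_matrix(ts)
  n <- ncol(ts)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(t(ts)) * h
  t(mvfft(X, inverse = TRUE)) / n
}

#' Low-pass filtering of power envelopes
#'
#' Zero-phase Butterworth low-pass with unit DC gain; the canonical cutoff of
#' 1 Hz isolates the slow envelope fluctuations that carry long-range
#' coupling.
#'
#' @param env an `envelope_set` from [envelope()], or a regions x samples
#'   matrix (then `fs` must be given).
#' @param cutoff cutoff frequency in Hz (default 1).
#' @param fs sampling rate, only needed when `env` is a bare matrix.
#' @param order Butterworth order (default 4).
#' @return Same type as `env`, low-pass filtered.
#' @export
lowpass_envelope <- function(env, cutoff = 1, fs = NULL, order = 4) {
  if (inherits(env, "envelope_set")) {
    env$values <- lowpass_envelope(env$values, cutoff, env$fs, order)
    return(env)
  }
  env <- as_ts_matrix(env)
  check_scalar(fs %||% stop_envdyn("`fs` required for matrix input"), "fs")
  if (cutoff >= fs / 2)
    stop_envdyn("cutoff %g Hz exceeds the Nyquist frequency %g Hz", cutoff, fs / 2)
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zero_phase_filter(env, flt)
}

#' Moving-window average downsampling of envelopes
#'
#' Averages the envelope over sliding windows (default 100 ms wide, sliding
#' every 25 ms, i.e. 75% overlap), emitting only windows fully contained in
#' the signal. With the defaults the output rate is 40 Hz regardless of the
#' input rate.
#'
#' @param env an `envelope_set` or regions x samples matrix (then `fs`
#'   required).
#' @param width_s window width in seconds (default 0.100).
#' @param step_s window step in seconds (default 0.025).
#' @param fs input sampling rate for matrix input.
#' @return Same type as `env` at sampling rate `1/step_s`. The output length
#'   is `floor((N - width) / step) + 1` windows.
#' @examples
#' env <- matrix(rep(2, 1000), 1)
#' window_average_downsample(env, fs = 1000)[1, 1:5]
#' @export
window_average_downsample <- function(env, width_s = 0.100, step_s = 0.025,
                                      fs = NULL) {
  if (inherits(env, "envelope_set")) {
    out <- env
    out$values <- window_average_downsample(env$values, width_s, step_s, env$fs)
    out$fs <- 1 / step_s
    out$edge_s <- 0  # assumed already trimmed upstream
    return(out)
  }
  env <- as_ts_matrix(env)
  if (is.null(fs)) stop_envdyn("`fs` required for matrix input")
  if (width_s < step_s) stop_envdyn("width_s must be >= step_s")
  n <- ncol(env)
  width_n <- max(1L, round(width_s * fs))
  if (n < width_n)
    stop_envdyn("signal (%d samples) shorter than one window (%d samples)",
                n, width_n)
  step_n <- step_s * fs  # may be non-integer; starts are floored per window
  n_out <- floor((n - width_n) / step_n) + 1
  starts <- floor((seq_len(n_out) - 1) * step_n)
  cs <- cbind(0, t(apply(env, 1, cumsum)))
  out <- (cs[, starts + width_n + 1, drop = FALSE] -
            cs[, starts + 1, drop = FALSE]) / width_n
  rownames(out) <- rownames(env)
  out
}

#' @rdname envelope
#' @param x an `envelope_set`.
#' @export
keep_idx <- function(x) {
  stopifnot(inherits(x, "envelope_set"))
  edge_keep_idx(ncol(x$values), x$fs, x$edge_s)
}

envelope_set <- function(values, fs, band = NULL, subject = NULL, edge_s = 0) {
  if (any(values < 0)) stop_envdyn("envelope values must be non-negative")
  structure(list(values = values, fs = fs, band = band, subject = subject,
                 edge_s = edge_s),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("<envelope_set> %d regions x %d samples at %g Hz%s%s\n",
              nrow(x$values), ncol(x$values), x$fs,
              if (!is.null(x$band)) paste0(", band ", as_band(x$band)$name) else "",
              if (x$edge_s > 0) sprintf(", %g s edges flagged", x$edge_s) else ""))
  invisible(x)
}

edge_keep_idx <- function(n, fs, edge_s) {
  k <- round(edge_s * fs)
  if (2 * k >= n) stop_envdyn("edge margin leaves no samples")
  (k + 1L):(n - k)
}

as_ts_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  check_matrix(x, "ts")
  x
}

zero_phase_filter <- function(x, flt) {
  b <- as.numeric(flt$b); a <- as.numeric(flt$a)
  m <- max(length(a), length(b))
  b <- c(b, numeric(m - length(b)))
  a <- c(a, numeric(m - length(a)))
  b <- b / a[1]; a <- a / a[1]
  out <- filtfilt_mat(b, a, x)
  dimnames(out) <- dimnames(x)
  out
}
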