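# Shared signal-processing primitives: colored-noise synthesis, zero-phase FIR
# filtering, polyphase resampling and the Welch power spectral density used to
# build the channel x frequency feature grid.

#' Synthesize 1/f^a ("pink-ish") noise
#'
#' Frequency-domain shaping of Gaussian white noise. The returned series has
#' unit standard deviation; multiply by the desired amplitude.
#'
#' @param n number of samples.
#' @param exponent spectral exponent a of the 1/f^a power shape (a = 0 is
#'   white, a = 1 pink). Power at frequency f is proportional to f^-a.
#' @param seed optional integer seed applied locally.
#' @return numeric vector of length `n` with sd 1.
#' @export
pinkNoise <- function(n, exponent = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- stats::nextn(n, 2)
  w <- stats::rnorm(m)
  amp <- spectralShape(m, exponent)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# memo cache for FFT-domain shaping vectors and filter responses
.dsp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .dsp_cache)) {
    assign(key, expr, envir = .dsp_cache)
  }
  get(key, envir = .dsp_cache)
}

# amplitude shaping vector for an m-point FFT (two-sided, DC zeroed)
spectralShape <- function(m, exponent) {
  cached(sprintf("shape_%d_%g", m, exponent), {
    f <- c(0, seq_len(m - 1))
    f <- pmin(f, m - f) # two-sided frequency index
    c(0, f[-1]^(-exponent / 2))
  })
}

# two-sided band mask on the m-point FFT grid
bandMask <- function(m, fs, band) {
  cached(sprintf("mask_%d_%g_%g_%g", m, fs, band[1], band[2]), {
    fr <- (seq_len(m) - 1) / m * fs
    fr <- pmin(fr, fs - fr)
    as.numeric(fr >= band[1] & fr <= band[2])
  })
}

#' Fraction of 1/f^a noise variance inside a frequency band
#'
#' Used to calibrate injected band-limited power boosts exactly: the shaping
#' used by [pinkNoise()] is known analytically on the FFT grid.
#'
#' @param n series length the noise is generated at.
#' @param fs sampling rate (samples/s).
#' @param band numeric length-2, band edges in Hz.
#' @param exponent spectral exponent (see [pinkNoise()]).
#' @return scalar in (0, 1).
#' @export
bandVarianceFraction <- function(n, fs, band, exponent = 1) {
  m <- stats::nextn(n, 2)
  amp <- spectralShape(m, exponent)
  fr <- (seq_len(m) - 1) / m * fs
  fr <- pmin(fr, fs - fr)
  p <- amp^2
  sum(p[fr >= band[1] & fr <= band[2]]) / sum(p)
}

#' Band-limited Gaussian noise
#'
#' White noise restricted to `band` by FFT masking; unit standard deviation.
#'
#' @inheritParams bandVarianceFraction
#' @return numeric vector of length `n`, sd 1.
#' @export
bandNoise <- function(n, fs, band) {
  m <- stats::nextn(n, 2)
  w <- stats::rnorm(m)
  mask <- bandMask(m, fs, band)
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Design a Hamming windowed-sinc FIR filter
#'
#' @param fs sampling rate.
#' @param low,high band edges in Hz; use `low = NULL` for low-pass and
#'   `high = NULL` for high-pass.
#' @param order filter order (even; taps = order + 1). Default scales with the
#'   narrower transition edge (~3.3 / normalized transition width).
#' @param type passed to [signal::fir1()]; "stop" gives a band-stop (notch).
#' @return numeric coefficient vector (odd length, symmetric).
#' @export
designFIR <- function(fs, low = NULL, high = NULL, order = NULL, type = "pass") {
  nyq <- fs / 2
  w <- c(low, high) / nyq
  if (is.null(order)) {
    edge <- min(c(low, high))
    tb <- max(edge / 2, 0.5) # transition bandwidth heuristic, Hz
    order <- ceiling(3.3 * fs / tb / 2) * 2
  }
  if (length(w) == 1L) {
    ftype <- if (!is.null(low) && is.null(high)) "high" else "low"
    signal::fir1(order, w, type = ftype, window = signal::hamming(order + 1))
  } else {
    signal::fir1(order, w, type = type, window = signal::hamming(order + 1))
  }
}

#' Apply a linear-phase FIR filter with zero net phase shift
#'
#' Single-pass FFT convolution with a symmetric FIR kernel; the constant group
#' delay (L-1)/2 is compensated exactly, so the net phase shift is zero.
#'
#' @param x numeric vector, or matrix with one signal per row.
#' @param h symmetric FIR coefficients of odd length.
#' @return filtered signal, same shape as `x`.
#' @export
filterZeroPhase <- function(x, h) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  L <- length(h)
  stopifnot(L %% 2L == 1L)
  m <- stats::nextn(n + L - 1L, 2)
  H <- stats::fft(c(h, numeric(m - L)))
  d <- (L - 1L) / 2L
  pad <- numeric(m - n)
  out <- x
  for (r in seq_len(nrow(x))) {
    X <- stats::fft(c(x[r, ], pad))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / m
    out[r, ] <- y[d + seq_len(n)]
  }
  if (vec) out[1L, ] else out
}

#' Welch power spectral density
#'
#' Hamming-windowed, overlapping periodogram average. One-sided density in
#' units^2/Hz on the FFT grid `seq(0, fs/2, by = fs/nfft)`.
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate.
#' @param nfft FFT/window length (default 1024).
#' @param noverlap samples of overlap between windows (default `nfft/2`).
#' @return list with `freq` (Hz) and `psd` (units^2/Hz), length `nfft/2 + 1`.
#' @export
welchPSD <- function(x, fs, nfft = 1024L, noverlap = nfft %/% 2L) {
  n <- length(x)
  if (n < nfft) stop("epoch shorter than one FFT window (", n, " < ", nfft, ")")
  step <- nfft - noverlap
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- signal::hamming(nfft)
  u <- sum(w^2)
  seg <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w, numeric(nfft))
  P <- abs(mvfft(seg))^2
  psd <- rowMeans(P)[seq_len(nfft / 2 + 1)] / (fs * u)
  psd[2:(nfft / 2)] <- 2 * psd[2:(nfft / 2)] # fold negative frequencies
  list(freq = (0:(nfft / 2)) * fs / nfft, psd = psd)
}

# run-length helper: durations of runs computed from timestamps (seconds).
# Returns data.frame(start_idx, end_idx, value, start_s, end_s).
runsFromFlags <- function(flags, times, fps) {
  r <- rle(as.logical(flags))
  end_idx <- cumsum(r$lengths)
  start_idx <- c(1L, head(end_idx, -1L) + 1L)
  # half-open [start, end): end of a run is the start of the next frame
  bound <- c(times, times[length(times)] + 1 / fps)
  data.frame(
    start_idx = start_idx, end_idx = end_idx, value = r$values,
    start_s = bound[start_idx], end_s = bound[end_idx + 1L]
  )
}
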