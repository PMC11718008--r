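#' Zero-phase band-pass filter
#'
#' FFT-domain filter with raised-cosine transition skirts, exactly zero-phase
#' (a real, even frequency response applied to the full spectrum). The
#' passband is flat (ripple-free); each transition band spans half an octave
#' below the lower edge and half an octave above the upper edge by default,
#' reaching full stop (> 100 dB numerically) one octave outside the band —
#' comfortably past the 40 dB contract. Offline processing at a 20 Hz frame
#' rate makes an FFT filter both exact and robust where very-low normalized
#' cutoffs would push IIR poles against the unit circle.
#'
#' @param trace Numeric series.
#' @param low,high Band edges, Hz (0 < low < high < prf/2).
#' @param prf Sampling rate, Hz.
#' @param transition Fractional transition width: each skirt spans
#'   `transition * edge` Hz (default 0.5, i.e. gain reaches zero at
#'   `low/2` and `1.5 * high`, clipped to Nyquist).
#' @return Filtered numeric series of the same length.
#' @export
bandpass <- function(trace, low, high, prf, transition = 0.5) {
  if (!(low > 0 && high > low && high < prf / 2)) {
    stop("invalid band: need 0 < low < high < prf/2", call. = FALSE)
  }
  n <- length(trace)
  # reflection padding: the FFT filter is circular, and any net drift
  # between the first and last samples would act as a step discontinuity
  # ringing into the passband; the even extension is continuous by
  # construction, and the edge effects stay at the (discarded) mirror joint
  x <- c(trace, rev(trace))
  m <- length(x)
  f <- seq(0, prf, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, prf - f)                       # folded (two-sided) frequency
  h <- cosine_gate(f, low, high, low * transition,
                   min(high * transition, prf / 2 - high))
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE))[seq_len(n)] / m
}

# flat between [low, high], raised-cosine skirts of widths wl / wh
cosine_gate <- function(f, low, high, wl, wh) {
  h <- numeric(length(f))
  h[f >= low & f <= high] <- 1
  lo <- f < low & f > low - wl
  h[lo] <- 0.5 * (1 - cos(pi * (f[lo] - (low - wl)) / wl))
  hi <- f > high & f < high + wh
  h[hi] <- 0.5 * (1 + cos(pi * (f[hi] - high) / wh))
  h
}

#' Cardiac-band filter
#'
#' Band-pass 0.8-6 Hz. The lower skirt is placed so that a 0.9 Hz tone (a
#' 54 beats/min fundamental) loses well under 3 dB: raising the lower edge
#' to 1 Hz is the classic failure mode in which the true fundamental is
#' suppressed and the second harmonic is reported as double the heart rate.
#'
#' @param trace Numeric series (movement-compensated displacement, mm).
#' @param prf Sampling rate, Hz.
#' @param band Band edges, Hz; `c(0.8, 3)` is the breath-hold preset.
#' @return Filtered series.
#' @export
bandpass_cardiac <- function(trace, prf, band = c(0.8, 6)) {
  bandpass(trace, band[1], band[2], prf)
}

#' Welch averaged periodogram
#'
#' Hann-windowed, 50%-overlap averaged periodogram with zero-padding for a
#' fine frequency grid. Small internal estimator (no installed package
#' provides one at this sampling regime).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param seg_len Segment length in samples (default: min(length, 60 s)).
#' @param pad Zero-padding factor for the FFT grid.
#' @return A tibble `freq_hz`, `power`.
#' @keywords internal
welch_psd <- function(x, fs, seg_len = NULL, pad = 8L) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, round(60 * fs))
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  nfft <- 2^ceiling(log2(seg_len * pad))
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - seg_len))))^2
  }
  keep <- seq_len(nfft %/% 2)
  tibble::tibble(freq_hz = (keep - 1) * fs / nfft,
                 power = acc[keep] / length(starts))
}
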