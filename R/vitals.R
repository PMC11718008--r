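#' Detect cardiac-waveform valleys
#'
#' The valley is the robust fiducial of the seat-back cardiac waveform (it
#' aligns with the ECG T-wave), so beats are timed at local minima. Minima
#' must be separated by at least `min_separation` (0.3 s, i.e. at most 200
#' beats/min) and have prominence at least `prominence_frac` of the median
#' candidate prominence. Valley times are refined to sub-sample precision by
#' parabolic interpolation, which matters at a 20 Hz frame rate where one
#' sample is 50 ms.
#'
#' @param waveform A `cardiac_waveform`, or a numeric trace (then `fs` must
#'   be given).
#' @param fs Sampling rate, Hz (taken from the waveform if absent).
#' @param min_separation Minimum valley spacing, s.
#' @param prominence_frac Minimum prominence as a fraction of the median
#'   cycle peak-to-valley amplitude (estimated as the median max-minus-min
#'   over windows of one fundamental period), which rejects the shallow
#'   inter-peak dip of the two-peak cycle shape.
#' @param upsample Band-limited (FFT) interpolation factor applied before
#'   detection. The cardiac waveform lives below 6 Hz, well under the 10 Hz
#'   Nyquist limit, so sinc interpolation is exact and removes the timing
#'   bias of locating a sharp valley on a 50 ms grid.
#' @return Numeric vector of valley times (s). Fewer than 3 detected valleys
#'   raises a warning and sets the attribute `insufficient = TRUE`.
#' @export
detect_valleys <- function(waveform, fs = NULL, min_separation = 0.3,
                           prominence_frac = 0.3, upsample = 4L) {
  fundamental <- NA_real_
  if (inherits(waveform, "cardiac_waveform")) {
    x <- waveform$trace
    fs <- waveform$fs
    fundamental <- waveform$fundamental
  } else {
    x <- as.numeric(waveform)
    if (is.null(fs)) stop("fs required for a bare numeric trace", call. = FALSE)
  }
  stopifnot(length(x) >= 3)
  if (upsample > 1) {
    x <- fft_interp(x, upsample)
    fs <- fs * upsample
  }
  peaks <- find_extrema(-x)               # valleys of x are peaks of -x
  if (nrow(peaks) == 0) return(insufficient_valleys())

  # median cycle peak-to-valley amplitude, over windows of one period
  if (is.na(fundamental)) {
    psd <- welch_psd(x, fs, seg_len = min(length(x), round(30 * fs)))
    sel <- psd$freq_hz >= 0.5 & psd$freq_hz <= 0.45 * fs
    fundamental <- psd$freq_hz[sel][which.max(psd$power[sel])]
  }
  period <- max(2L, round(fs / fundamental))
  n_win <- floor(length(x) / period)
  spans <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * period + 1):(w * period)]
    max(seg) - min(seg)
  }, numeric(1))
  cycle_amp <- stats::median(spans)

  # enforce separation greedily, most prominent first
  peaks <- peaks[order(-peaks$prominence), ]
  keep <- logical(0)
  kept_idx <- integer(0)
  min_gap <- min_separation * fs
  for (i in seq_len(nrow(peaks))) {
    if (all(abs(peaks$index[i] - kept_idx) >= min_gap)) {
      kept_idx <- c(kept_idx, peaks$index[i])
      keep <- c(keep, TRUE)
    } else keep <- c(keep, FALSE)
  }
  peaks <- peaks[keep, ]
  peaks <- peaks[peaks$prominence >= prominence_frac * cycle_amp, ]
  peaks <- peaks[order(peaks$index), ]
  if (nrow(peaks) < 3) return(insufficient_valleys())

  refine_valley_times(x, fs, peaks$index)
}

# exact interpolation of a band-limited series: zero-padded spectrum
fft_interp <- function(x, L) {
  n <- length(x)
  X <- stats::fft(x)
  h <- floor(n / 2)
  X2 <- complex(n * L)
  X2[seq_len(h + 1)] <- X[seq_len(h + 1)]
  if (n %% 2 == 0) {                      # split the Nyquist bin
    X2[h + 1] <- X[h + 1] / 2
    X2[n * L - h + 1] <- X[h + 1] / 2
    if (h > 1) X2[(n * L - h + 2):(n * L)] <- X[(h + 2):n]
  } else {
    X2[(n * L - h + 1):(n * L)] <- X[(h + 2):n]
  }
  Re(stats::fft(X2, inverse = TRUE)) * L / (n * L)
}

# sub-sample valley timing. With enough beats, each valley is aligned to the
# ensemble-average cycle shape by local least-squares matching over integer
# lags plus parabolic interpolation (uses the full cycle, not 3 samples);
# isolated valleys fall back to a parabola through the minimum.
refine_valley_times <- function(x, fs, idx, max_lag = 2L) {
  parab <- function(i) {
    if (i <= 1 || i >= length(x)) return((i - 1) / fs)
    num <- x[i - 1] - x[i + 1]
    den <- x[i - 1] - 2 * x[i] + x[i + 1]
    delta <- if (abs(den) > .Machine$double.eps) 0.5 * num / den else 0
    (i - 1 + max(-0.5, min(0.5, delta))) / fs
  }
  if (length(idx) < 8) return(vapply(idx, parab, numeric(1)))

  hw <- max(3L, round(0.4 * stats::median(diff(idx))))
  ok <- idx - hw - max_lag >= 1 & idx + hw + max_lag <= length(x)
  if (sum(ok) < 5) return(vapply(idx, parab, numeric(1)))
  template <- rowMeans(vapply(idx[ok], function(i) x[(i - hw):(i + hw)],
                              numeric(2 * hw + 1)))
  vapply(seq_along(idx), function(j) {
    i <- idx[j]
    if (!ok[j]) return(parab(i))
    lags <- -max_lag:max_lag
    sse <- vapply(lags, function(l) {
      sum((x[(i + l - hw):(i + l + hw)] - template)^2)
    }, numeric(1))
    b <- which.min(sse)
    delta <- 0
    if (b > 1 && b < length(lags)) {
      den <- sse[b - 1] - 2 * sse[b] + sse[b + 1]
      if (abs(den) > .Machine$double.eps) {
        delta <- max(-0.5, min(0.5, 0.5 * (sse[b - 1] - sse[b + 1]) / den))
      }
    }
    (i - 1 + lags[b] + delta) / fs
  }, numeric(1))
}

insufficient_valleys <- function() {
  warning("fewer than 3 valleys detected: insufficient beats", call. = FALSE)
  structure(numeric(), insufficient = TRUE)
}

# strict local maxima with scipy-style prominences
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), prominence = numeric()))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    base_l <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1, i - 1)])
    right <- x[seq.int(i + 1, n)]
    higher_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(higher_r)) min(higher_r) else n - i)])
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Heart-rate variability from valley times
#'
#' Interbeat intervals are successive valley-time differences. RMSSD is the
#' root mean square of successive IBI differences; SDRR the population
#' standard deviation of the IBIs; pNN50 the percentage of successive IBI
#' differences whose magnitude exceeds 50 ms.
#'
#' @param valley_times Valley times in s (>= 4 beats).
#' @param valid Optional logical vector (one per valley): beats marked
#'   `FALSE` (e.g. interpolated replacements for missed detections) bound
#'   intervals that are not normal-to-normal; those intervals are excluded
#'   from SDRR and their successive differences from RMSSD/pNN50, the
#'   standard NN-interval convention. HR and the reported `ibi_series` use
#'   the full series.
#' @return A list: `ibi_series` (ms), `hr` (beats/min, `60000 / mean(ibi)`),
#'   `rmssd` (ms), `sdrr` (ms), `pnn50` (%).
#' @examples
#' compute_hrv(cumsum(c(0, 0.800, 0.860, 0.865, 0.920)))
#' @export
compute_hrv <- function(valley_times, valid = NULL) {
  if (length(valley_times) < 4) {
    stop("need at least 4 valleys for HRV metrics", call. = FALSE)
  }
  ibi <- diff(valley_times) * 1000
  if (is.null(valid)) valid <- rep(TRUE, length(valley_times))
  stopifnot(length(valid) == length(valley_times))
  nn <- valid[-length(valid)] & valid[-1]          # interval endpoints genuine
  dn <- nn[-length(nn)] & nn[-1]                   # both intervals genuine
  d <- diff(ibi)
  if (!any(nn) || !any(dn)) {
    nn <- rep(TRUE, length(ibi))
    dn <- rep(TRUE, length(d))
  }
  list(
    ibi_series = ibi,
    hr = 60000 / mean(ibi),
    rmssd = sqrt(mean(d[dn]^2)),
    sdrr = sqrt(mean((ibi[nn] - mean(ibi[nn]))^2)),   # population SD
    pnn50 = 100 * mean(abs(d[dn]) > 50)
  )
}

#' Classify cardiac-waveform morphology
#'
#' Healthy seated subjects show two peaks then a valley per cardiac cycle;
#' a three-peaks-then-valley cycle is the atypical pattern associated with a
#' prolonged QTc. Cycles are delimited valley-to-valley and peaks are
#' counted above a relative prominence floor.
#'
#' Two estimators are provided. `"ensemble"` (default) time-normalizes
#' every cycle, averages them into one mean cycle, and counts its peaks:
#' beat-incoherent noise shrinks with the number of beats while the
#' physiological peaks persist, which matters when the per-beat
#' displacement (~0.02 mm) is close to the noise floor. `"per_cycle"`
#' counts peaks cycle by cycle and requires a `majority` of cycles to
#' agree — preferable when cycle shape may genuinely alternate within a
#' recording (an ensemble average would blend the shapes instead of
#' reporting the mixture as indeterminate).
#'
#' @param waveform A `cardiac_waveform` or numeric trace (typically the
#'   band-passed 0.8-6 Hz displacement: the two/three-peak pattern is a
#'   property of the filtered waveform).
#' @param valley_times Valley times, s (needs >= 5 complete cycles).
#' @param fs Sampling rate if `waveform` is bare numeric.
#' @param prominence_frac Relative prominence floor for counting a peak,
#'   as a fraction of the cycle's peak-to-valley span. The default 0.06 is
#'   calibrated on band-limited template trains: the weakest genuine
#'   secondary peak retains ~0.10 of the span while ensemble-averaged noise
#'   ripples stay under ~0.02.
#' @param majority Cycle fraction required for a definite label
#'   (`"per_cycle"` method).
#' @param upsample Band-limited interpolation factor (a 20 Hz frame rate
#'   gives under 20 samples per cycle, too coarse for counting extrema).
#' @param method `"ensemble"` or `"per_cycle"`.
#' @return `"typical_two_peak"`, `"atypical_multi_peak"`, or
#'   `"indeterminate"`.
#' @export
classify_morphology <- function(waveform, valley_times, fs = NULL,
                                prominence_frac = 0.06, majority = 0.7,
                                upsample = 4L,
                                method = c("ensemble", "per_cycle")) {
  method <- match.arg(method)
  if (inherits(waveform, "cardiac_waveform")) {
    x <- waveform$trace
    fs <- waveform$fs
  } else {
    x <- as.numeric(waveform)
    if (is.null(fs)) stop("fs required for a bare numeric trace", call. = FALSE)
  }
  if (upsample > 1) {
    x <- fft_interp(x, upsample)
    fs <- fs * upsample
  }
  if (length(valley_times) < 6) return("indeterminate")   # < 5 cycles

  cycle_peak_count <- function(seg) {
    peaks <- find_extrema(seg)
    sum(peaks$prominence >= prominence_frac * (max(seg) - min(seg)))
  }

  if (method == "ensemble") {
    grid <- seq(0, 1, length.out = 100L)
    segs <- vapply(seq_len(length(valley_times) - 1), function(i) {
      a <- round(valley_times[i] * fs) + 1L
      b <- round(valley_times[i + 1] * fs) + 1L
      if (a < 1 || b > length(x) || b - a < 8) return(rep(NA_real_, 100L))
      stats::approx(seq(0, 1, length.out = b - a + 1), x[a:b], grid)$y
    }, numeric(100L))
    ok <- colSums(is.na(segs)) == 0
    if (sum(ok) < 5) return("indeterminate")
    n <- cycle_peak_count(rowMeans(segs[, ok, drop = FALSE]))
    if (n == 2) return("typical_two_peak")
    if (n >= 3) return("atypical_multi_peak")
    return("indeterminate")
  }

  counts <- vapply(seq_len(length(valley_times) - 1), function(i) {
    a <- max(1L, round(valley_times[i] * fs) + 1L)
    b <- min(length(x), round(valley_times[i + 1] * fs) + 1L)
    if (b - a < 4) return(NA_integer_)
    cycle_peak_count(x[a:b])
  }, integer(1))
  counts <- counts[!is.na(counts)]
  if (length(counts) < 5) return("indeterminate")
  if (mean(counts == 2) >= majority) return("typical_two_peak")
  if (mean(counts >= 3) >= majority) return("atypical_multi_peak")
  "indeterminate"
}

#' Refine beat times against a wide-band waveform
#'
#' The harmonic reconstruction is narrowband by construction: it locates
#' beats robustly but low-pass filters the beat-to-beat timing jitter that
#' RMSSD and pNN50 measure. Each coarse valley is therefore re-timed on the
#' full-band (0.8-6 Hz) waveform — the domain in which the valley is the
#' physiological fiducial — by least-squares alignment of the local segment
#' against the ensemble-average cycle, within a small search window around
#' the coarse time.
#'
#' @param valley_times Coarse valley times, s.
#' @param trace Wide-band cardiac displacement (band-passed, mm).
#' @param fs Sampling rate of `trace`, Hz.
#' @param search Half-width of the per-beat search window, s.
#' @param upsample Band-limited interpolation factor.
#' @return Refined valley times, s.
#' @export
refine_beats_wideband <- function(valley_times, trace, fs, search = 0.15,
                                  upsample = 4L) {
  if (length(valley_times) < 8) return(valley_times)
  if (upsample > 1) {
    trace <- fft_interp(trace, upsample)
    fs <- fs * upsample
  }
  idx <- round(valley_times * fs) + 1L
  hw <- max(3L, round(0.4 * stats::median(diff(idx))))
  max_lag <- max(1L, round(search * fs))
  ok <- idx - hw - max_lag >= 1 & idx + hw + max_lag <= length(trace)
  if (sum(ok) < 5) return(valley_times)
  template <- rowMeans(vapply(idx[ok], function(i) trace[(i - hw):(i + hw)],
                              numeric(2 * hw + 1)))
  vapply(seq_along(idx), function(j) {
    if (!ok[j]) return(valley_times[j])
    i <- idx[j]
    lags <- -max_lag:max_lag
    sse <- vapply(lags, function(l) {
      sum((trace[(i + l - hw):(i + l + hw)] - template)^2)
    }, numeric(1))
    b <- which.min(sse)
    delta <- 0
    if (b > 1 && b < length(lags)) {
      den <- sse[b - 1] - 2 * sse[b] + sse[b + 1]
      if (abs(den) > .Machine$double.eps) {
        delta <- max(-0.5, min(0.5, 0.5 * (sse[b - 1] - sse[b + 1]) / den))
      }
    }
    (i - 1 + lags[b] + delta) / fs
  }, numeric(1))
}

#' Fuse per-bin beat estimates
#'
#' The torso occupies several range bins; fusing them suppresses bin-local
#' noise and corruption. Per-bin heart rates first pass one-sigma outlier
#' rejection; the surviving bin closest to the survivors' mean HR anchors the
#' beat list, and each of its valleys is replaced by the median of the
#' matching valleys (within `match_window`) across all surviving bins.
#'
#' @param per_bin_valleys List of valley-time vectors (s), one per bin.
#' @param per_bin_hr Numeric vector of per-bin HR estimates (beats/min);
#'   `NA` for bins whose reconstruction was refused.
#' @param sigma_multiplier Outlier band width, SDs.
#' @param match_window Cross-bin valley matching half-window, s.
#' @param vote_frac Fraction of surviving bins that must report a beat for
#'   it to be kept. Genuine beats appear in (nearly) every bin — the torso
#'   bins share the same physiology — while noise-driven spurious valleys
#'   are bin-local, so a strict majority removes them.
#' @return A list: `valley_times` (fused, s), `surviving_bins` (indices into
#'   the input list), `reference_bin` (surviving bin closest to the mean
#'   HR), `all_rejected` (logical flag).
#' @export
fuse_bins <- function(per_bin_valleys, per_bin_hr, sigma_multiplier = 1,
                      match_window = 0.25, vote_frac = 0.5) {
  stopifnot(length(per_bin_valleys) == length(per_bin_hr))
  usable <- which(!is.na(per_bin_hr))
  if (length(usable) == 0) {
    return(list(valley_times = numeric(), surviving_bins = integer(),
                reference_bin = NA_integer_, all_rejected = TRUE))
  }
  keep_rel <- if (length(usable) >= 3) {
    reject_outlier_bins(per_bin_hr[usable], sigma_multiplier)
  } else seq_along(usable)
  keep <- usable[keep_rel]
  all_rejected <- length(keep) == 0
  if (all_rejected) {
    keep <- usable[which.min(abs(per_bin_hr[usable] - mean(per_bin_hr[usable])))]
  }
  ref <- keep[which.min(abs(per_bin_hr[keep] - stats::median(per_bin_hr[keep])))]

  # anchor on the reference bin's beat list: each of its valleys gathers the
  # nearest valley within the window from every surviving bin; a beat is
  # kept only with majority support and timed by the cross-bin median
  fused <- vapply(per_bin_valleys[[ref]], function(v) {
    matches <- vapply(keep, function(b) {
      vb <- per_bin_valleys[[b]]
      if (length(vb) == 0) return(NA_real_)
      nearest <- vb[which.min(abs(vb - v))]
      if (abs(nearest - v) <= match_window) nearest else NA_real_
    }, numeric(1))
    if (sum(!is.na(matches)) > vote_frac * length(keep)) {
      stats::median(matches, na.rm = TRUE)
    } else NA_real_
  }, numeric(1))
  list(valley_times = sort(fused[!is.na(fused)]), surviving_bins = keep,
       reference_bin = ref, all_rejected = all_rejected)
}

#' Correct beat-detection artifacts in a valley series
#'
#' Standard interbeat-series cleanup applied before HRV computation: a
#' spurious extra beat splits one interval into two short ones (each well
#' below the median, summing to about one median interval) — the shared
#' valley is removed; a missed beat leaves an interval of about twice the
#' median — evenly spaced beats are interpolated into it. Both rules are
#' conservative (relative to the running median IBI) and iterate to a fixed
#' point.
#'
#' @param valley_times Valley times, s.
#' @param k_mad Deviation scale: an interval counts as an outlier beyond
#'   `median ± max(k_mad * MAD, min_frac * median)`, so the rule adapts to
#'   the subject's own beat-to-beat variability.
#' @param min_frac Floor of the outlier band as a fraction of the median
#'   (guards the MAD collapsing on near-constant series).
#' @return Corrected valley times, s, with attribute `"inserted"`: the times
#'   of interpolated beats. Intervals bounded by an interpolated beat are
#'   not normal ("NN") intervals and are excluded from difference-based HRV
#'   metrics downstream.
#' @export
correct_ibi_artifacts <- function(valley_times, k_mad = 4, min_frac = 0.25) {
  v <- sort(valley_times)
  inserted <- numeric()
  budget <- 3L * length(v) + 10L
  repeat {
    budget <- budget - 1L
    if (length(v) < 4 || budget <= 0) break
    ibi <- diff(v)
    med <- stats::median(ibi)
    dev <- max(k_mad * stats::mad(ibi), min_frac * med)
    # two detections of the same beat: physiologically impossible spacing
    dup <- which(ibi < 0.3)
    if (length(dup)) {
      i <- dup[1]
      v[i] <- (v[i] + v[i + 1]) / 2
      v <- v[-(i + 1)]
      next
    }
    # remove the valley shared by two short intervals with a plausible sum
    short <- which(ibi[-length(ibi)] < med - dev &
                     ibi[-1] < med - dev &
                     abs(ibi[-length(ibi)] + ibi[-1] - med) < dev)
    if (length(short)) {
      v <- v[-(short[1] + 1)]
      next
    }
    long <- which(ibi > med + dev)
    if (length(long)) {
      i <- long[1]
      n_add <- max(1L, round(ibi[i] / med) - 1L)
      add <- v[i] + seq_len(n_add) * ibi[i] / (n_add + 1)
      inserted <- c(inserted, add)
      v <- sort(c(v, add))
      next
    }
    # mistimed beat: adjacent short/long intervals whose sum is plausible
    # but whose difference is physiologically impossible — re-centre the
    # shared valley (successive differences this large do not occur in
    # genuine sinus rhythm; they are detection offsets)
    d <- diff(ibi)
    mist <- which(abs(d) > 0.2 &
                    abs(ibi[-length(ibi)] + ibi[-1] - 2 * med) < 0.3 * med)
    if (length(mist)) {
      i <- mist[1]
      v[i + 1] <- (v[i] + v[i + 2]) / 2
      next
    }
    break
  }
  structure(v, inserted = inserted[inserted %in% v])
}
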