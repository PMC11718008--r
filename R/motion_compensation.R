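#' Movement-compensation settings
#'
#' Body movements (posture shifts, torso rocks) dwarf breathing and cardiac
#' displacement and cannot be removed by filtering: a narrow pulse smears
#' sinc-like energy across the whole band and a DC step corrupts every
#' frequency. They are instead removed in the time domain by zeroing
#' super-threshold steps of the first-differenced trace. The shipped
#' 0.48 mm/sample threshold is the empirical-rule (mean + 3 SD) bound on
#' clean-breathing step sizes at a 20 Hz frame rate; it can be recalibrated
#' on synthetic cohorts with [calibrate_threshold()].
#'
#' @param derivative_threshold Spike threshold in mm per slow-time sample.
#' @param sigma_multiplier Cross-bin outlier band half-width in standard
#'   deviations (the one-sigma rule by default).
#' @param fill How masked steps are replaced: `"interp"` (default)
#'   linearly interpolates the derivative across each masked run from its
#'   clean neighbours, preserving the slow breathing drift underneath the
#'   event; `"zero"` sets them to zero (the plain set-to-zero-then-cumsum
#'   rule — equivalent on isolated spikes, but with dilation it also deletes
#'   the breathing change during the event, leaving a baseline break).
#' @param hysteresis Lower threshold (mm/sample) of the double-threshold
#'   spike detector: a spike run found above `derivative_threshold` is
#'   extended outwards while steps still exceed `hysteresis`. A body
#'   movement is temporally contiguous — its central steps exceed the main
#'   threshold while the ramp-in/ramp-out steps do not, and left in place
#'   they survive as broadband residue in the cardiac band. The default
#'   0.25 mm sits above the steepest per-frame step quiet breathing
#'   produces (~0.15 mm at the band edge).
#' @param spike_dilation Extra samples of margin added to each side of an
#'   extended spike run. Setting this and `hysteresis` to zero restores
#'   pure single-threshold masking.
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(derivative_threshold = 0.48, sigma_multiplier = 1,
                          fill = c("interp", "zero"), hysteresis = 0.25,
                          spike_dilation = 5L) {
  fill <- match.arg(fill)
  stopifnot(derivative_threshold > 0, sigma_multiplier > 0,
            hysteresis >= 0, hysteresis <= derivative_threshold,
            spike_dilation >= 0)
  structure(list(derivative_threshold = derivative_threshold,
                 sigma_multiplier = sigma_multiplier, fill = fill,
                 hysteresis = hysteresis,
                 spike_dilation = as.integer(spike_dilation)),
            class = "motion_config")
}

#' Time-domain body-movement compensation
#'
#' First-differences the trace, zeroes every step whose magnitude exceeds the
#' threshold, and rebuilds the trace by cumulative summation from the
#' original first value. Edges are treated like interior samples. Zeroing
#' (rather than interpolating) the spike steps is what makes the operation
#' idempotent: the rebuilt trace contains no new super-threshold steps.
#'
#' @param trace Numeric displacement series, mm (length >= 2).
#' @param config A [motion_config()].
#' @return A list: `trace` (compensated series, mm), `spike_mask` (logical,
#'   per-sample; element i marks the step into sample i; first element FALSE).
#' @examples
#' compensate_movement(c(0, 0, 2, 2, 2))$trace # step removed -> all zeros
#' @export
compensate_movement <- function(trace, config = motion_config()) {
  stopifnot(length(trace) >= 2)
  d <- diff(trace)
  spike <- abs(d) > config$derivative_threshold
  if (!any(spike)) {              # clean trace: exact pass-through
    return(list(trace = trace, spike_mask = c(FALSE, spike)))
  }
  if (any(spike)) {
    if (config$hysteresis > 0) {
      above <- abs(d) > config$hysteresis
      # extend each spike run while steps stay above the lower threshold
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        if (any(spike[starts[r]:ends[r]])) spike[starts[r]:ends[r]] <- TRUE
      }
    }
    if (config$spike_dilation > 0) {
      w <- config$spike_dilation
      idx <- which(spike)
      grow <- unique(unlist(lapply(idx, function(i) {
        max(1L, i - w):min(length(d), i + w)
      })))
      spike[grow] <- TRUE
    }
  }
  if (any(spike)) {
    if (config$fill == "interp" && !all(spike)) {
      clean <- which(!spike)
      d[spike] <- stats::approx(clean, d[clean], xout = which(spike),
                                rule = 2)$y
    } else {
      d[spike] <- 0
    }
  }
  list(trace = trace[1] + c(0, cumsum(d)),
       spike_mask = c(FALSE, spike))
}

#' One-sigma cross-bin outlier rejection
#'
#' Keeps the per-bin scalar summaries (window HR or BR estimates) lying
#' within `sigma_multiplier` standard deviations of the cross-bin mean. At
#' least one bin always survives (the one closest to the mean). Applied to
#' per-bin estimates, never to raw samples.
#'
#' @param per_bin_values Numeric vector, one summary value per bin (>= 3 for
#'   a meaningful spread; fewer passes through with a warning).
#' @param sigma_multiplier Band half-width in SDs.
#' @return Integer indices of surviving bins.
#' @export
reject_outlier_bins <- function(per_bin_values, sigma_multiplier = 1) {
  n <- length(per_bin_values)
  if (n < 3) {
    warning("fewer than 3 bins: outlier rejection skipped", call. = FALSE)
    return(seq_len(n))
  }
  mu <- mean(per_bin_values)
  s <- stats::sd(per_bin_values)
  keep <- which(abs(per_bin_values - mu) <= sigma_multiplier * s + 1e-12)
  if (length(keep) == 0) keep <- which.min(abs(per_bin_values - mu))
  keep
}

#' Recalibrate the spike threshold on clean recordings
#'
#' Empirical-rule calibration: the threshold is the mean plus three standard
#' deviations of the absolute per-sample steps observed in movement-free
#' breathing traces.
#'
#' @param traces A list of numeric displacement traces (mm) known to be free
#'   of body movements.
#' @return Threshold in mm/sample.
#' @export
calibrate_threshold <- function(traces) {
  steps <- abs(unlist(lapply(traces, diff)))
  mean(steps) + 3 * stats::sd(steps)
}
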