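#' Physiological displacement profile for the forward model
#'
#' Describes the seated subject the simulator emulates: breathing displacement
#' in the 0.1-0.8 Hz band at millimetre scale with weighted 2nd-4th
#' harmonics, and a quasi-periodic cardiac displacement train (~0.02 mm) with
#' a two-peaks-then-valley (or three-peak) cycle shape. Interbeat intervals
#' follow a mean-reverting AR(1) sequence with stationary standard deviation
#' `ibi_sd`, clipped to 0.3-1.5 s.
#'
#' @param breathing_rate Breaths per minute (band centre must lie in 6-48,
#'   i.e. 0.1-0.8 Hz).
#' @param breathing_amplitude Fundamental breathing displacement amplitude, mm.
#' @param breathing_harmonic_weights Amplitudes of harmonics 2-4 relative to
#'   the fundamental (length 3). In quiet breathing the harmonics have
#'   amplitudes comparable to the cardiac displacement itself — a few
#'   hundredths of a millimetre against a 1 mm fundamental — hence the
#'   2-4% defaults; deep breathing is emulated by raising them (the second
#'   harmonic can then dominate the whole cardiac band).
#' @param mean_ibi Mean interbeat interval, s (cardiac fundamental
#'   `1/mean_ibi` must lie in 0.8-6 Hz).
#' @param ibi_sd Stationary IBI standard deviation, ms.
#' @param ibi_ar Lag-1 autocorrelation of the IBI sequence. Resting RR series
#'   are strongly autocorrelated (respiratory coupling), hence 0.8.
#' @param cardiac_amplitude Cardiac displacement amplitude, mm.
#' @param cardiac_template_kind `"two_peak"` or `"three_peak"`.
#' @param first_to_second_peak_ratio Height ratio of the cycle's peaks.
#' @param noise_sd White displacement-noise standard deviation, mm.
#' @param seed Integer seed making the subject reproducible.
#'
#' @return An object of class `physio_profile` (a named list).
#' @export
physio_profile <- function(breathing_rate = 15,
                           breathing_amplitude = 1,
                           breathing_harmonic_weights = c(0.04, 0.02, 0.01),
                           mean_ibi = 0.857,
                           ibi_sd = 40,
                           ibi_ar = 0.8,
                           cardiac_amplitude = 0.02,
                           cardiac_template_kind = "two_peak",
                           first_to_second_peak_ratio = 0.7,
                           noise_sd = 0,
                           seed = 1L) {
  f_breath <- breathing_rate / 60
  if (breathing_amplitude > 0 && (f_breath < 0.1 || f_breath > 0.8)) {
    stop("breathing fundamental ", signif(f_breath, 3),
         " Hz outside the 0.1-0.8 Hz breathing band", call. = FALSE)
  }
  if (cardiac_amplitude > 0) {
    f_card <- 1 / mean_ibi
    if (f_card < 0.8 || f_card > 6) {
      stop("cardiac fundamental ", signif(f_card, 3),
           " Hz outside the 0.8-6 Hz cardiac band", call. = FALSE)
    }
  }
  stopifnot(length(breathing_harmonic_weights) == 3,
            ibi_sd >= 0, abs(ibi_ar) < 1, noise_sd >= 0)
  structure(
    list(
      breathing_rate = breathing_rate,
      breathing_amplitude = breathing_amplitude,
      breathing_harmonic_weights = breathing_harmonic_weights,
      mean_ibi = mean_ibi,
      ibi_sd = ibi_sd,
      ibi_ar = ibi_ar,
      cardiac_amplitude = cardiac_amplitude,
      cardiac_template_kind = cardiac_template_kind,
      first_to_second_peak_ratio = first_to_second_peak_ratio,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "physio_profile"
  )
}

#' A transient body-movement artifact
#'
#' Seated-subject body movements appear in the displacement trace either as a
#' narrow strong pulse (torso rocks and returns) or as a positive/negative DC
#' step (posture shift). Both have per-frame derivatives far above anything
#' breathing or the heart produce, which is what the time-domain compensation
#' keys on.
#'
#' @param onset Event start time, s.
#' @param kind `"narrow_pulse"`, `"dc_step_positive"` or `"dc_step_negative"`.
#' @param magnitude Peak (pulse) or step height, mm.
#' @param duration Event ramp time, s. Together with `magnitude` this sets
#'   the per-frame displacement step, which must land in the radar's
#'   detectable window: above the compensation threshold (0.48 mm/sample,
#'   else it is not an artifact in this model's sense) but below the
#'   unambiguous limit of a quarter wavelength per frame (~1.24 mm at 20 Hz;
#'   faster motion aliases in the slow-time phase and no longer looks like
#'   a spike to anything). The defaults (5 mm over 1 s; peak step
#'   ~0.79 mm/frame) sit inside that window.
#' @return An object of class `movement_event`.
#' @export
movement_event <- function(onset, kind = c("narrow_pulse", "dc_step_positive",
                                           "dc_step_negative"),
                           magnitude = 5, duration = 1) {
  kind <- match.arg(kind)
  stopifnot(onset >= 0, magnitude > 0, duration > 0)
  structure(list(onset = onset, kind = kind, magnitude = magnitude,
                 duration = duration),
            class = "movement_event")
}

#' Generate ground-truth torso displacement
#'
#' The forward model's displacement trace at the frame rate:
#' breathing fundamental plus weighted 2nd-4th harmonics, a cardiac template
#' train resampled beat-by-beat along a jittered IBI sequence, movement
#' artifacts, and optional white displacement noise. Ground truth (valley
#' times, IBI series, clean displacement) is recorded for evaluation.
#'
#' @param profile A [physio_profile()].
#' @param movement_events List of [movement_event()] objects (may be empty).
#' @param duration Recording length, s (>= 30 s recommended for HRV use).
#' @param prf Frame rate, Hz.
#'
#' @return A list with class `displacement_truth`:
#' * `displacement`: tibble `time_s`, `disp_mm` — the observed (artifact-laden)
#'   trace;
#' * `truth`: list with `valley_times` (s), `ibi_series` (ms), `br_true`
#'   (breaths/min), `hr_true` (beats/min), `displacement_clean` (mm vector,
#'   breathing + cardiac only).
#' @export
generate_displacement <- function(profile, movement_events = list(),
                                  duration = 300, prf = 20) {
  stopifnot(inherits(profile, "physio_profile"), duration > 0, prf > 0)
  n <- round(duration * prf)
  t <- (seq_len(n) - 1) / prf

  with_seed(profile$seed, {
    breathing <- breathing_component(profile, t)
    card <- cardiac_component(profile, t, duration)
    noise <- if (profile$noise_sd > 0) stats::rnorm(n, 0, profile$noise_sd) else 0
  })
  clean <- breathing + card$trace
  artifacts <- movement_component(movement_events, t, prf)
  disp <- clean + artifacts + noise

  ibi_ms <- diff(card$valley_times) * 1000
  truth <- list(
    valley_times = card$valley_times,
    ibi_series = ibi_ms,
    br_true = profile$breathing_rate,
    hr_true = if (length(ibi_ms)) 60000 / mean(ibi_ms) else NA_real_,
    displacement_clean = clean
  )
  structure(
    list(displacement = tibble::tibble(time_s = t, disp_mm = disp),
         truth = truth, profile = profile, prf = prf),
    class = "displacement_truth"
  )
}

breathing_component <- function(profile, t) {
  if (profile$breathing_amplitude <= 0) return(rep(0, length(t)))
  f <- profile$breathing_rate / 60
  ph <- stats::runif(4, 0, 2 * pi)
  a <- profile$breathing_amplitude
  w <- c(1, profile$breathing_harmonic_weights)
  x <- rep(0, length(t))
  for (k in 1:4) x <- x + a * w[k] * sin(2 * pi * k * f * t + ph[k])
  x
}

cardiac_component <- function(profile, t, duration) {
  if (profile$cardiac_amplitude <= 0) {
    return(list(trace = rep(0, length(t)), valley_times = numeric()))
  }
  ibis <- simulate_ibi_sequence(profile, duration)
  # valley train: first valley a random fraction of a beat after t = 0
  v <- stats::runif(1, 0, ibis[1]) + c(0, cumsum(ibis))
  tpl <- generate_cardiac_template(profile$cardiac_template_kind,
                                   profile$first_to_second_peak_ratio,
                                   n_points = 256L)
  u_v <- attr(tpl, "valley_phase")
  # continuous beat phase: 0 at each valley, advancing by 1 per beat
  phase <- beat_phase(t, v)
  idx <- (phase + u_v) %% 1
  trace <- profile$cardiac_amplitude *
    stats::approx(x = seq(0, 1, length.out = 257),
                  y = c(tpl, tpl[1]), xout = idx)$y
  list(trace = trace, valley_times = v[v >= 0 & v <= max(t)])
}

# mean-reverting AR(1) IBI sequence (s), stationary sd = ibi_sd ms,
# clipped to the physiological 0.3-1.5 s window
simulate_ibi_sequence <- function(profile, duration) {
  mu <- profile$mean_ibi
  sd_s <- profile$ibi_sd / 1000
  phi <- profile$ibi_ar
  n_max <- ceiling((duration + 5) / max(mu - 4 * sd_s, 0.3)) + 2L
  e <- stats::rnorm(n_max, 0, sd_s * sqrt(1 - phi^2))
  x <- numeric(n_max)
  x[1] <- mu + stats::rnorm(1, 0, sd_s)
  for (i in 2:n_max) x[i] <- mu + phi * (x[i - 1] - mu) + e[i]
  x <- pmin(pmax(x, 0.3), 1.5)
  keep <- which(cumsum(x) <= duration + 2 * mu)
  x[seq_len(max(length(keep), 2L))]
}

# piecewise-linear beat phase: counts beats, 0 at valley v[i], 1 at v[i+1];
# extrapolates with the edge IBIs outside the valley train
beat_phase <- function(t, v) {
  nb <- length(v)
  iv <- findInterval(t, v)
  phase <- numeric(length(t))
  inside <- iv >= 1 & iv < nb
  phase[inside] <- (t[inside] - v[iv[inside]]) / (v[iv[inside] + 1] - v[iv[inside]])
  before <- iv < 1
  phase[before] <- (t[before] - v[1]) / (v[2] - v[1])
  after <- iv >= nb
  phase[after] <- (t[after] - v[nb]) / (v[nb] - v[nb - 1])
  phase
}

movement_component <- function(events, t, prf) {
  x <- rep(0, length(t))
  for (ev in events) {
    stopifnot(inherits(ev, "movement_event"))
    if (ev$kind == "narrow_pulse") {
      inside <- t >= ev$onset & t <= ev$onset + ev$duration
      x[inside] <- x[inside] +
        ev$magnitude * 0.5 * (1 - cos(2 * pi * (t[inside] - ev$onset) / ev$duration))
    } else {
      sgn <- if (ev$kind == "dc_step_positive") 1 else -1
      ramp <- pmin(pmax((t - ev$onset) / ev$duration, 0), 1)
      x <- x + sgn * ev$magnitude * ramp
    }
  }
  x
}

# run code with a local RNG state: seeded, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
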