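#' Reference synthetic seated-subject cohort
#'
#' Generates one recording of the package's standard evaluation cohort:
#' seated subjects monitored for `duration` seconds at a 20 Hz frame rate,
#' with breathing rates spread over 9-20 breaths/min at 1 mm displacement,
#' a two-peak cardiac waveform at 0.02 mm, interbeat-interval jitter of
#' 40 ms (SD), three narrow 5 mm movement pulses at seeded times, and
#' chirp-level phase noise. The subject's mean interbeat interval is drawn
#' from 0.70-1.05 s (resting heart rates of roughly 57-86 beats/min),
#' independent of the breathing rate, as in a resting adult population.
#'
#' @param seed Recording seed (also selects the breathing rate from the
#'   9-20 breaths/min grid).
#' @param duration Recording length, s.
#' @param config A [radar_config()].
#' @param n_events Number of movement pulses.
#' @param template `"two_peak"` or `"three_peak"` cardiac cycle shape.
#' @return As [simulate_recording()]: list with `cube`, `truth`,
#'   `displacement`, `profile`, `bins`.
#' @export
cohort_recording <- function(seed, duration = 300, config = radar_config(),
                             n_events = 3, template = "two_peak") {
  brs <- seq(9, 20, length.out = 8)
  draws <- with_seed(seed + 1000L, stats::runif(1 + n_events))
  profile <- physio_profile(
    breathing_rate = brs[(seed - 1) %% 8 + 1],
    mean_ibi = 0.70 + 0.35 * draws[1],
    ibi_sd = 40,
    cardiac_template_kind = template,
    seed = seed
  )
  events <- purrr::map(seq_len(n_events), function(i) {
    movement_event(onset = 20 + (duration - 45) * draws[1 + i],
                   kind = "narrow_pulse", magnitude = 5, duration = 1)
  })
  simulate_recording(profile, events, duration = duration, config = config)
}
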