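#' Breathing-rate estimation
#'
#' Band-passes the movement-compensated displacement to the 0.1-0.8 Hz
#' breathing band and locates the dominant Welch-spectrum peak. The first
#' four harmonics of the peak are reported: they drive the
#' breathing-multiple exclusion rule of the cardiac harmonic selection.
#' If the breathing-band RMS displacement falls below the breath-hold floor
#' (0.15 mm), the subject is flagged as breath-holding and the breathing
#' rate is undefined.
#'
#' @param trace Displacement series, mm (movement-compensated).
#' @param prf Sampling rate, Hz.
#' @param window Welch segment length, s (>= 20 s; default 60 s).
#' @param band Breathing band edges, Hz.
#' @param breath_hold_floor RMS displacement below which the window is
#'   treated as a breath-hold, mm.
#' @return An object of class `respiration_estimate`: list with `br`
#'   (breaths/min, `NA` during breath-hold), `peak_frequency` (Hz),
#'   `band`, `harmonics` (Hz, orders 1-4), `band_rms` (mm), `breath_hold`
#'   (logical).
#' @export
estimate_br <- function(trace, prf, window = 60, band = c(0.1, 0.8),
                        breath_hold_floor = 0.15) {
  stopifnot(window >= 20 || length(trace) / prf < 20)
  filt <- bandpass(trace, band[1], band[2], prf)
  band_rms <- sqrt(mean(filt^2))
  if (band_rms < breath_hold_floor) {
    return(structure(list(br = NA_real_, peak_frequency = NA_real_,
                          band = band, harmonics = numeric(),
                          band_rms = band_rms, breath_hold = TRUE),
                     class = "respiration_estimate"))
  }
  psd <- welch_psd(filt, prf, seg_len = round(min(window, length(trace) / prf) * prf))
  in_band <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  peak <- psd$freq_hz[in_band][which.max(psd$power[in_band])]
  structure(
    list(br = 60 * peak, peak_frequency = peak, band = band,
         harmonics = peak * (1:4), band_rms = band_rms, breath_hold = FALSE),
    class = "respiration_estimate"
  )
}

#' @export
print.respiration_estimate <- function(x, ...) {
  if (x$breath_hold) {
    cat(sprintf("<respiration_estimate> breath-hold (band RMS %.3f mm)\n",
                x$band_rms))
  } else {
    cat(sprintf("<respiration_estimate> BR %.1f breaths/min (peak %.3f Hz, band RMS %.2f mm)\n",
                x$br, x$peak_frequency, x$band_rms))
  }
  invisible(x)
}
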