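#' Radar waveform and system configuration
#'
#' Bundles the chirp/waveform parameters of a 60 GHz FMCW radar together with
#' the geometry derived from them. Defaults reproduce a seat-back monitoring
#' design: a 5 GHz sweep starting at 58 GHz, 64 fast-time samples per chirp at
#' 1 MHz, 32 chirps per frame, and a 20 Hz frame rate (twice the 10 Hz maximum
#' vibration frequency the system is designed to observe).
#'
#' Derived quantities:
#' * chirp duration `T = BW / K` (here 64 us, exactly one chirp of samples),
#' * range resolution `delta_r = c / (2 BW)` (3 cm),
#' * maximum unambiguous range `samples_per_chirp / 2 * delta_r` (96 cm),
#' * centre wavelength `lambda = c / (f_min + BW / 2)` (~4.96 mm), the scale
#'   that converts slow-time phase to displacement.
#'
#' @param f_min Sweep start frequency in Hz.
#' @param bandwidth Sweep bandwidth in Hz.
#' @param slope Chirp slope in Hz/s.
#' @param sample_rate Fast-time ADC rate in Hz.
#' @param samples_per_chirp Fast-time samples recorded per chirp.
#' @param chirps_per_frame Chirps averaged into one frame.
#' @param prf Frame (pulse repetition) rate in Hz.
#' @param idle_time Inter-chirp idle time in s (bookkeeping only).
#' @param c Propagation speed in m/s. The conventional radar value 3e8 keeps
#'   the printed design identities exact (3 cm resolution, 96 cm max range).
#'
#' @return An object of class `radar_config`: a list with the fields above
#'   plus `chirp_duration`, `range_resolution`, `max_range`, `wavelength`.
#' @examples
#' cfg <- radar_config()
#' cfg$range_resolution # 0.03 m
#' cfg$max_range        # 0.96 m
#' @export
radar_config <- function(f_min = 58e9,
                         bandwidth = 5e9,
                         slope = 78.128e12,
                         sample_rate = 1e6,
                         samples_per_chirp = 64L,
                         chirps_per_frame = 32L,
                         prf = 20,
                         idle_time = 5e-6,
                         c = 3e8) {
  stopifnot(f_min > 0, bandwidth > 0, slope > 0, sample_rate > 0,
            samples_per_chirp >= 2, chirps_per_frame >= 1, prf > 0)
  chirp_duration <- bandwidth / slope
  # the sweep must fill the sampled window: BW = K * T within one sample period
  if (abs(chirp_duration - samples_per_chirp / sample_rate) > 1 / sample_rate) {
    stop("bandwidth/slope imply a chirp duration inconsistent with ",
         "samples_per_chirp/sample_rate (|BW/K - N/fs| > 1/fs)", call. = FALSE)
  }
  range_resolution <- c / (2 * bandwidth)
  cfg <- structure(
    list(
      f_min = f_min,
      bandwidth = bandwidth,
      slope = slope,
      sample_rate = sample_rate,
      samples_per_chirp = as.integer(samples_per_chirp),
      chirps_per_frame = as.integer(chirps_per_frame),
      prf = prf,
      idle_time = idle_time,
      c = c,
      chirp_duration = chirp_duration,
      range_resolution = range_resolution,
      max_range = samples_per_chirp / 2 * range_resolution,
      wavelength = c / (f_min + bandwidth / 2)
    ),
    class = "radar_config"
  )
  cfg
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  sweep: %.1f-%.1f GHz (BW %.1f GHz, slope %.3f MHz/us)\n",
              x$f_min / 1e9, (x$f_min + x$bandwidth) / 1e9,
              x$bandwidth / 1e9, x$slope / 1e12))
  cat(sprintf("  chirp: %d samples @ %.0f MHz (T = %.1f us), %d chirps/frame\n",
              x$samples_per_chirp, x$sample_rate / 1e6,
              x$chirp_duration * 1e6, x$chirps_per_frame))
  cat(sprintf("  frame rate: %g Hz; range res %.1f cm; max range %.0f cm; lambda %.2f mm\n",
              x$prf, x$range_resolution * 100, x$max_range * 100,
              x$wavelength * 1e3))
  invisible(x)
}

#' Convert a range in metres to its fast-time FFT bin
#'
#' Bin indexing is 0-based: bin `b` covers ranges around `b * delta_r`.
#'
#' @param range_m Range(s) in metres.
#' @param config A [radar_config()].
#' @return Integer bin index/indices.
#' @export
range_to_bin <- function(range_m, config) {
  as.integer(round(range_m / config$range_resolution))
}

#' Beat frequency of a scatterer
#'
#' `f_b = 2 R K / c`: the fast-time frequency at which a reflector at range
#' `R` appears after mixing.
#'
#' @inheritParams range_to_bin
#' @return Beat frequency in Hz.
#' @export
beat_frequency <- function(range_m, config) {
  2 * range_m * config$slope / config$c
}
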