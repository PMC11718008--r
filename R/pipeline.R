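#' Full processing-chain configuration
#'
#' One document holding every tunable of the chain: radar geometry, motion
#' compensation, band edges, decomposition parameters, bin selection, and
#' fusion windows. Validated on construction; [read_pipeline_config()]
#' rejects unknown keys.
#'
#' @param radar A [radar_config()].
#' @param motion A [motion_config()].
#' @param bins 0-based torso range bins to process.
#' @param breathing_band,cardiac_band Band edges, Hz.
#' @param vmd_k,vmd_alpha,vmd_tau,vmd_tol,vmd_max_iter Decomposition
#'   parameters (see [vmd_decompose()]). The pipeline default
#'   `vmd_alpha = 40000` makes the mode half-width `fs / sqrt(alpha)` about
#'   0.1 Hz at a 20 Hz frame rate: narrow enough to resolve a cardiac
#'   fundamental from a breathing multiple ~0.15 Hz away (generic
#'   literature values of a few thousand give ~0.3 Hz-wide modes, which
#'   swallow both lines into one mode and break the breathing-rejection
#'   logic).
#' @param use_vmd If `FALSE`, the cardiac waveform is the band-passed trace
#'   itself (the ablation baseline) instead of a harmonic reconstruction.
#' @param multi_bin If `FALSE`, only the first bin in `bins` is processed
#'   (single-bin ablation).
#' @param fusion_window Cross-bin valley matching half-window, s.
#' @param beat_correction Apply [correct_ibi_artifacts()] to the fused
#'   valley series before HRV computation.
#' @param wideband_refine Re-time fused beats on the band-passed 0.8-6 Hz
#'   waveform with [refine_beats_wideband()]. Off by default: it recovers
#'   timing detail the narrowband reconstruction smooths away, but only
#'   when the wide-band per-beat signal-to-noise ratio is high (clean,
#'   breath-hold-like recordings); under breathing interference and phase
#'   noise it locks onto the interference instead.
#' @param edge_guard Seconds at each end of the recording whose beats are
#'   excluded from NN-interval metrics (filter settling).
#' @param sqi_floor Signal-quality floor: beats whose local cycle
#'   peak-to-valley amplitude falls below this fraction of the median cycle
#'   amplitude (a ~4 dB drop, the signature of destructive interference or
#'   a weak reflection) are excluded from NN-interval metrics.
#' @param movement_guard Half-width (s) of the window around detected
#'   movement spikes whose beats are excluded from NN-interval metrics: the
#'   compensation removes the gross displacement step, but the cardiac
#'   microstructure during the event — and the band-pass ringing around it —
#'   is unrecoverable.
#' @param welch_window Breathing spectral-estimation segment, s.
#' @param breath_hold_floor Breathing-band RMS floor, mm.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(radar = radar_config(),
                            motion = motion_config(),
                            bins = 4:9,
                            breathing_band = c(0.1, 0.8),
                            cardiac_band = c(0.8, 6),
                            vmd_k = 10L, vmd_alpha = 40000, vmd_tau = 0,
                            vmd_tol = 1e-7, vmd_max_iter = 500L,
                            use_vmd = TRUE, multi_bin = TRUE,
                            fusion_window = 0.25, beat_correction = TRUE,
                            wideband_refine = FALSE,
                            movement_guard = 3.5, edge_guard = 5,
                            sqi_floor = 0.45, welch_window = 60,
                            breath_hold_floor = 0.15) {
  stopifnot(inherits(radar, "radar_config"), inherits(motion, "motion_config"),
            length(bins) >= 1, all(bins >= 0),
            breathing_band[1] > 0, breathing_band[2] > breathing_band[1],
            cardiac_band[1] >= breathing_band[2],
            cardiac_band[2] > cardiac_band[1],
            cardiac_band[2] < radar$prf / 2,
            vmd_k >= 1, vmd_alpha > 0, vmd_tol > 0,
            fusion_window > 0, breath_hold_floor >= 0)
  structure(
    list(radar = radar, motion = motion, bins = as.integer(bins),
         breathing_band = breathing_band, cardiac_band = cardiac_band,
         vmd_k = as.integer(vmd_k), vmd_alpha = vmd_alpha, vmd_tau = vmd_tau,
         vmd_tol = vmd_tol, vmd_max_iter = as.integer(vmd_max_iter),
         use_vmd = isTRUE(use_vmd), multi_bin = isTRUE(multi_bin),
         fusion_window = fusion_window,
         beat_correction = isTRUE(beat_correction),
         wideband_refine = isTRUE(wideband_refine),
         movement_guard = movement_guard, edge_guard = edge_guard,
         sqi_floor = sqi_floor, welch_window = welch_window,
         breath_hold_floor = breath_hold_floor),
    class = "pipeline_config"
  )
}

#' Run the full inverse chain on a radar cube
#'
#' Executes, in order: DC removal, chirp averaging, fast-time FFT, per-bin
#' phase extraction and unwrapping, time-domain movement compensation,
#' breathing-rate estimation with one-sigma cross-bin rejection, cardiac
#' band-pass, variational mode decomposition, breathing-multiple-aware
#' harmonic selection and reconstruction, valley detection, cross-bin
#' fusion, and IBI/HR/HRV computation.
#'
#' @param cube A `radar_cube` (from [synthesize_cube()] or
#'   [read_radar_cube()]).
#' @param config A [pipeline_config()].
#' @return A `vitals_report`: list with fields `br` (breaths/min), `hr`
#'   (beats/min), `ibi_series` (ms), `rmssd`, `sdrr` (ms), `pnn50` (%),
#'   `morphology`, `valley_times` (s), `per_bin` (tibble of per-bin
#'   diagnostics), `surviving_bins`, `flags` (character), `resp`
#'   (`respiration_estimate`), `waveform` (reference-bin
#'   `cardiac_waveform`, or `NULL`), `status` one of `"ok"`,
#'   `"breath_hold"`, `"refused"`, `"insufficient_beats"`.
#' @export
run_pipeline <- function(cube, config = pipeline_config()) {
  stopifnot(inherits(cube, "radar_cube"), inherits(config, "pipeline_config"))
  prf <- config$radar$prf
  bins <- if (config$multi_bin) config$bins else config$bins[1]

  disp <- cube |>
    remove_dc() |>
    average_chirps() |>
    range_fft(config$radar) |>
    extract_displacement(bin_ids = bins, config = config$radar)
  traces <- bin_matrix(disp)

  comp_list <- lapply(seq_len(ncol(traces)), function(j) {
    compensate_movement(traces[, j], config$motion)
  })
  comp <- vapply(comp_list, function(cm) cm$trace, numeric(nrow(traces)))
  spike_any <- Reduce(`|`, lapply(comp_list, function(cm) cm$spike_mask))
  n_spikes <- sum(spike_any)
  spike_times <- disp$time_s[spike_any]

  # breathing: per-bin estimates, one-sigma fusion
  resp_bins <- lapply(seq_len(ncol(comp)), function(j) {
    estimate_br(comp[, j], prf, window = config$welch_window,
                band = config$breathing_band,
                breath_hold_floor = config$breath_hold_floor)
  })
  brs <- vapply(resp_bins, function(r) r$br %||% NA_real_, numeric(1))
  flags <- character()
  if (n_spikes > 0) flags <- c(flags, "movement_compensated")
  if (mean(is.na(brs)) > 0.5) {
    resp <- resp_bins[[1]]
    resp$breath_hold <- TRUE
    resp$br <- NA_real_
    flags <- c(flags, "breath_hold")
  } else {
    ok <- which(!is.na(brs))
    keep <- ok[reject_outlier_bins(brs[ok], config$motion$sigma_multiplier)]
    fused_peak <- stats::median(vapply(resp_bins[keep],
                                       function(r) r$peak_frequency, numeric(1)))
    resp <- structure(
      list(br = 60 * fused_peak, peak_frequency = fused_peak,
           band = config$breathing_band, harmonics = fused_peak * (1:4),
           band_rms = stats::median(vapply(resp_bins[keep],
                                           function(r) r$band_rms, numeric(1))),
           breath_hold = FALSE),
      class = "respiration_estimate"
    )
  }

  # cardiac chain per bin
  per_bin <- purrr::map(seq_along(bins), function(j) {
    card <- bandpass_cardiac(comp[, j], prf, config$cardiac_band)
    waveform <- NULL
    refused <- FALSE
    if (config$use_vmd) {
      imfs <- vmd_decompose(card, prf, K = config$vmd_k,
                            alpha = config$vmd_alpha, tau = config$vmd_tau,
                            tol = config$vmd_tol,
                            max_iter = config$vmd_max_iter,
                            init_band = config$cardiac_band)
      plan <- select_harmonics(imfs, resp)
      if (plan$refused) {
        refused <- TRUE
      } else {
        waveform <- reconstruct(plan, imfs)
      }
    } else {
      waveform <- structure(
        list(trace = card, fundamental = NA_real_,
             harmonic_orders_used = integer(), source_mode_indices = integer(),
             hr_spectral = NA_real_, fs = prf),
        class = "cardiac_waveform"
      )
    }
    valleys <- if (refused) numeric() else
      suppressWarnings(detect_valleys(waveform))
    hr <- if (length(valleys) >= 4) 60 / mean(diff(valleys)) else NA_real_
    list(bin = bins[j], waveform = waveform, bandpassed = card,
         valleys = valleys, hr = hr, br = brs[j], refused = refused)
  })

  hr_bins <- vapply(per_bin, function(b) b$hr, numeric(1))
  fusion <- fuse_bins(purrr::map(per_bin, "valleys"), hr_bins,
                      config$motion$sigma_multiplier, config$fusion_window)
  if (fusion$all_rejected) flags <- c(flags, "all_bins_rejected")
  # re-time beats on the wide-band waveform: the narrowband reconstruction
  # locates beats but smooths away the short-term timing variability
  if (config$use_vmd && config$wideband_refine &&
      length(fusion$valley_times) >= 8 && !is.na(fusion$reference_bin)) {
    ref_rel <- match(fusion$reference_bin, seq_along(bins))
    fusion$valley_times <- refine_beats_wideband(
      fusion$valley_times, per_bin[[ref_rel]]$bandpassed, prf)
  }

  valley_valid <- NULL
  if (config$beat_correction && length(fusion$valley_times) >= 4) {
    corrected <- correct_ibi_artifacts(fusion$valley_times)
    valley_valid <- !(corrected %in% attr(corrected, "inserted"))
    fusion$valley_times <- as.numeric(corrected)
    # beats inside a movement event (and the surrounding filter ringing)
    # are not trustworthy fiducials: drop them from the NN-interval set
    if (length(spike_times)) {
      near_spike <- vapply(fusion$valley_times, function(v) {
        any(abs(spike_times - v) <= config$movement_guard)
      }, logical(1))
      valley_valid <- valley_valid & !near_spike
    }
    # the band-pass and decomposition settle over the first/last few
    # seconds: edge beats are not normal intervals either
    t_end <- max(disp$time_s)
    valley_valid <- valley_valid &
      fusion$valley_times > config$edge_guard &
      fusion$valley_times < t_end - config$edge_guard
    # signal-quality index: beats in cycles whose local peak-to-valley
    # amplitude collapses (destructive interference, weak reflection) have
    # unreliable timing
    ref_bin_rel <- match(fusion$reference_bin, seq_along(bins))
    if (!is.na(ref_bin_rel) && !is.null(per_bin[[ref_bin_rel]]$waveform)) {
      wtr <- per_bin[[ref_bin_rel]]$waveform$trace
      half_ibi <- 0.5 * stats::median(diff(fusion$valley_times))
      amps <- vapply(fusion$valley_times, function(v) {
        a <- max(1L, floor((v - half_ibi) * prf) + 1L)
        b <- min(length(wtr), ceiling((v + half_ibi) * prf) + 1L)
        max(wtr[a:b]) - min(wtr[a:b])
      }, numeric(1))
      valley_valid <- valley_valid & amps >= config$sqi_floor * stats::median(amps)
    }
    # never let quality flags hollow out the series entirely
    if (mean(valley_valid) < 0.5) valley_valid <- NULL
  }

  status <- "ok"
  if (all(vapply(per_bin, function(b) b$refused, logical(1)))) {
    status <- "refused"
    flags <- c(flags, "reconstruction_refused")
  } else if (length(fusion$valley_times) < 4) {
    status <- "insufficient_beats"
  }
  if (isTRUE(resp$breath_hold) && status == "ok") status <- "breath_hold"

  hrv <- if (length(fusion$valley_times) >= 4) {
    compute_hrv(fusion$valley_times, valid = valley_valid)
  } else {
    list(ibi_series = numeric(), hr = NA_real_, rmssd = NA_real_,
         sdrr = NA_real_, pnn50 = NA_real_)
  }
  ref_wave <- NULL
  morph <- "indeterminate"
  if (!is.na(fusion$reference_bin)) {
    ref <- per_bin[[match(fusion$reference_bin, seq_along(bins))]]
    ref_wave <- ref$waveform
    # morphology is a property of the band-passed waveform (the pattern the
    # seat radar shows during calm rest), not of the harmonic reconstruction
    if (length(fusion$valley_times) >= 6) {
      morph <- classify_morphology(ref$bandpassed, fusion$valley_times,
                                   fs = prf)
    }
  }

  structure(
    list(br = resp$br, hr = hrv$hr, ibi_series = hrv$ibi_series,
         rmssd = hrv$rmssd, sdrr = hrv$sdrr, pnn50 = hrv$pnn50,
         morphology = morph, valley_times = fusion$valley_times,
         per_bin = tibble::tibble(
           bin = vapply(per_bin, function(b) b$bin, integer(1)),
           hr = hr_bins,
           br = vapply(per_bin, function(b) b$br, numeric(1)),
           refused = vapply(per_bin, function(b) b$refused, logical(1)),
           surviving = seq_along(per_bin) %in% fusion$surviving_bins
         ),
         surviving_bins = vapply(per_bin, function(b) b$bin,
                                 integer(1))[fusion$surviving_bins],
         flags = flags, resp = resp, waveform = ref_wave, status = status),
    class = "vitals_report"
  )
}

#' @export
print.vitals_report <- function(x, ...) {
  cat("<vitals_report> status:", x$status, "\n")
  cat(sprintf("  BR %.1f breaths/min | HR %.1f beats/min | %d beats\n",
              x$br %||% NA, x$hr %||% NA, length(x$ibi_series) + 1))
  cat(sprintf("  RMSSD %.1f ms | SDRR %.1f ms | pNN50 %.1f%% | morphology: %s\n",
              x$rmssd, x$sdrr, x$pnn50, x$morphology))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
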