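#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a vitals report into a per-beat tibble
#'
#' @param x A `vitals_report`.
#' @param ... Unused.
#' @return A tibble with one row per beat: `beat`, `valley_time_s`,
#'   `ibi_ms` (`NA` for the first beat).
#' @method tidy vitals_report
#' @export
tidy.vitals_report <- function(x, ...) {
  tibble::tibble(
    beat = seq_along(x$valley_times),
    valley_time_s = x$valley_times,
    ibi_ms = c(NA_real_, x$ibi_series)
  )
}

#' One-row summary of a vitals report
#'
#' @param x A `vitals_report`.
#' @param ... Unused.
#' @return A one-row tibble: `status`, `br`, `hr`, `rmssd`, `sdrr`, `pnn50`,
#'   `morphology`, `n_beats`, `n_surviving_bins`.
#' @method glance vitals_report
#' @export
glance.vitals_report <- function(x, ...) {
  tibble::tibble(
    status = x$status, br = x$br, hr = x$hr, rmssd = x$rmssd,
    sdrr = x$sdrr, pnn50 = x$pnn50, morphology = x$morphology,
    n_beats = length(x$valley_times),
    n_surviving_bins = length(x$surviving_bins)
  )
}

#' Tidy an IMF set into a mode-level tibble
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return A tibble: `mode`, `center_hz`, `power`.
#' @method tidy imf_set
#' @export
tidy.imf_set <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$center_frequencies),
                 center_hz = x$center_frequencies,
                 power = x$powers)
}

#' One-row summary of an IMF decomposition
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `converged`, `n_iter`,
#'   `residual_fraction` (residual RMS over input RMS).
#' @method glance imf_set
#' @export
glance.imf_set <- function(x, ...) {
  input <- rowSums(x$modes) + x$residual
  tibble::tibble(
    k = ncol(x$modes), converged = x$converged, n_iter = x$n_iter,
    residual_fraction = sqrt(sum(x$residual^2) / max(sum(input^2),
                                                     .Machine$double.eps))
  )
}

#' Tidy a cardiac waveform into a sample-level tibble
#'
#' @param x A `cardiac_waveform`.
#' @param ... Unused.
#' @return A tibble: `time_s`, `disp_mm`.
#' @method tidy cardiac_waveform
#' @export
tidy.cardiac_waveform <- function(x, ...) {
  tibble::tibble(time_s = (seq_along(x$trace) - 1) / x$fs,
                 disp_mm = x$trace)
}

#' Tidy an evaluation into a per-beat error tibble
#'
#' @param x A `vitals_evaluation`.
#' @param ... Unused.
#' @return A tibble: `beat`, `abs_ibi_error_ms`.
#' @method tidy vitals_evaluation
#' @export
tidy.vitals_evaluation <- function(x, ...) {
  tibble::tibble(beat = seq_along(x$ibi_errors),
                 abs_ibi_error_ms = x$ibi_errors)
}

#' One-row evaluation summary
#'
#' @param x A `vitals_evaluation`.
#' @param ... Unused.
#' @return The evaluation's one-row summary tibble.
#' @method glance vitals_evaluation
#' @export
glance.vitals_evaluation <- function(x, ...) x$summary
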