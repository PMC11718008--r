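#' Remove the fast-time DC component of every chirp
#'
#' Subtracts each chirp's fast-time mean so that static leakage does not
#' smear into the low range bins of the fast-time FFT.
#'
#' @param cube A `radar_cube`.
#' @return The cube with zero-mean chirps.
#' @export
remove_dc <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  mu <- rowMeans(cube$samples, dims = 2)            # frames x chirps
  cube$samples <- cube$samples -
    array(mu, dim(cube$samples))                    # recycled along fast time
  cube
}

#' Average the chirps of each frame
#'
#' Breathing and cardiac motion are quasi-static across the chirps of one
#' frame, so the chirps are near-identical and averaging them leaves the beat
#' signal intact while suppressing per-chirp phase noise by ~10 log10(n) dB
#' for white noise.
#'
#' @param cube A `radar_cube`.
#' @return A numeric matrix frames x fast-time samples with attributes
#'   `config` and `timestamps`.
#' @export
average_chirps <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  avg <- rowMeans(aperm(cube$samples, c(1, 3, 2)), dims = 2)
  structure(avg, config = cube$config, timestamps = cube$timestamps)
}

#' Fast-time FFT: averaged chirps to a range-profile matrix
#'
#' One-sided fast-time spectrum per frame; bin `b` (0-based) covers ranges
#' around `b * delta_r`. A rectangular fast-time window is used: the torso
#' scatterers are isolated point reflectors and the 64-sample chirp gives
#' 3 cm bins that already separate them.
#'
#' @param averaged Output of [average_chirps()] (or any frames x samples
#'   matrix with a `config` attribute).
#' @param config A [radar_config()]; defaults to the matrix's own.
#' @return An object of class `range_profile`: list with `values` (complex,
#'   frames x bins), `bin_axis` (m), `frame_times` (s), `config`.
#' @export
range_fft <- function(averaged, config = attr(averaged, "config")) {
  stopifnot(is.matrix(averaged), !is.null(config))
  n <- ncol(averaged)
  spec <- t(stats::mvfft(t(averaged)))      # fast-time FFT along samples
  keep <- seq_len(n / 2)                    # one-sided
  structure(
    list(values = spec[, keep, drop = FALSE],
         bin_axis = (keep - 1) * config$range_resolution,
         frame_times = attr(averaged, "timestamps") %||%
           ((seq_len(nrow(averaged)) - 1) / config$prf),
         config = config),
    class = "range_profile"
  )
}

#' Extract per-bin displacement from the slow-time phase
#'
#' For each selected range bin the complex slow-time series is reduced to its
#' phase, unwrapped across 2 pi jumps (torso motion spans several wavelengths),
#' scaled by `lambda / (4 pi)` to millimetres, and shifted to start at 0 mm
#' (absolute range is not tracked in the displacement domain).
#'
#' @param profiles A `range_profile` from [range_fft()].
#' @param bin_ids 0-based range-bin indices; default 4:9, the 12-27 cm
#'   seat-back torso span.
#' @param config A [radar_config()]; defaults to the profile's own.
#' @return A `bin_displacement` tibble: `time_s` plus one `bin<k>_mm` column
#'   per selected bin, with attributes `prf`, `bin_ids`.
#' @export
extract_displacement <- function(profiles, bin_ids = 4:9,
                                 config = profiles$config) {
  stopifnot(inherits(profiles, "range_profile"))
  n_bins <- ncol(profiles$values)
  if (any(bin_ids < 0 | bin_ids >= n_bins)) {
    stop("bin index out of bounds (0..", n_bins - 1, ")", call. = FALSE)
  }
  scale_mm <- config$wavelength / (4 * pi) * 1000
  traces <- purrr::map(bin_ids, function(b) {
    ph <- unwrap_phase(Arg(profiles$values[, b + 1]))
    (ph - ph[1]) * scale_mm
  })
  names(traces) <- paste0("bin", bin_ids, "_mm")
  out <- tibble::tibble(time_s = profiles$frame_times, !!!traces)
  attr(out, "prf") <- config$prf
  attr(out, "bin_ids") <- bin_ids
  class(out) <- c("bin_displacement", class(out))
  out
}

# correct 2*pi jumps in a sampled phase series
unwrap_phase <- function(phi) {
  d <- diff(phi)
  phi + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Bin displacement columns as a matrix
#' @param x A `bin_displacement` tibble.
#' @return Numeric matrix frames x bins.
#' @keywords internal
bin_matrix <- function(x) {
  as.matrix(dplyr::select(tibble::as_tibble(x), -dplyr::any_of("time_s")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
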