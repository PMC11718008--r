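#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-bin displacement traces
#'
#' @param object A `bin_displacement` tibble.
#' @param ... Unused.
#' @return A ggplot: one line per range bin.
#' @method autoplot bin_displacement
#' @export
autoplot.bin_displacement <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              -"time_s", names_to = "bin",
                              values_to = "disp_mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$disp_mm,
                                     colour = .data$bin)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)", colour = NULL)
}

#' Plot an IMF decomposition
#'
#' @param object An `imf_set`.
#' @param ... Unused.
#' @return A ggplot faceted by mode, labelled with centre frequencies.
#' @method autoplot imf_set
#' @export
autoplot.imf_set <- function(object, ...) {
  t <- (seq_len(nrow(object$modes)) - 1) / object$fs
  long <- purrr::map_dfr(seq_len(ncol(object$modes)), function(k) {
    tibble::tibble(
      mode = sprintf("IMF %d (%.2f Hz)", k, object$center_frequencies[k]),
      time_s = t, value = object$modes[, k]
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~mode, ncol = 1, scales = "free_y",
                        strip.position = "right") +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)")
}

#' Plot a reconstructed cardiac waveform
#'
#' @param object A `cardiac_waveform`.
#' @param valleys Optional valley times (s) to mark.
#' @param ... Unused.
#' @return A ggplot of the waveform, with valley markers when given.
#' @method autoplot cardiac_waveform
#' @export
autoplot.cardiac_waveform <- function(object, valleys = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$time_s, .data$disp_mm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "cardiac displacement (mm)")
  if (!is.null(valleys) && length(valleys)) {
    p <- p + ggplot2::geom_vline(xintercept = valleys, colour = "red",
                                 linetype = "dotted", linewidth = 0.2)
  }
  p
}

#' Plot the interbeat-interval tachogram of a report
#'
#' @param object A `vitals_report`.
#' @param ... Unused.
#' @return A ggplot of IBI (ms) over beat time.
#' @method autoplot vitals_report
#' @export
autoplot.vitals_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$ibi_ms)),
                  ggplot2::aes(.data$valley_time_s, .data$ibi_ms)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "IBI (ms)")
}
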