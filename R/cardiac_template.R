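#' Unit-cycle cardiac displacement template
#'
#' Builds one cycle of the skin-displacement shape the heart imprints on the
#' torso. In seated, resting subjects the cycle shows two sequential peaks
#' followed by a single dominant valley (the valley aligning with the ECG
#' T-wave); subjects with a prolonged QTc show three peaks before the valley.
#' The shape is only known qualitatively, so the template is parametric: a sum
#' of smooth raised-cosine-like (Gaussian) lobes placed inside the cycle, with
#' the peak count and the dominance of the valley as the contract.
#'
#' @param kind `"two_peak"` (typical) or `"three_peak"` (atypical,
#'   prolonged-QTc-like).
#' @param peak_ratio Height of the first peak relative to the second
#'   (dimensionless, > 0). At rest the second peak dominates, so the default
#'   profile uses ratios below 1.
#' @param n_points Samples per cycle (>= 16).
#'
#' @return A numeric vector of length `n_points`: one zero-mean cycle with
#'   `max(abs(.)) == 1`, exactly `kind`-many local maxima and a single global
#'   minimum (the valley). The attribute `"valley_phase"` gives the cycle
#'   fraction (0-1) at which the valley sits.
#' @examples
#' tpl <- generate_cardiac_template("two_peak", 0.7, 64)
#' attr(tpl, "valley_phase")
#' @export
generate_cardiac_template <- function(kind = c("two_peak", "three_peak"),
                                      peak_ratio = 0.7,
                                      n_points = 64L) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 16, peak_ratio > 0)
  u <- (seq_len(n_points) - 1) / n_points
  lobes <- switch(kind,
    two_peak = list(
      centers = c(0.15, 0.42, 0.72),
      heights = c(peak_ratio, 1, -1.4)
    ),
    three_peak = list(
      centers = c(0.10, 0.32, 0.54, 0.80),
      heights = c(peak_ratio, 1, 0.85 * peak_ratio + 0.15, -1.4)
    )
  )
  width <- 0.065
  x <- rep(0, n_points)
  for (i in seq_along(lobes$centers)) {
    x <- x + lobes$heights[i] * wrapped_gaussian(u, lobes$centers[i], width)
  }
  x <- x - mean(x)
  x <- x / max(abs(x))
  structure(x, valley_phase = u[which.min(x)])
}

# periodic Gaussian bump on the unit circle (3 wraps suffice for width << 1)
wrapped_gaussian <- function(u, center, width) {
  exp(-((u - center) / width)^2 / 2) +
    exp(-((u - center - 1) / width)^2 / 2) +
    exp(-((u - center + 1) / width)^2 / 2)
}

#' Count circular local maxima of a sampled cycle
#'
#' Brute-force extremum scan treating the cycle as periodic. Used both by the
#' template contract tests and by morphology classification.
#'
#' @param x Numeric vector, one sampled cycle.
#' @return Integer count of strict local maxima.
#' @keywords internal
count_cycle_peaks <- function(x) {
  n <- length(x)
  xl <- x[c(n, seq_len(n - 1))]
  xr <- x[c(seq_len(n)[-1], 1)]
  sum(x > xl & x >= xr)
}
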