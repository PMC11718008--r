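#' Plan a cardiac-harmonic reconstruction from IMFs
#'
#' Implements the harmonic-selection rule that turns a 10-mode decomposition
#' of the 0.8-6 Hz band into a cardiac waveform:
#'
#' 1. every in-band mode is scored as a candidate fundamental by its
#'    harmonic pattern: the number of harmonic orders (2-4) at which another
#'    mode sits within the strict [harmonic_tolerance()] of an integer
#'    multiple of it, with total supported power as the tie-break. A heart
#'    beat is a displacement pulse train, rich in harmonics, so the true
#'    fundamental out-scores both its own second harmonic (an octave error
#'    would find support only at even orders) and breathing harmonics
#'    (whose in-band multiples are themselves excluded as breathing);
#' 2. if the best-supported candidate sits on a breathing multiple (orders
#'    1-4 of the estimated breathing rate), the heart rate cannot be trusted
#'    and reconstruction is refused — in deep breathing the strongest
#'    in-band mode is routinely the breathing second harmonic, but it has no
#'    cardiac-style harmonic pattern, so the cardiac mode out-scores it and
#'    processing continues;
#' 3. modes near integer multiples (1-4) of the winning fundamental are
#'    gathered into the reconstruction plan, except any that also sit on a
#'    breathing multiple (breathing wins);
#' 4. at least two usable components (fundamental + >= 1 harmonic) are
#'    required, otherwise reconstruction is refused rather than risking a
#'    breathing harmonic being reported as the heart.
#'
#' During breath-hold the exclusion list is empty.
#'
#' @param imfs An `imf_set` from [vmd_decompose()].
#' @param resp A `respiration_estimate` (or `NULL` for breath-hold mode).
#' @param tolerance Scalar breathing-exclusion tolerance in Hz, or `NULL`
#'   for the default `max(0.05 Hz, 3%)` rule.
#' @param gather_tol Half-width (Hz) of the window within which modes are
#'   gathered onto a harmonic order, either a number or a function of the
#'   target frequency. Wider than the exclusion tolerance on purpose:
#'   beat-to-beat jitter broadens each cardiac harmonic by several percent,
#'   splitting it over adjacent modes, and the breathing-exclusion rule
#'   (which always wins) already guards the gathered set.
#' @param max_order Highest harmonic order considered, for both cardiac
#'   inclusion and breathing exclusion.
#' @return An object of class `harmonic_plan`: list with `refused` (logical),
#'   `reason`, `fundamental_hz`, `mode_indices`, `harmonic_orders`
#'   (parallel to `mode_indices`; 1 = fundamental), `exclusions` (Hz).
#' @export
select_harmonics <- function(imfs, resp = NULL, tolerance = NULL,
                             gather_tol = function(f) pmax(0.15, 0.08 * f),
                             max_order = 4L) {
  if (is.numeric(gather_tol)) {
    gt <- gather_tol
    gather_tol <- function(f) rep(gt, length.out = length(f))
  }
  stopifnot(inherits(imfs, "imf_set"))
  exclusions <- if (is.null(resp) || isTRUE(resp$breath_hold)) {
    numeric()
  } else {
    resp$peak_frequency * seq_len(max_order)
  }
  excl_tol <- if (is.null(tolerance)) harmonic_tolerance(exclusions) else
    rep(tolerance, length.out = length(exclusions))
  on_breathing <- function(f) {
    length(exclusions) > 0 && any(abs(f - exclusions) <= excl_tol)
  }

  cf <- imfs$center_frequencies
  pow <- imfs$powers
  excluded <- vapply(cf, on_breathing, logical(1))
  band <- imfs$band %||% c(0.8, 6)
  cand <- which(pow > 0 & cf >= band[1] & cf <= band[2])
  if (length(cand) == 0) {
    return(refused_plan("no usable modes in the cardiac band", exclusions))
  }

  # harmonic-pattern score of each candidate fundamental
  support <- function(f0) {
    orders <- 0L
    p <- 0
    for (k in 2:4) {
      # peak-position errors scale with the order, so match on the
      # implied fundamental cf/k rather than at the k-th multiple
      m <- which(!excluded & pow > 0 &
                   abs(cf / k - f0) <= harmonic_tolerance(f0))
      if (length(m)) {
        orders <- orders + 1L
        p <- p + sum(pow[m])
      }
    }
    list(orders = orders, power = p)
  }
  n_sup <- integer(length(cand))
  p_sup <- numeric(length(cand))
  for (i in seq_along(cand)) {
    s <- support(cf[cand[i]])
    n_sup[i] <- s$orders
    p_sup[i] <- s$power + pow[cand[i]]
  }
  best <- cand[order(-n_sup, -p_sup)][1]
  if (excluded[best]) {
    return(refused_plan("cardiac fundamental coincides with a breathing multiple",
                        exclusions))
  }
  fund_idx <- best
  f0 <- cf[fund_idx]

  # accept every mode matching an order: beat-to-beat jitter spreads one
  # physiological harmonic across sidebands that the decomposition can split
  # over adjacent modes, and all of them carry beat-timing information
  idx <- fund_idx
  orders <- 1L
  for (k in 1:max_order) {
    target <- k * f0
    cand <- which(abs(imfs$center_frequencies - target) <= gather_tol(target) &
                    imfs$powers > 0)
    cand <- setdiff(cand, idx)
    cand <- cand[!vapply(imfs$center_frequencies[cand], on_breathing, logical(1))]
    if (length(cand)) {
      # keep the order's main mode plus siblings carrying a meaningful
      # share of it (jitter sidebands), not bare noise modes
      main <- max(imfs$powers[cand])
      cand <- cand[imfs$powers[cand] >= 0.1 * main]
      idx <- c(idx, cand)
      orders <- c(orders, rep(k, length(cand)))
    }
  }
  if (length(idx) < 2) {
    return(refused_plan("fewer than 2 usable harmonics", exclusions))
  }
  structure(
    list(refused = FALSE, reason = NULL, fundamental_hz = f0,
         mode_indices = idx, harmonic_orders = orders,
         exclusions = exclusions),
    class = "harmonic_plan"
  )
}

refused_plan <- function(reason, exclusions) {
  structure(
    list(refused = TRUE, reason = reason, fundamental_hz = NA_real_,
         mode_indices = integer(), harmonic_orders = integer(),
         exclusions = exclusions),
    class = "harmonic_plan"
  )
}

#' Reconstruct the cardiac waveform from a harmonic plan
#'
#' Sample-wise sum of the planned modes; deterministic given the IMF set.
#'
#' @param plan A `harmonic_plan` with at least two components.
#' @param imfs The `imf_set` the plan indexes into.
#' @return An object of class `cardiac_waveform`: list with `trace` (mm),
#'   `fundamental` (Hz), `harmonic_orders_used`, `source_mode_indices`,
#'   `hr_spectral` (beats/min), `fs`.
#' @export
reconstruct <- function(plan, imfs) {
  stopifnot(inherits(plan, "harmonic_plan"), inherits(imfs, "imf_set"))
  if (plan$refused || length(plan$mode_indices) < 2) {
    stop("cardiac waveform cannot be reconstructed: ",
         plan$reason %||% "fewer than 2 components", call. = FALSE)
  }
  structure(
    list(trace = rowSums(imfs$modes[, plan$mode_indices, drop = FALSE]),
         fundamental = plan$fundamental_hz,
         harmonic_orders_used = plan$harmonic_orders,
         source_mode_indices = plan$mode_indices,
         hr_spectral = 60 * plan$fundamental_hz,
         fs = imfs$fs),
    class = "cardiac_waveform"
  )
}

#' @export
print.cardiac_waveform <- function(x, ...) {
  cat(sprintf("<cardiac_waveform> fundamental %.3f Hz (%.0f beats/min), harmonics {%s}\n",
              x$fundamental, x$hr_spectral,
              paste(x$harmonic_orders_used, collapse = ",")))
  invisible(x)
}
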