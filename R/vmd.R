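#' Variational mode decomposition
#'
#' Decomposes a series into `K` narrowband intrinsic mode functions (IMFs)
#' with jointly estimated centre frequencies, by the standard alternating
#' (ADMM) scheme: each mode's spectrum is updated as a Wiener-filtered
#' residual around its current centre frequency, the centre frequency moves
#' to the spectral centroid of the mode, and a dual variable enforces (for
#' `tau > 0`) exact reconstruction. The signal is mirror-extended by half its
#' length on each side before decomposition to suppress boundary artifacts
#' and trimmed afterwards. Modes are returned sorted by centre frequency.
#'
#' Defaults follow common practice for this task: `alpha = 2000` (bandwidth
#' penalty), `tau = 0` (no exact enforcement; tolerant to noise),
#' `tol = 1e-7`, at most 500 iterations, and centre frequencies initialized
#' on a uniform grid over the cardiac band (0.8-6 Hz). `K = 10` modes are
#' used so that breathing harmonics leaking through the band edge, cardiac
#' harmonics, and noise each get their own mode.
#'
#' @param trace Numeric series (band-limited upstream; length >= 4 K).
#' @param fs Sampling rate, Hz.
#' @param K Number of modes.
#' @param alpha Bandwidth penalty.
#' @param tau Dual-ascent step (0 disables exact reconstruction).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`.
#' @param init_band Frequency interval (Hz) over which the initial centre
#'   frequencies are spread uniformly.
#' @param reseed_rounds A weak spectral line lying between two stronger
#'   neighbours can be left unclaimed by every mode (its energy stranded in
#'   the residual) because the alternating updates are greedy. After each
#'   convergence, if the residual's strongest in-band line exceeds twice the
#'   weakest mode's spectral peak, that mode is re-seeded onto the residual
#'   line and the updates continue — at most `reseed_rounds` times.
#'   Deterministic; 0 disables.
#' @param merge_tol When the signal holds fewer narrowband components than
#'   `K`, surplus modes converge onto the same centre frequency and split
#'   that component's energy arbitrarily (a degenerate equilibrium of the
#'   alternating scheme). Modes whose final centre frequencies lie within
#'   `merge_tol` Hz of each other are therefore aggregated — their spectra
#'   summed (reconstruction is unchanged), the freed slots kept as zero
#'   modes — so that mode power rankings are well defined. The default
#'   (`NULL`) is a fifth of the mode half-width `fs / sqrt(alpha)`:
#'   components closer than that are unresolvable by construction, while
#'   genuinely distinct neighbouring lines stay separate. `0` disables.
#'
#' @return An object of class `imf_set`: list with `modes` (matrix, samples x
#'   K, ascending centre frequency), `center_frequencies` (Hz), `powers`
#'   (mean-square amplitude per mode), `residual` (input minus mode sum),
#'   `converged`, `n_iter`, `fs`.
#' @export
vmd_decompose <- function(trace, fs, K = 10L, alpha = 2000, tau = 0,
                          tol = 1e-7, max_iter = 500L,
                          init_band = c(0.8, 6), reseed_rounds = 5L,
                          merge_tol = NULL) {
  n <- length(trace)
  stopifnot(n >= 4 * K, fs > 0, K >= 1)
  if (is.null(merge_tol)) merge_tol <- fs / (5 * sqrt(alpha))

  # mirror extension: half the signal reflected onto each side
  half <- floor(n / 2)
  x <- c(rev(trace[seq_len(half)]), trace, rev(trace[(n - half + 1):n]))
  T_len <- length(x)

  # one-sided spectrum; the negative half stays identically zero throughout
  f_hat <- stats::fft(x)
  n_pos <- floor(T_len / 2) + 1L
  f_pos <- f_hat[seq_len(n_pos)]
  freqs <- (seq_len(n_pos) - 1) / T_len            # cycles/sample, [0, 0.5]

  omega <- seq(init_band[1], init_band[2], length.out = K) / fs
  u <- matrix(0 + 0i, n_pos, K)
  lambda <- complex(n_pos)
  sum_uk <- complex(n_pos)
  converged <- FALSE
  iter <- 0L
  eps <- .Machine$double.eps

  in_band <- freqs * fs >= init_band[1] & freqs * fs <= init_band[2]
  round <- 0L
  repeat {
    sum_all <- rowSums(u)
    converged <- FALSE
    iter_round <- 0L
    while (iter_round < max_iter) {
      iter_round <- iter_round + 1L
      iter <- iter + 1L
      u_prev <- u
      for (k in seq_len(K)) {
        sum_uk <- sum_all - u[, k]     # all other modes, freshest iterates
        u[, k] <- (f_pos - sum_uk - lambda / 2) /
          (1 + alpha * (freqs - omega[k])^2)
        sum_all <- sum_uk + u[, k]
        p <- Mod(u[, k])^2
        omega[k] <- sum(freqs * p) / (sum(p) + eps)
      }
      if (tau > 0) lambda <- lambda + tau * (sum_all - f_pos)
      delta <- sum(colSums(Mod(u - u_prev)^2) /
                     (colSums(Mod(u_prev)^2) + eps))
      if (is.finite(delta) && delta < tol) {
        converged <- TRUE
        break
      }
    }
    # greedy updates can strand a weak line between two stronger neighbours:
    # re-seed the weakest mode onto a clearly stronger residual line
    round <- round + 1L
    if (round > reseed_rounds) break
    res_pow <- Mod(f_pos - sum_all)^2
    res_pow[!in_band] <- 0
    # a strong line keeps a residual tail proportional to its own strength
    # even when a mode sits right on it; only residual OUTSIDE every mode's
    # half-width counts as an unclaimed component
    halfwidth <- 1 / sqrt(alpha)
    for (om in omega) res_pow[abs(freqs - om) <= halfwidth] <- 0
    peak_i <- which.max(res_pow)
    mode_peaks <- apply(Mod(u)^2, 2, max)
    weakest <- which.min(mode_peaks)
    if (res_pow[peak_i] > 2 * mode_peaks[weakest]) {
      omega[weakest] <- freqs[peak_i]
      u[, weakest] <- 0 + 0i
    } else break
  }

  # aggregate modes that converged onto the same centre frequency
  if (merge_tol > 0 && K > 1) {
    merged <- merge_degenerate_modes(u, omega, merge_tol / fs)
    u <- merged$u
    omega <- merged$omega
  }

  # back to the time domain: hermitian completion, inverse FFT, trim mirror
  idx <- (half + 1):(half + n)
  modes <- vapply(seq_len(K), function(k) {
    full <- complex(T_len)
    full[seq_len(n_pos)] <- u[, k]
    full[T_len:(n_pos + 1)] <- Conj(u[, k])[2:(T_len - n_pos + 1)]
    Re(stats::fft(full, inverse = TRUE) / T_len)[idx]
  }, numeric(n))

  # reported centre frequency: spectral peak of the mode (parabolic-refined).
  # The ADMM-internal centroid is biased by the Wiener filter's heavy tails
  # overlapping neighbouring components; the peak is robust to that and is
  # what harmonic matching needs.
  cf_hz <- vapply(seq_len(K), function(k) {
    p <- Mod(u[, k])^2
    if (max(p) <= 0) return(omega[k] * fs)
    i <- which.max(p)
    delta <- 0
    if (i > 1 && i < n_pos) {
      den <- p[i - 1] - 2 * p[i] + p[i + 1]
      if (abs(den) > 0) delta <- max(-0.5, min(0.5, 0.5 * (p[i - 1] - p[i + 1]) / den))
    }
    (i - 1 + delta) / T_len * fs
  }, numeric(1))

  ord <- order(cf_hz)
  modes <- modes[, ord, drop = FALSE]
  cf <- cf_hz[ord]
  structure(
    list(modes = modes,
         center_frequencies = cf,
         powers = colMeans(modes^2),
         residual = trace - rowSums(modes),
         converged = converged, n_iter = iter, fs = fs, band = init_band),
    class = "imf_set"
  )
}

# cluster centre frequencies within tol (chained, on the sorted order);
# each cluster's spectra are summed into one slot, the rest become zero
# modes parked at their old centres
merge_degenerate_modes <- function(u, omega, tol) {
  ord <- order(omega)
  cluster <- cumsum(c(1, diff(omega[ord]) > tol))
  for (cl in unique(cluster)) {
    members <- ord[cluster == cl]
    if (length(members) < 2) next
    w <- colSums(Mod(u[, members, drop = FALSE])^2)
    target <- members[which.max(w)]
    u[, target] <- rowSums(u[, members, drop = FALSE])
    omega[target] <- if (sum(w) > 0) sum(omega[members] * w) / sum(w) else
      omega[target]
    u[, setdiff(members, target)] <- 0 + 0i
  }
  list(u = u, omega = omega)
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d modes over %d samples (fs %g Hz)%s\n",
              ncol(x$modes), nrow(x$modes), x$fs,
              if (x$converged) "" else " [not converged]"))
  print(tibble::tibble(mode = seq_along(x$center_frequencies),
                       center_hz = x$center_frequencies,
                       power = x$powers))
  invisible(x)
}

#' Strongest mode outside an exclusion list
#'
#' Returns the index of the highest-power mode whose centre frequency is not
#' within tolerance of any excluded frequency (the breathing-rate multiples).
#' Mode strength is the mean-square amplitude of the time-domain mode.
#'
#' @param imfs An `imf_set`.
#' @param exclude Frequencies to avoid, Hz (typically `k * BR`, k = 1..4).
#' @param tolerance Either a scalar tolerance in Hz or `NULL` to use the
#'   default per-frequency rule `max(0.05 Hz, 3%)` via
#'   [harmonic_tolerance()].
#' @return Mode index, or `NA_integer_` if every mode is excluded (no
#'   cardiac component found).
#' @export
dominant_mode <- function(imfs, exclude = numeric(), tolerance = NULL) {
  stopifnot(inherits(imfs, "imf_set"))
  tol <- if (is.null(tolerance)) harmonic_tolerance(exclude) else
    rep(tolerance, length.out = length(exclude))
  ok <- vapply(imfs$center_frequencies, function(cf) {
    !any(abs(cf - exclude) <= tol)
  }, logical(1))
  if (!any(ok)) return(NA_integer_)
  cand <- which(ok)
  cand[which.max(imfs$powers[cand])]
}

#' Integer-multiple matching tolerance
#'
#' Half-width of the band around a frequency within which another frequency
#' counts as "the same": `max(0.05 Hz, 3%)`.
#'
#' @param f Frequencies, Hz.
#' @return Tolerances, Hz (same length as `f`).
#' @export
harmonic_tolerance <- function(f) pmax(0.05, 0.03 * f)
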