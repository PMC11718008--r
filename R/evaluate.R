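#' Evaluate estimated beats against ground truth
#'
#' Greedy nearest-neighbour matching of estimated valleys to ground-truth
#' valleys within a `match_window` (unmatched true beats count as misses),
#' then error aggregation: per-beat absolute IBI error (estimated IBI minus
#' true IBI for consecutive matched true beats — shift-invariant), HR
#' relative error, and HRV-metric differences computed on the full estimated
#' vs true IBI series.
#'
#' @param valley_times Estimated valley times, s (or a `vitals_report`).
#' @param truth Ground-truth list from [generate_displacement()] (fields
#'   `valley_times`, `ibi_series`, `hr_true`).
#' @param match_window Matching half-window, s.
#' @return A list of class `vitals_evaluation`:
#' * `summary`: one-row tibble (`n_true`, `n_matched`, `n_missed`,
#'   `median_abs_ibi_error_ms`, `max_abs_ibi_error_ms`,
#'   `mean_abs_valley_offset_ms`, `hr_true`, `hr_est`, `hr_rel_error_pct`,
#'   `rmssd_error_ms`, `sdrr_error_ms`, `pnn50_error_pct`);
#' * `ibi_errors`: per-beat absolute IBI errors, ms;
#' * `valley_offsets`: signed matched-valley offsets, ms.
#' @export
evaluate_against_truth <- function(valley_times, truth, match_window = 0.25) {
  if (inherits(valley_times, "vitals_report")) {
    valley_times <- valley_times$valley_times
  }
  tv <- truth$valley_times
  est <- sort(valley_times)
  match <- match_valleys(tv, est, match_window)

  offsets <- (est[match] - tv) * 1000
  ibi_err <- abs(diff(est[match]) - diff(tv)) * 1000
  ibi_err <- ibi_err[!is.na(ibi_err)]

  hrv_err <- c(rmssd = NA_real_, sdrr = NA_real_, pnn50 = NA_real_)
  hr_est <- NA_real_
  if (length(est) >= 4) {
    h_est <- compute_hrv(est)
    h_true <- compute_hrv(tv)
    hr_est <- h_est$hr
    hrv_err <- c(rmssd = abs(h_est$rmssd - h_true$rmssd),
                 sdrr = abs(h_est$sdrr - h_true$sdrr),
                 pnn50 = abs(h_est$pnn50 - h_true$pnn50))
  }
  summary <- tibble::tibble(
    n_true = length(tv),
    n_matched = sum(!is.na(match)),
    n_missed = sum(is.na(match)),
    median_abs_ibi_error_ms = if (length(ibi_err)) stats::median(ibi_err) else NA_real_,
    max_abs_ibi_error_ms = if (length(ibi_err)) max(ibi_err) else NA_real_,
    mean_abs_valley_offset_ms = mean(abs(offsets), na.rm = TRUE),
    hr_true = truth$hr_true,
    hr_est = hr_est,
    hr_rel_error_pct = 100 * abs(hr_est - truth$hr_true) / truth$hr_true,
    rmssd_error_ms = hrv_err[["rmssd"]],
    sdrr_error_ms = hrv_err[["sdrr"]],
    pnn50_error_pct = hrv_err[["pnn50"]]
  )
  structure(list(summary = summary, ibi_errors = ibi_err,
                 valley_offsets = offsets[!is.na(offsets)]),
            class = "vitals_evaluation")
}

# one-to-one greedy matching: for each true valley (in order of increasing
# distance to its nearest estimate) claim the nearest unclaimed estimate
match_valleys <- function(true_times, est_times, window) {
  n <- length(true_times)
  match <- rep(NA_integer_, n)
  if (length(est_times) == 0 || n == 0) return(match)
  taken <- logical(length(est_times))
  ord <- order(vapply(true_times,
                      function(v) min(abs(est_times - v)), numeric(1)))
  for (i in ord) {
    d <- abs(est_times - true_times[i])
    d[taken] <- Inf
    j <- which.min(d)
    if (d[j] <= window) {
      match[i] <- j
      taken[j] <- TRUE
    }
  }
  match
}

#' @export
print.vitals_evaluation <- function(x, ...) {
  cat("<vitals_evaluation>\n")
  print(x$summary)
  invisible(x)
}
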