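#' Write / read a radar cube as portable text
#'
#' Long-format CSV (one row per chirp: `frame`, `chirp`, `s1..sN`) plus a
#' JSON sidecar (`<path>.json`) holding the radar configuration, so a cube
#' round-trips without loss of geometry.
#'
#' @param cube A `radar_cube`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_radar_cube <- function(cube, path) {
  stopifnot(inherits(cube, "radar_cube"))
  d <- dim(cube$samples)
  flat <- matrix(aperm(cube$samples, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- tibble::tibble(
    frame = rep(seq_len(d[1]), each = d[2]),
    chirp = rep(seq_len(d[2]), times = d[1])
  )
  colnames(flat) <- paste0("s", seq_len(d[3]))
  readr::write_csv(dplyr::bind_cols(df, tibble::as_tibble(flat)), path)
  cfg <- cube$config
  cfg_list <- unclass(cfg)
  jsonlite::write_json(cfg_list, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_radar_cube
#' @export
read_radar_cube <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  cfg_list <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- radar_config(
    f_min = cfg_list$f_min, bandwidth = cfg_list$bandwidth,
    slope = cfg_list$slope, sample_rate = cfg_list$sample_rate,
    samples_per_chirp = cfg_list$samples_per_chirp,
    chirps_per_frame = cfg_list$chirps_per_frame,
    prf = cfg_list$prf, idle_time = cfg_list$idle_time, c = cfg_list$c
  )
  n_frames <- max(df$frame)
  n_chirps <- max(df$chirp)
  samp <- as.matrix(df[, grep("^s\\d+$", names(df))])
  cube <- aperm(array(samp, c(n_chirps, n_frames, ncol(samp))), c(2, 1, 3))
  structure(list(samples = cube, config = config,
                 timestamps = (seq_len(n_frames) - 1) / config$prf),
            class = "radar_cube")
}

#' Write / read per-bin displacement traces as CSV
#'
#' Columns `time_s`, `bin<k>_mm`.
#'
#' @param disp A `bin_displacement` tibble.
#' @param path CSV path.
#' @param prf Frame rate to attach on read (inferred from `time_s` when
#'   omitted).
#' @return `path` invisibly / the `bin_displacement` tibble.
#' @export
write_displacement_csv <- function(disp, path) {
  readr::write_csv(tibble::as_tibble(disp), path)
  invisible(path)
}

#' @rdname write_displacement_csv
#' @export
read_displacement_csv <- function(path, prf = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(prf)) prf <- 1 / stats::median(diff(out$time_s))
  attr(out, "prf") <- prf
  attr(out, "bin_ids") <- as.integer(sub("^bin(\\d+)_mm$", "\\1",
                                         grep("^bin\\d+_mm$", names(out),
                                              value = TRUE)))
  class(out) <- c("bin_displacement", class(out))
  out
}

#' Serialize a vitals report to JSON
#'
#' Fixed key order and full-precision numbers, so identical inputs give
#' byte-identical files.
#'
#' @param report A `vitals_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals_json <- function(report, path) {
  stopifnot(inherits(report, "vitals_report"))
  out <- list(
    status = report$status,
    br_breaths_per_min = report$br,
    hr_beats_per_min = report$hr,
    rmssd_ms = report$rmssd,
    sdrr_ms = report$sdrr,
    pnn50_pct = report$pnn50,
    morphology = report$morphology,
    flags = report$flags,
    surviving_bins = report$surviving_bins,
    valley_times_s = report$valley_times,
    ibi_series_ms = report$ibi_series,
    per_bin = report$per_bin
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected; every bound is re-validated through
#' the constructors on load.
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` invisibly / a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$radar <- unclass(lst$radar)[c("f_min", "bandwidth", "slope",
                                    "sample_rate", "samples_per_chirp",
                                    "chirps_per_frame", "prf", "idle_time", "c")]
  lst$motion <- unclass(lst$motion)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c("radar", "motion", "bins", "breathing_band", "cardiac_band",
             "vmd_k", "vmd_alpha", "vmd_tau", "vmd_tol", "vmd_max_iter",
             "use_vmd", "multi_bin", "fusion_window", "beat_correction",
             "wideband_refine",
             "movement_guard", "edge_guard", "sqi_floor", "welch_window",
             "breath_hold_floor")
  extra <- setdiff(names(lst), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  radar <- do.call(radar_config, lst$radar %||% list())
  motion <- do.call(motion_config, lst$motion %||% list())
  args <- lst[setdiff(names(lst), c("radar", "motion"))]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipeline_config, c(list(radar = radar, motion = motion), args))
}
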