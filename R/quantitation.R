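#' Fit a through-origin calibration curve
#'
#' Calibration responses are regressed through the origin on the standard
#' concentrations (the calibration is parameterised by slope alone).  The
#' fit must reach a linear correlation coefficient R^2 >= 0.999; while it
#' does not, the highest concentration level is dropped and the fit
#' repeated, provided at least `min_points` levels remain.  The retained
#' concentration range becomes the linear range.
#'
#' @param points Data frame with columns `concentration` (mg/L, > 0) and
#'   `response` (area units, >= 0); optionally `snr`.
#' @param r2_min Minimum acceptable R^2 (default 0.999).
#' @param min_points Minimum retained levels (default 5; 7 levels are the
#'   usual design).
#' @return A `calibration_curve` list: `slope`, `r_squared`, `range_low`,
#'   `range_high`, `n_points`, `dropped` (concentrations removed).
#' @export
fit_calibration <- function(points, r2_min = 0.999, min_points = 5L) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "response") %in% names(points)))
  pts <- points[order(points$concentration), ]
  if (anyDuplicated(pts$concentration))
    stop("calibration levels must have distinct concentrations")
  if (any(pts$concentration <= 0)) stop("concentrations must be positive")
  if (any(pts$response < 0)) stop("responses must be non-negative")
  if (nrow(pts) < min_points)
    stop("at least ", min_points, " calibration points are required")
  dropped <- numeric(0)
  repeat {
    fit <- through_origin_fit(pts$concentration, pts$response)
    if (fit$r_squared >= r2_min) break
    if (nrow(pts) <= min_points)
      stop(sprintf(paste0("calibration failure: R^2 = %.6f < %.4f with the ",
                          "minimum %d levels retained"),
                   fit$r_squared, r2_min, min_points))
    dropped <- c(dropped, pts$concentration[nrow(pts)])
    pts <- pts[-nrow(pts), ]
  }
  structure(list(slope = fit$slope, r_squared = fit$r_squared,
                 range_low = min(pts$concentration),
                 range_high = max(pts$concentration),
                 n_points = nrow(pts), dropped = dropped),
            class = "calibration_curve")
}

# Through-origin least squares with R^2 measured against the mean (the
# conventional linearity statistic reported with calibration lines).
through_origin_fit <- function(x, y) {
  if (all(y == 0)) stop("calibration failure: all responses are zero")
  slope <- sum(x * y) / sum(x * x)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, r_squared = r2)
}

#' LOD and LOQ from baseline noise
#'
#' Limits of detection and quantitation at signal-to-noise ratios of 3 and
#' 10: `lod = 3 * noise_sd / slope`, `loq = 10 * noise_sd / slope`.
#'
#' @param noise_sd Baseline noise standard deviation (response units).
#' @param slope Calibration slope (response units per mg/L), > 0.
#' @return List with `lod` and `loq` in mg/L.
#' @export
estimate_lod_loq <- function(noise_sd, slope) {
  if (slope <= 0) stop("slope must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  list(lod = 3 * noise_sd / slope, loq = 10 * noise_sd / slope)
}

#' Quantify a peak area against a catalog record
#'
#' Converts a peak area on the record's quantitation channel into a
#' concentration.  The area is first corrected multiplicatively by the
#' internal-standard drift ratio (nominal/observed psoralen response),
#' divided by the calibration slope to give the concentration in the
#' SPE-concentrated extract, then divided by the concentration factor
#' (default 9, the 9-fold enrichment of the extraction) to give the
#' concentration in the original juice.  Flags mark results below the LOD
#' or LOQ or above the calibrated range (all referred to the concentrate).
#'
#' @param area Peak area (response units) on the quantitation channel.
#' @param record One catalog row carrying a calibration for its
#'   quantitation channel.
#' @param is_ratio Internal-standard correction ratio
#'   (nominal/observed), > 0; 1 means no drift.
#' @param concentration_factor Extract enrichment factor (default 9).
#' @return A `quant_result` list: `compound_id`, `concentration` (mg/L in
#'   juice), `concentrate_concentration` (mg/L in the measured extract)
#'   and `flags` (character subset of `below_LOD`, `below_LOQ`,
#'   `above_range`).
#' @export
quantify_peak <- function(area, record, is_ratio = 1, concentration_factor = 9) {
  if (is_ratio <= 0) stop("is_ratio must be positive")
  if (area < 0) stop("area must be non-negative")
  ch <- quant_channel_for(record)
  side <- if (ch$detector == "UV") "uv" else "fl"
  slope <- record[[paste0(side, "_slope")]]
  if (is.na(slope))
    stop(sprintf(paste0("compound %s has no %s calibration; report its ",
                        "response peak area instead"),
                 record$id, ch$detector))
  conc_extract <- area / slope * is_ratio
  flags <- character(0)
  lod <- record[[paste0(side, "_lod")]]
  loq <- record[[paste0(side, "_loq")]]
  hi <- record[[paste0(side, "_range_high")]]
  if (!is.na(lod) && conc_extract < lod) flags <- c(flags, "below_LOD")
  if (!is.na(loq) && conc_extract < loq) flags <- c(flags, "below_LOQ")
  if (!is.na(hi) && conc_extract > hi) flags <- c(flags, "above_range")
  structure(list(compound_id = record$id,
                 concentration = conc_extract / concentration_factor,
                 concentrate_concentration = conc_extract,
                 flags = flags),
            class = "quant_result")
}

#' Surrogate recovery and precision report
#'
#' Summarises replicate determinations of a spiked analyte surrogate
#' (coumarin, xanthotoxin or gardenin A at 5 mg/L) over several days:
#' recovery is the grand mean over the spike level, intraday precision the
#' mean of the per-day relative standard deviations, interday precision
#' the RSD of the day means.
#'
#' @param surrogate Surrogate name.
#' @param spiked Spiked concentration (mg/L), > 0.
#' @param replicate_measurements List of numeric vectors, one per day,
#'   each with >= 2 replicate concentrations (mg/L); >= 2 days.
#' @return A `recovery_report` list: `surrogate`, `spiked`,
#'   `measured_mean`, `recovery` (percent), `intraday_rsd`, `interday_rsd`
#'   (percent).
#' @export
recovery_report <- function(surrogate, spiked, replicate_measurements) {
  if (spiked <= 0) stop("spiked concentration must be positive")
  if (!is.list(replicate_measurements) || length(replicate_measurements) < 2L)
    stop("at least two days of replicates are required")
  if (any(vapply(replicate_measurements, length, integer(1)) < 2L))
    stop("each day needs at least two replicates")
  day_means <- vapply(replicate_measurements, mean, numeric(1))
  day_rsd <- vapply(replicate_measurements, function(x) {
    m <- mean(x); if (m == 0) 0 else 100 * stats::sd(x) / m
  }, numeric(1))
  grand <- mean(unlist(replicate_measurements))
  inter <- if (mean(day_means) == 0) 0 else
    100 * stats::sd(day_means) / mean(day_means)
  structure(list(surrogate = surrogate, spiked = spiked,
                 measured_mean = grand, recovery = 100 * grand / spiked,
                 intraday_rsd = mean(day_rsd), interday_rsd = inter),
            class = "recovery_report")
}
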