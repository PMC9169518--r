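#' Chromatogram peak
#'
#' A detected peak with its retention time, per-channel responses and
#' (optionally) full UV and emission spectra.  Channels are named by
#' detector and wavelength: UV areas/heights at 250, 270 and 330 nm
#' (`"uv250"`, `"uv270"`, `"uv330"`) and fluorescence emission heights at
#' 400, 450 and 500 nm (`"fl400"`, `"fl450"`, `"fl500"`).
#'
#' @param rt Retention time (minutes), > 0.
#' @param areas Named numeric vector of peak areas per channel.
#' @param heights Named numeric vector of peak heights per channel.
#' @param uv_spectrum Optional [spectrum_trace()] on the UV axis.
#' @param em_spectrum Optional [spectrum_trace()] on the emission axis, or
#'   `NULL` for non-fluorescing peaks.
#' @return A `chromatogram_peak` object.
#' @export
chromatogram_peak <- function(rt, areas = numeric(), heights = numeric(),
                              uv_spectrum = NULL, em_spectrum = NULL) {
  rt <- as.numeric(rt)
  if (length(rt) != 1L || is.na(rt) || rt <= 0) stop("rt must be a positive scalar")
  if (any(areas < 0, na.rm = TRUE) || any(heights < 0, na.rm = TRUE))
    stop("areas and heights must be non-negative")
  if (!is.null(uv_spectrum)) stopifnot(uv_spectrum$axis == "UV")
  if (!is.null(em_spectrum)) stopifnot(em_spectrum$axis == "emission")
  structure(list(rt = rt, areas = areas, heights = heights,
                 uv_spectrum = uv_spectrum, em_spectrum = em_spectrum),
            class = "chromatogram_peak")
}

#' Fluorescence peak-height ratio
#'
#' The numeric fluorescence fingerprint of a peak: the ratio of the highest
#' to the second-highest emission response among the monitored channels
#' (400, 450, 500 nm).  Ties are broken toward the shorter wavelength.
#'
#' @param heights Named numeric vector, names are wavelengths in nm (or
#'   `"fl<nm>"` channel names); at least two channels.
#' @return List with `high` (nm of the highest channel), `second` (nm of
#'   the runner-up) and `ratio` (>= 1).
#' @export
fl_peak_ratio <- function(heights) {
  nm <- as.numeric(sub("^fl", "", names(heights)))
  if (anyNA(nm)) stop("height names must be wavelengths (e.g. '450' or 'fl450')")
  h <- as.numeric(heights)
  keep <- !is.na(h)
  nm <- nm[keep]; h <- h[keep]
  if (length(h) < 2L) stop("at least two monitored wavelengths are required")
  if (all(h <= 0)) stop("all fluorescence heights are zero: non-fluorescing peak")
  o <- order(-h, nm)                      # ties toward shorter wavelength
  list(high = nm[o[1]], second = nm[o[2]], ratio = h[o[1]] / h[o[2]])
}

#' Identification gates
#'
#' Thresholds applied when matching a sample peak against the catalog.
#' The defaults require near-identical full spectra (UV conformity >=
#' 0.99, emission conformity >= 0.98 when both peak and standard
#' fluoresce), a retention-index window of +/- 15 index units, and a
#' fluorescence peak-height ratio within 25 percent (relative) of the
#' standard's.
#'
#' @param uv_conformity_min,em_conformity_min Minimum spectral conformity.
#' @param ri_delta_max Maximum absolute retention-index difference.
#' @param ratio_rel_tol Maximum relative deviation of the fluorescence
#'   peak-height ratio.
#' @return A `match_gates` list.
#' @export
match_gates <- function(uv_conformity_min = 0.99, em_conformity_min = 0.98,
                        ri_delta_max = 15, ratio_rel_tol = 0.25) {
  structure(list(uv_conformity_min = uv_conformity_min,
                 em_conformity_min = em_conformity_min,
                 ri_delta_max = ri_delta_max,
                 ratio_rel_tol = ratio_rel_tol),
            class = "match_gates")
}

record_passes_gates <- function(peak, rec, peak_ri, gates, scores_out = FALSE) {
  scores <- list(uv_conformity = NA_real_, em_conformity = NA_real_,
                 ri_delta = NA_real_, ratio_delta = NA_real_)
  pass <- TRUE
  # UV full-spectrum conformity
  if (!is.null(peak$uv_spectrum)) {
    ref_uv <- uv_spectrum_from_maxima(rec$uv_maxima[[1]], rec$family)
    scores$uv_conformity <- spectrum_conformity(peak$uv_spectrum, ref_uv)
    pass <- pass && scores$uv_conformity >= gates$uv_conformity_min
  }
  # fluorescence presence must agree; emission conformity when both fluoresce
  peak_fluoresces <- !is.null(peak$em_spectrum) ||
    any(peak$heights[grepl("^fl", names(peak$heights))] > 0, na.rm = TRUE)
  if (xor(peak_fluoresces, isTRUE(rec$fluoresces))) pass <- FALSE
  if (pass && !is.null(peak$em_spectrum) && isTRUE(rec$fluoresces)) {
    ref_em <- emission_spectrum_from_max(rec$emission_max)
    scores$em_conformity <- spectrum_conformity(peak$em_spectrum, ref_em)
    pass <- pass && scores$em_conformity >= gates$em_conformity_min
  }
  # retention index (skipped when either side has none, e.g. pre-C8 elution)
  if (!is.na(peak_ri) && !is.na(rec$ri)) {
    scores$ri_delta <- peak_ri - rec$ri
    pass <- pass && abs(scores$ri_delta) <= gates$ri_delta_max
  }
  # fluorescence peak-height ratio fingerprint
  fl_h <- peak$heights[grepl("^fl", names(peak$heights))]
  if (pass && length(fl_h) >= 2 && any(fl_h > 0, na.rm = TRUE) &&
      isTRUE(rec$fluoresces) && !is.na(rec$fl_ratio)) {
    pr <- fl_peak_ratio(fl_h)
    scores$ratio_delta <- abs(pr$ratio - rec$fl_ratio) / rec$fl_ratio
    pass <- pass && pr$high == rec$fl_monitor_high &&
      pr$second == rec$fl_monitor_second &&
      scores$ratio_delta <= gates$ratio_rel_tol
  }
  if (scores_out) list(pass = pass, scores = scores) else pass
}

#' Identify a chromatogram peak against the catalog
#'
#' Applies the three-pronged identification: full-spectrum conformity (UV,
#' and emission when both peak and standard fluoresce), the fluorescence
#' peak-height ratio fingerprint, and the retention-index window.  A match
#' is reported only when exactly one catalog record passes every
#' applicable gate; zero or multiple passing records yield no match (an
#' ambiguous identification is never resolved to the best candidate, to
#' avoid feeding a doubtful identity into the authenticity models).
#'
#' @param peak A [chromatogram_peak()].
#' @param catalog An `oha_catalog` from [load_catalog()].
#' @param anchors An [anchor_series()] for retention-index computation.
#' @param gates A [match_gates()] object.
#' @return List with `matched_id` (compound id or `NA`), `ambiguous`
#'   (logical), `candidates` (ids passing all gates), `scores` (gate
#'   scores against the matched record, when unique), and `deduced_class`
#'   (spectral substitution class from [classify_spectrum()], computed for
#'   unmatched peaks with a UV spectrum).
#' @export
identify_peak <- function(peak, catalog, anchors, gates = match_gates()) {
  stopifnot(inherits(peak, "chromatogram_peak"))
  peak_ri <- compute_retention_index(peak$rt, anchors)
  passing <- character(0); scores <- NULL
  for (i in seq_len(nrow(catalog))) {
    res <- record_passes_gates(peak, catalog[i, ], peak_ri, gates, scores_out = TRUE)
    if (res$pass) {
      passing <- c(passing, catalog$id[i])
      scores <- res$scores
    }
  }
  matched <- if (length(passing) == 1L) passing else NA_character_
  deduced <- NA_character_
  if (is.na(matched) && !is.null(peak$uv_spectrum)) {
    uv_max <- spectrum_maxima(peak$uv_spectrum)
    em_max <- if (!is.null(peak$em_spectrum))
      peak$em_spectrum$wavelengths[which.max(peak$em_spectrum$intensities)]
    else NA_real_
    deduced <- classify_spectrum(uv_max, em_max)
  }
  list(matched_id = matched,
       ambiguous = length(passing) > 1L,
       candidates = passing,
       ri = peak_ri,
       scores = if (!is.na(matched)) scores else NULL,
       deduced_class = deduced)
}

#' Local maxima of a spectrum trace
#'
#' Detects band maxima (local peaks above a relative intensity floor) in a
#' spectrum; used to feed measured spectra into [classify_spectrum()].
#'
#' @param trace A [spectrum_trace()].
#' @param min_rel Minimum intensity relative to the global maximum for a
#'   band to count.
#' @return Wavelengths (nm) of the detected maxima, ascending.
#' @export
spectrum_maxima <- function(trace, min_rel = 0.15) {
  y <- trace$intensities; w <- trace$wavelengths
  n <- length(y)
  if (n < 3) return(w[which.max(y)])
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  out <- w[is_max & y >= min_rel * max(y)]
  sort(out)
}
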