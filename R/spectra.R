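#' Spectrum traces
#'
#' A `spectrum_trace` is a max-normalised detector spectrum on a strictly
#' increasing wavelength grid.  Two axes exist: `"UV"` (diode-array
#' absorbance, 210--400 nm) and `"emission"` (fluorescence emission under
#' 340 nm excitation, 340--560 nm).
#'
#' @param axis `"UV"` or `"emission"`.
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm),
#'   within the axis scan window.
#' @param intensities Non-negative intensities, same length as `wavelengths`.
#'   They are rescaled so the maximum is exactly 1.
#' @return An object of class `spectrum_trace` with elements `axis`,
#'   `wavelengths`, `intensities`.
#' @export
spectrum_trace <- function(axis = c("UV", "emission"), wavelengths, intensities) {
  axis <- match.arg(axis)
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (length(wavelengths) == 0L)
    stop("empty spectrum")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  win <- axis_window(axis)
  if (min(wavelengths) < win[1] || max(wavelengths) > win[2])
    stop(sprintf("%s wavelengths must lie within [%g, %g] nm", axis, win[1], win[2]))
  mx <- max(intensities)
  if (mx > 0) intensities <- intensities / mx
  structure(list(axis = axis, wavelengths = wavelengths, intensities = intensities),
            class = "spectrum_trace")
}

axis_window <- function(axis) {
  switch(axis, UV = c(210, 400), emission = c(340, 560),
         stop("unknown spectral axis: ", axis))
}

#' @export
print.spectrum_trace <- function(x, ...) {
  cat(sprintf("<spectrum_trace: %s, %d points, %g-%g nm, max at %g nm>\n",
              x$axis, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$wavelengths[which.max(x$intensities)]))
  invisible(x)
}

# Band-role amplitudes used when reconstructing a library spectrum from its
# listed absorbance maxima.  Furanocoumarins carry a dominant shoulder band
# (240-280 nm) and a weaker main band near 310 nm; coumarins and
# methoxyflavones peak at their longest-wavelength band.
uv_band_amplitude <- function(lambda, family) {
  if (family == "FC") {
    if (lambda < 240) 0.70
    else if (lambda < 280) 1.00
    else if (lambda < 305) 0.50
    else 0.45
  } else {
    if (lambda < 240) 0.80
    else if (lambda < 280) if (family == "MF") 0.60 else 0.35
    else if (lambda < 312) 0.55
    else 1.00
  }
}

#' Model a UV absorbance spectrum from listed band maxima
#'
#' Reconstructs a smooth, max-normalised absorbance trace as a sum of
#' Gaussian bands centred at the catalogued absorbance maxima.  Band
#' amplitudes follow the family-specific pattern seen across the three OHA
#' families (furanocoumarins show a dominant shoulder near 250/270 nm and a
#' smaller main band near 310 nm; coumarins and methoxyflavones peak at
#' their longest-wavelength band).  This parametric stand-in is used for
#' library/reference spectra and by the chromatogram simulator; measured
#' spectra can be supplied wherever a `spectrum_trace` is accepted.
#'
#' @param maxima Ascending absorbance maxima (nm) within 210--400.
#' @param family `"MF"`, `"coumarin"` or `"FC"`.
#' @param grid Wavelength grid; default 1-nm from 210 to 400.
#' @return A `spectrum_trace` on the UV axis.
#' @export
uv_spectrum_from_maxima <- function(maxima, family = c("coumarin", "FC", "MF"),
                                    grid = 210:400) {
  family <- match.arg(family)
  maxima <- sort(as.numeric(maxima))
  if (length(maxima) == 0L) stop("empty maxima")
  y <- rep(0, length(grid))
  for (lambda in maxima) {
    amp <- uv_band_amplitude(lambda, family)
    sigma <- if (lambda < 280) 9 else 13
    y <- y + amp * exp(-(grid - lambda)^2 / (2 * sigma^2))
  }
  spectrum_trace("UV", grid, y)
}

#' Model a fluorescence emission spectrum from its maximum
#'
#' Emission bands are modelled as asymmetric Gaussians (narrower on the
#' blue side, tailing to the red), the typical shape of coumarin and
#' furanocoumarin emission under 340 nm excitation.
#'
#' @param emission_max Emission maximum (nm) within 340--560.
#' @param sigma_blue,sigma_red Band half-widths (nm) below/above the maximum.
#' @param grid Wavelength grid; default 1-nm from 340 to 560.
#' @return A `spectrum_trace` on the emission axis.
#' @export
emission_spectrum_from_max <- function(emission_max, sigma_blue = 20,
                                       sigma_red = 32, grid = 340:560) {
  if (is.na(emission_max)) stop("emission_max is NA")
  sigma <- ifelse(grid <= emission_max, sigma_blue, sigma_red)
  y <- exp(-(grid - emission_max)^2 / (2 * sigma^2))
  spectrum_trace("emission", grid, y)
}

#' Spectral conformity between a sample peak and a standard
#'
#' The conforming degree of two spectra on the same axis: both are linearly
#' resampled to the common 1-nm grid of their overlapping wavelength
#' support, max-normalised, and scored by Pearson correlation, clipped to
#' \[0, 1\].  1 means shape-identical spectra; values near 0 mean unrelated
#' or anti-correlated shapes.
#'
#' @param sample,reference `spectrum_trace` objects on the same axis.
#' @return Conformity score in \[0, 1\].
#' @export
spectrum_conformity <- function(sample, reference) {
  stopifnot(inherits(sample, "spectrum_trace"), inherits(reference, "spectrum_trace"))
  if (sample$axis != reference$axis)
    stop("spectra are on different axes: ", sample$axis, " vs ", reference$axis)
  lo <- max(min(sample$wavelengths), min(reference$wavelengths))
  hi <- min(max(sample$wavelengths), max(reference$wavelengths))
  if (hi <= lo) stop("disjoint wavelength supports")
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  if (length(grid) < 3L) stop("overlapping support too narrow to score")
  a <- stats::approx(sample$wavelengths, sample$intensities, xout = grid)$y
  b <- stats::approx(reference$wavelengths, reference$intensities, xout = grid)$y
  a <- a / max(a); b <- b / max(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("flat spectrum on common support; conformity undefined")
  r <- stats::cor(a, b)
  min(max(r, 0), 1)
}

#' Assign an OHA substitution class from spectral maxima
#'
#' Encodes the empirical spectra-to-structure screening rules that relate
#' UV band positions and the fluorescence emission maximum to the
#' substitution pattern of the three OHA families.  Landmarks (all with a
#' +/- 7 nm acceptance window unless noted):
#'
#' * Furanocoumarins carry a strong shoulder near 250 nm (mono-substituted)
#'   or 270 nm (5,8-disubstituted) together with a main band in 305--320
#'   nm.  A main band near 310 nm indicates 5-OR; below 305 nm, 8-OR; a
#'   270-shoulder indicates 5,8-diOR.  Absent emission with an FC-shaped
#'   UV spectrum indicates 5-OH (hydroxylation at C5 quenches emission).
#' * Coumarins are read from the longest-wavelength UV band and the
#'   emission maximum: main about 323 nm with emission about 395 nm means
#'   7-OR (with an extra 256 nm shoulder: 7-OR,8-R); main at or beyond 336
#'   nm with emission near 460 nm means 6-OR,7-OH; main at or beyond 336 nm
#'   with emission near 422 nm means 6,7-diOR; main about 330 nm with
#'   red-shifted emission (>= 450 nm) means 5-OR,7-OH, unless a double
#'   shoulder below 263 nm indicates 5,7-diOR; main about 323 nm with
#'   emission near 437 nm also means 5,7-diOR.
#' * Methoxyflavones show one (4'-OMe) or two (3',4'-diOMe) shoulder bands
#'   in 240--280 nm beside a main band above 320 nm; a red-shifted main
#'   band without emission indicates additional 5-OH.
#'
#' Spectra matching no rule are reported as `"uncategorized C"` or
#' `"uncategorized FC"`.
#'
#' @param uv_maxima Ascending UV absorbance maxima (nm).
#' @param emission_max Emission maximum (nm) or `NA` for non-fluorescing
#'   peaks.
#' @param window Half-width (nm) of the landmark acceptance windows.
#' @return A substitution-class label (character scalar).
#' @export
classify_spectrum <- function(uv_maxima, emission_max = NA, window = 7) {
  uv_maxima <- sort(as.numeric(uv_maxima))
  if (length(uv_maxima) == 0L) stop("empty uv_maxima")
  emission_max <- as.numeric(emission_max)
  near <- function(x, landmark) abs(x - landmark) <= window
  has_band <- function(lo, hi) any(uv_maxima >= lo & uv_maxima <= hi)

  fc_main <- uv_maxima[uv_maxima >= 305 & uv_maxima <= 320]
  fc_shoulder_250 <- has_band(250 - window, 250 + window)
  fc_shoulder_270 <- has_band(270 - window, 270 + window)
  if (length(fc_main) > 0 && (fc_shoulder_250 || fc_shoulder_270)) {
    # furanocoumarin shape: shoulder + main band in 305-320 nm
    if (fc_shoulder_270) return("5,8-diOR FC")
    main <- fc_main[which.max(fc_main)]
    if (is.na(emission_max)) return("5-OH FC")
    if (near(main, 310)) return("5-OR FC")
    return("uncategorized FC")
  }
  # 8-OR FCs have their main band slightly below 305 nm
  fc_main_short <- uv_maxima[uv_maxima >= 296 & uv_maxima < 305]
  if (length(fc_main_short) > 0 && fc_shoulder_250 && !has_band(313, 400) &&
      (is.na(emission_max) || emission_max >= 460)) {
    return(if (is.na(emission_max)) "5-OH FC" else "8-OR FC")
  }

  main <- max(uv_maxima)
  shoulders <- uv_maxima[uv_maxima >= 240 & uv_maxima < 280]
  double_shoulder <- sum(uv_maxima >= 245 & uv_maxima < 263) >= 2
  mf_main <- main >= 332 & main <= 355
  if (mf_main && length(shoulders) > 0 && is.na(emission_max) &&
      main > 343) {
    return("5-OH MF")
  }

  # coumarin rules on the longest-wavelength band + emission maximum
  if (!is.na(emission_max)) {
    if (main >= 336 && near(emission_max, 422)) return("6,7-diOR C")
    if (main >= 336 && near(emission_max, 461)) return("6-OR,7-OH C")
    if (double_shoulder && main >= 323 && main <= 335 &&
        emission_max >= 430 && emission_max < 470) return("5,7-diOR C")
    if (main >= 327 && main <= 335 && emission_max >= 450) return("5-OR,7-OH C")
    if (main >= 320 && main <= 326 && near(emission_max, 461)) return("7-OH C")
    if (abs(main - 323) <= 4 && near(emission_max, 395)) {
      if (has_band(249, 263)) return("7-OR,8-R C")
      return("7-OR C")
    }
  }

  # methoxyflavone shapes (double vs single 240-280 nm shoulder)
  if (mf_main && length(shoulders) >= 2) return("3',4'-diOMe MF")
  if (mf_main && length(shoulders) == 1 &&
      (is.na(emission_max) || emission_max < 450)) return("4'-OMe MF")

  if (length(fc_main) > 0 || length(fc_main_short) > 0) return("uncategorized FC")
  "uncategorized C"
}
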