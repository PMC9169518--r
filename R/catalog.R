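#' @title Compound catalog
#' @description Readers, writers and accessors for the OHA reference
#'   library: 39 quantified compounds (methoxyflavones, coumarins,
#'   furanocoumarins) plus 13 tentatively screened candidates labelled with
#'   roman numerals.  Each record carries spectral maxima, fluorescence
#'   monitoring metadata, retention data and (for the knowns) UV and/or
#'   fluorescence calibration parameters.
#' @name catalog
NULL

catalog_columns <- c(
  "id", "name", "family", "substitution_class", "uv_maxima", "emission_max",
  "fl_monitor_high", "fl_monitor_second", "fl_ratio", "rt_min", "ri",
  "quant_detector", "quant_wavelength",
  "uv_slope", "uv_r2", "uv_range_low", "uv_range_high", "uv_lod", "uv_loq",
  "cf_uv",
  "fl_slope", "fl_r2", "fl_range_low", "fl_range_high", "fl_lod", "fl_loq",
  "cf_fl")

#' Load a compound catalog
#'
#' Reads a catalog CSV (see `catalog_columns` in the package source for
#' the schema) and validates every record: families must be `MF`,
#' `coumarin` or `FC`; UV maxima must lie within 210--400 nm and emission
#' maxima within 340--560 nm; fluorescence peak-height ratios must be
#' >= 1; non-fluorescing compounds must not carry a fluorescence
#' calibration; calibrations must have R^2 >= 0.999 and LOD < LOQ.
#'
#' @param path Path to a catalog CSV.  Default: the catalog packaged with
#'   citrusOHA.
#' @return An `oha_catalog` data frame, one row per compound, with
#'   `uv_maxima` parsed into a list-column of numeric vectors and a
#'   logical `fluoresces` column derived from `emission_max`.
#' @export
load_catalog <- function(path = system.file("extdata", "oha_catalog.csv",
                                            package = "citrusOHA")) {
  if (!nzchar(path) || !file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (nrow(df) == 0L) stop("catalog load error: file has no compound rows")
  missing_cols <- setdiff(catalog_columns, names(df))
  if (length(missing_cols) > 0)
    stop("catalog load error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, catalog_columns]
  df$uv_maxima <- lapply(strsplit(df$uv_maxima, ";", fixed = TRUE),
                         function(v) sort(as.numeric(v)))
  df$fluoresces <- !is.na(df$emission_max)
  for (i in seq_len(nrow(df))) validate_record(df[i, ], i)
  if (anyDuplicated(df$id))
    stop("catalog load error: duplicate compound id ",
         df$id[anyDuplicated(df$id)])
  structure(df, class = c("oha_catalog", "data.frame"))
}

validate_record <- function(rec, row) {
  fail <- function(field, why)
    stop(sprintf("catalog load error: row %d (id %s), field %s: %s",
                 row, rec$id, field, why))
  if (!rec$family %in% c("MF", "coumarin", "FC"))
    fail("family", paste0("unknown family '", rec$family, "'"))
  uv <- rec$uv_maxima[[1]]
  if (length(uv) == 0 || any(is.na(uv))) fail("uv_maxima", "empty or non-numeric")
  if (any(uv < 210 | uv > 400)) fail("uv_maxima", "outside 210-400 nm")
  if (!is.na(rec$emission_max) && (rec$emission_max < 340 || rec$emission_max > 560))
    fail("emission_max", "outside 340-560 nm")
  if (!rec$fluoresces) {
    if (!is.na(rec$fl_slope)) fail("fl_slope", "fluorescence calibration on a non-fluorescing compound")
    if (!is.na(rec$fl_ratio)) fail("fl_ratio", "ratio on a non-fluorescing compound")
  } else if (!is.na(rec$fl_ratio)) {
    if (rec$fl_ratio < 1) fail("fl_ratio", "must be >= 1 (highest over second-highest)")
    if (!rec$fl_monitor_high %in% c(400, 450, 500) ||
        !rec$fl_monitor_second %in% c(400, 450, 500))
      fail("fl_monitor_high", "monitored wavelengths must be 400/450/500 nm")
  }
  if (is.na(rec$rt_min) || rec$rt_min <= 0) fail("rt_min", "must be positive")
  for (side in c("uv", "fl")) {
    slope <- rec[[paste0(side, "_slope")]]
    if (is.na(slope)) next
    r2 <- rec[[paste0(side, "_r2")]]
    lod <- rec[[paste0(side, "_lod")]]; loq <- rec[[paste0(side, "_loq")]]
    if (slope <= 0) fail(paste0(side, "_slope"), "must be positive")
    # catalogued R^2 values are printed to 3-4 decimals; accept anything
    # that rounds to >= 0.999 (fit_calibration enforces 0.999 exactly)
    if (is.na(r2) || round(r2, 3) < 0.999)
      fail(paste0(side, "_r2"), "calibration requires R^2 >= 0.999")
    if (!is.na(lod) && !is.na(loq) && lod >= loq)
      fail(paste0(side, "_lod"), "LOD must be smaller than LOQ")
  }
  if (!is.na(rec$quant_detector) &&
      !rec$quant_detector %in% c("UV", "FL"))
    fail("quant_detector", "must be UV or FL")
  invisible(TRUE)
}

#' Write a compound catalog
#'
#' Serialises an `oha_catalog` back to the CSV schema read by
#' [load_catalog()].  Numbers are written with up to 15 significant digits
#' and missing values as `NA`, so a load/write cycle round-trips the
#' packaged catalog byte-identically.
#'
#' @param catalog An `oha_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)[, c(catalog_columns[1:4], "uv_maxima",
                                   catalog_columns[6:27])]
  df$uv_maxima <- vapply(catalog$uv_maxima, function(v)
    paste(format_num(v), collapse = ";"), character(1))
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]] <- format_num(df[[col]])
  # names and class labels legitimately contain commas; quote text fields
  text_cols <- which(names(df) %in% c("id", "name", "family",
                                      "substitution_class", "uv_maxima",
                                      "quant_detector"))
  utils::write.csv(df, path, row.names = FALSE, quote = text_cols, na = "NA")
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE,
                                            trim = TRUE)
  }, character(1))
  out
}

#' Quantitation channel for a compound
#'
#' Default detection rule: methoxyflavones and coumarins are quantified by
#' UV at 330 nm, mono-substituted (5- or 8-OR) furanocoumarins at 250 nm,
#' and 5,8-disubstituted furanocoumarins at 270 nm.  A per-compound
#' `quant_detector`/`quant_wavelength` entry in the catalog overrides the
#' rule (a few compounds are better served by a fluorescence channel).
#'
#' @param record One catalog row.
#' @return List with elements `detector` (`"UV"` or `"FL"`) and
#'   `wavelength` (nm).
#' @export
quant_channel_for <- function(record) {
  if (!is.na(record$quant_detector) && !is.na(record$quant_wavelength))
    return(list(detector = record$quant_detector,
                wavelength = record$quant_wavelength))
  fam <- record$family
  cls <- record$substitution_class
  if (!fam %in% c("MF", "coumarin", "FC")) stop("unknown family: ", fam)
  if (fam %in% c("MF", "coumarin"))
    return(list(detector = "UV", wavelength = 330))
  if (grepl("5,8-diOR", cls, fixed = TRUE))
    return(list(detector = "UV", wavelength = 270))
  list(detector = "UV", wavelength = 250)
}

#' Look up catalog records by compound id
#'
#' @param catalog An `oha_catalog`.
#' @param ids Character ids (`"1"`..`"39"` or `"I"`..`"XIII"`) or compound
#'   names.
#' @return The matching catalog rows, in the order of `ids`.
#' @export
catalog_records <- function(catalog, ids) {
  idx <- match(ids, catalog$id)
  byname <- is.na(idx)
  idx[byname] <- match(ids[byname], catalog$name)
  if (anyNA(idx))
    stop("compound(s) not in catalog: ", paste(ids[is.na(idx)], collapse = ", "))
  catalog[idx, ]
}
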