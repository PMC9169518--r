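#' Sample metadata
#'
#' @param sample_id Unique sample identifiers.
#' @param species `"orange"`, `"mandarin"`, `"grapefruit"` or `"pomelo"`.
#' @param subgroup `"none"`, or for pomelo only, `"SG"` (Shatianyou group)
#'   or `"WG"` (Wendan group).
#' @param cultivar,region,harvest_year Provenance descriptors.
#' @return A `sample_meta` data frame.
#' @export
sample_meta <- function(sample_id, species, subgroup = "none",
                        cultivar = NA_character_, region = NA_character_,
                        harvest_year = NA_integer_) {
  species <- as.character(species)
  bad <- !species %in% c("orange", "mandarin", "grapefruit", "pomelo")
  if (any(bad)) stop("unknown species: ", paste(unique(species[bad]), collapse = ", "))
  df <- data.frame(sample_id = as.character(sample_id), species = species,
                   subgroup = as.character(subgroup),
                   cultivar = as.character(cultivar),
                   region = as.character(region),
                   harvest_year = as.integer(harvest_year),
                   stringsAsFactors = FALSE)
  if (any(!df$subgroup %in% c("none", "SG", "WG")))
    stop("subgroup must be none, SG or WG")
  if (any(df$subgroup != "none" & df$species != "pomelo"))
    stop("only pomelo samples carry an SG/WG subgroup")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[anyDuplicated(df$sample_id)])
  structure(df, class = c("sample_meta", "data.frame"))
}

#' Profile matrix
#'
#' The samples x compounds concentration matrix at the heart of the
#' pipeline.  Calibrated compounds are stored in mg/L of juice; screened
#' candidates without calibration carry response peak areas instead, and
#' the per-column `value_kind` records which is which (autoscaling before
#' chemometrics makes the units immaterial, but the audit trail is kept).
#'
#' @param meta A [sample_meta()] data frame, one row per sample.
#' @param values Numeric matrix (samples x compounds, non-negative);
#'   column names are compound labels.
#' @param value_kind Named character vector per column, `"concentration"`
#'   or `"area"`.  Default: all `"concentration"`.
#' @param flags Optional data frame side table (`sample_id`, `compound_id`,
#'   `flag`) preserving below-LOQ annotations.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(meta, values, value_kind = NULL, flags = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(meta))
    stop("meta and values disagree on the number of samples")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("values must have unique compound column labels")
  if (any(values < 0, na.rm = TRUE)) stop("negative entries are not allowed")
  rownames(values) <- meta$sample_id
  if (is.null(value_kind))
    value_kind <- stats::setNames(rep("concentration", ncol(values)),
                                  colnames(values))
  if (!all(colnames(values) %in% names(value_kind)))
    stop("value_kind must cover every column")
  structure(list(meta = meta, values = values,
                 value_kind = value_kind[colnames(values)], flags = flags),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix: %d samples x %d compounds (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s %d", names(table(x$meta$species)),
                            as.integer(table(x$meta$species))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' Subset a profile matrix
#'
#' @param x A `profile_matrix`.
#' @param i Row (sample) index.
#' @param j Column (compound) index or labels.
#' @param ... Ignored.
#' @return A `profile_matrix` restricted to the selection.
#' @export
`[.profile_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  vals <- x$values[i, j, drop = FALSE]
  profile_matrix(x$meta[i, , drop = FALSE], vals,
                 x$value_kind[colnames(vals)], x$flags)
}

#' Assemble a profile matrix from quantitation results
#'
#' Builds the samples x compounds matrix from per-peak quantitation
#' results.  A compound not reported for a sample counts as not detected
#' (0); below-LOD results are set to 0; below-LOQ results keep their value
#' (trace detections are informative) and the flag is preserved in the
#' side table.
#'
#' @param quant_results Data frame with columns `sample_id`, `compound_id`,
#'   `value` and optionally `flags` (character, `;`-separated).
#' @param meta A [sample_meta()] covering every `sample_id`.
#' @param column_spec Character vector of compound labels defining the
#'   columns (order preserved).
#' @param value_kind Optional named `"concentration"`/`"area"` vector.
#' @return A `profile_matrix`.
#' @export
assemble_matrix <- function(quant_results, meta, column_spec, value_kind = NULL) {
  stopifnot(all(c("sample_id", "compound_id", "value") %in% names(quant_results)))
  qr <- quant_results[quant_results$compound_id %in% column_spec, , drop = FALSE]
  key <- paste(qr$sample_id, qr$compound_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, compound) results: ",
         sub("\r", " / ", key[anyDuplicated(key)][1]))
  if (!all(qr$sample_id %in% meta$sample_id))
    stop("quant results reference samples missing from metadata")
  vals <- matrix(0, nrow(meta), length(column_spec),
                 dimnames = list(meta$sample_id, column_spec))
  has_flags <- "flags" %in% names(qr)
  flag_rows <- list()
  for (k in seq_len(nrow(qr))) {
    fl <- if (has_flags && !is.na(qr$flags[k]) && nzchar(qr$flags[k]))
      strsplit(qr$flags[k], ";", fixed = TRUE)[[1]] else character(0)
    v <- qr$value[k]
    if ("below_LOD" %in% fl) v <- 0
    vals[qr$sample_id[k], qr$compound_id[k]] <- v
    if (length(fl) > 0)
      flag_rows[[length(flag_rows) + 1L]] <-
        data.frame(sample_id = qr$sample_id[k], compound_id = qr$compound_id[k],
                   flag = paste(fl, collapse = ";"), stringsAsFactors = FALSE)
  }
  flags <- if (length(flag_rows) > 0) do.call(rbind, flag_rows) else NULL
  profile_matrix(meta, vals, value_kind, flags)
}

#' Relative-weight normalisation
#'
#' Normalises each compound across all samples: every column is divided by
#' its maximum, so the sample with the highest amount of a compound gets
#' relative weight 1.0.  This is the transformation behind the
#' species-profile heat map view of the data.  All-zero columns stay
#' all-zero.
#'
#' @param pm A `profile_matrix`.
#' @return List with `weights` (a `profile_matrix` of values in \[0, 1\])
#'   and `maxima` (named vector of the per-column maxima used).
#' @export
relative_weight <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  maxima <- apply(pm$values, 2, max)
  scale <- ifelse(maxima > 0, maxima, 1)
  w <- sweep(pm$values, 2, scale, "/")
  list(weights = profile_matrix(pm$meta, w, pm$value_kind, pm$flags),
       maxima = maxima)
}

#' Group averages of a profile matrix
#'
#' Collapses replicate samples to group means, typically one mean profile
#' per cultivar x region x harvest-year combination; these averages are
#' the units from which virtual blends are built.
#'
#' @param pm A `profile_matrix`.
#' @param grouping Character subset of `c("cultivar", "region",
#'   "harvest_year")` (species and subgroup are always kept).
#' @return A `profile_matrix` with one row per distinct group; sample ids
#'   are the concatenated group keys.
#' @export
cultivar_averages <- function(pm, grouping = c("cultivar", "region", "harvest_year")) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (nrow(pm$values) == 0L) stop("empty profile matrix")
  grouping <- match.arg(grouping, c("cultivar", "region", "harvest_year"),
                        several.ok = TRUE)
  keys <- pm$meta[, c("species", "subgroup", grouping), drop = FALSE]
  key_str <- apply(keys, 1, paste, collapse = "|")
  groups <- split(seq_len(nrow(pm$values)), key_str)
  groups <- groups[unique(key_str)]            # keep first-appearance order
  vals <- t(vapply(groups, function(idx)
    colMeans(pm$values[idx, , drop = FALSE]), numeric(ncol(pm$values))))
  colnames(vals) <- colnames(pm$values)
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- pm$meta[first, , drop = FALSE]
  meta$sample_id <- names(groups)
  rownames(meta) <- NULL
  profile_matrix(sample_meta(meta$sample_id, meta$species, meta$subgroup,
                             meta$cultivar, meta$region, meta$harvest_year),
                 vals, pm$value_kind)
}
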