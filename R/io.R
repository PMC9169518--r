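#' Write a profile matrix to CSV
#'
#' Schema: metadata columns `sample_id`, `species`, `subgroup`,
#' `cultivar`, `region`, `harvest_year`, then one column per compound.
#' Values are serialised with 6 significant digits and `NA` for missing,
#' giving a deterministic byte stream for fixed input.
#'
#' @param pm A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  df <- cbind(pm$meta,
              as.data.frame(signif(pm$values, 6), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a profile matrix from CSV
#'
#' Inverse of [write_profile_matrix()].  Missing concentrations (`NA`)
#' are read as 0 (not detected) and recorded in the flag side table.
#'
#' @param path CSV path.
#' @param value_kind Optional named `"concentration"`/`"area"` vector.
#' @return A `profile_matrix`.
#' @export
read_profile_matrix <- function(path, value_kind = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample_id", "species", "subgroup", "cultivar", "region",
                 "harvest_year")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols) > 0)
    stop("profile matrix header lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id at row ",
         which(duplicated(df$sample_id))[1], ": ",
         df$sample_id[duplicated(df$sample_id)][1])
  compound_cols <- setdiff(names(df), meta_cols)
  if (length(compound_cols) == 0) stop("no compound columns found")
  vals <- as.matrix(df[, compound_cols, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric compound column in ", path)
  na_idx <- which(is.na(vals), arr.ind = TRUE)
  flags <- NULL
  if (nrow(na_idx) > 0) {
    flags <- data.frame(sample_id = df$sample_id[na_idx[, 1]],
                        compound_id = compound_cols[na_idx[, 2]],
                        flag = "not_detected", stringsAsFactors = FALSE)
    vals[is.na(vals)] <- 0
  }
  meta <- sample_meta(df$sample_id, df$species, df$subgroup, df$cultivar,
                      df$region, df$harvest_year)
  profile_matrix(meta, vals, value_kind, flags)
}

#' Serialise a purity model to JSON
#'
#' Writes scaling parameters, per-component weights and loadings,
#' regression coefficients, the cross-validation error path and the
#' decision rule, so a trained model can be stored and reloaded.
#'
#' @param model A `purity_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purity_model <- function(model, path) {
  stopifnot(inherits(model, "purity_model"))
  obj <- list(
    package = "citrusOHA",
    version = as.character(utils::packageVersion("citrusOHA")),
    scenario = model$scenario,
    variables = model$variables,
    n_components = model$n_components,
    mean_y = model$mean_y,
    scaling = list(means = as.list(model$scaling$means),
                   sds = as.list(model$scaling$sds)),
    coefficients = stats::setNames(as.list(model$fit$coefficients),
                                   model$variables),
    weights = apply(model$fit$weights, 2, identity, simplify = FALSE),
    x_loadings = apply(model$fit$x_loadings, 2, identity, simplify = FALSE),
    y_loadings = model$fit$y_loadings,
    rmsecv = model$rmsecv, rmsecv_path = model$rmsecv_path,
    decision = list(authentic_min = model$decision$authentic_min,
                    fraud_max = model$decision$fraud_max))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a purity model from JSON
#'
#' @param path JSON path written by [write_purity_model()].
#' @return A `purity_model` (sufficient for [predict_purity()],
#'   [evaluate_model()] and [classify_label()]).
#' @export
read_purity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- obj$variables
  as_mat <- function(x) if (is.list(x)) do.call(cbind, x) else as.matrix(x)
  W <- as_mat(obj$weights)
  P <- as_mat(obj$x_loadings)
  fit <- structure(list(coefficients = unlist(obj$coefficients),
                        weights = W, x_loadings = P,
                        y_loadings = obj$y_loadings,
                        n_components = obj$n_components),
                   class = "pls1_fit")
  structure(list(scenario = obj$scenario, variables = vars, fit = fit,
                 scaling = list(means = stats::setNames(unlist(obj$scaling$means), vars),
                                sds = stats::setNames(unlist(obj$scaling$sds), vars)),
                 mean_y = obj$mean_y, n_components = obj$n_components,
                 rmsecv = obj$rmsecv, rmsecv_path = obj$rmsecv_path,
                 decision = decision_rule(obj$decision$authentic_min,
                                          obj$decision$fraud_max)),
            class = "purity_model")
}

#' Run manifest
#'
#' Records how a pipeline artifact was produced: the operation, its
#' configuration, the seed, input file hashes and output paths, with a
#' timestamp and the package version.
#'
#' @param command Short operation name (e.g. `"simulate"`, `"train"`).
#' @param config List of parameters used.
#' @param seed Seed used, if any.
#' @param inputs,outputs Character vectors of file paths; existing inputs
#'   are content-hashed.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(command, config = list(), seed = NA_integer_,
                         inputs = character(0), outputs = character(0)) {
  hash_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    unname(tools::md5sum(p))
  }
  structure(list(command = command, config = config, seed = seed,
                 inputs = stats::setNames(lapply(inputs, hash_file), inputs),
                 outputs = outputs,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 package_version = as.character(utils::packageVersion("citrusOHA"))),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
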