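#' Adulteration scenarios
#'
#' The three published blend scenarios with their marker variables and
#' decision thresholds:
#'
#' * `orange_vs_mandarin`: mandarin juice in sweet orange juice; markers
#'   isosinensetin, sinensetin, tangeretin; authentic at predicted purity
#'   (PP) >= 94 percent, fraudulent below 82 percent.
#' * `grapefruit_vs_SG`: Shatianyou-group pomelo juice in grapefruit
#'   juice; markers meranzin, 3,5,6,7,8,3',4'-heptamethoxyflavone,
#'   osthole, 6',7'-epoxybergamottin, bergamottin; authentic >= 94,
#'   fraudulent < 85.
#' * `grapefruit_vs_WG`: Wendan-group pomelo juice in grapefruit juice;
#'   markers bergaptol, isomeranzin, 6',7'-dihydroxybergamottin;
#'   authentic >= 95, fraudulent < 87.
#'
#' @param scenario Scenario name.
#' @return List with `main_species`, `adulterant`, `variables` (compound
#'   names), `purity_levels` (training blend purities, percent),
#'   `include_pure_adulterant` and `decision` (a [decision_rule()]).
#' @export
scenario_spec <- function(scenario = c("orange_vs_mandarin",
                                       "grapefruit_vs_SG",
                                       "grapefruit_vs_WG")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    orange_vs_mandarin = list(
      scenario = scenario, main_species = "orange", adulterant = "mandarin",
      variables = c("isosinensetin", "sinensetin", "tangeretin"),
      purity_levels = c(95, 90, 80), include_pure_adulterant = TRUE,
      decision = decision_rule(94, 82)),
    grapefruit_vs_SG = list(
      scenario = scenario, main_species = "grapefruit", adulterant = "pomelo-SG",
      variables = c("meranzin", "3,5,6,7,8,3',4'-heptamethoxyflavone",
                    "osthole", "6',7'-epoxy-bergamottin", "bergamottin"),
      purity_levels = c(90, 80), include_pure_adulterant = FALSE,
      decision = decision_rule(94, 85)),
    grapefruit_vs_WG = list(
      scenario = scenario, main_species = "grapefruit", adulterant = "pomelo-WG",
      variables = c("bergaptol", "isomeranzin", "6',7'-dihydroxy-bergamottin"),
      purity_levels = c(90, 80), include_pure_adulterant = FALSE,
      decision = decision_rule(95, 87)))
}

#' Decision rule for a purity model
#'
#' @param authentic_min Predicted purity (percent) at or above which the
#'   product is regarded as authentic.
#' @param fraud_max Predicted purity below which the product is evaluated
#'   as fraudulently mislabeled.  Between the two bounds the result is
#'   indeterminate and additional analytical methods are required.
#' @return A `decision_rule` list.
#' @export
decision_rule <- function(authentic_min, fraud_max) {
  if (fraud_max >= authentic_min)
    stop("fraud_max must be below authentic_min")
  structure(list(authentic_min = authentic_min, fraud_max = fraud_max),
            class = "decision_rule")
}

#' Classify a predicted purity
#'
#' @param pp Predicted purity in percent (may lie outside \[0, 100\]; the
#'   raw model output is never clipped).
#' @param rule A [decision_rule()].
#' @return `"authentic"`, `"indeterminate"` or `"fraudulent"` (vectorised
#'   over `pp`).
#' @export
classify_label <- function(pp, rule) {
  stopifnot(inherits(rule, "decision_rule"))
  out <- ifelse(pp >= rule$authentic_min, "authentic",
                ifelse(pp < rule$fraud_max, "fraudulent", "indeterminate"))
  out
}

#' Generate exhaustive virtual blends
#'
#' Forms every pairwise in-silico mixture of a main-species profile and an
#' adulterant profile at each purity level: a blend at purity `p` percent
#' is `p/100 * main + (1 - p/100) * adulterant`, elementwise on the common
#' variable columns (exact mass conservation).  Pure main profiles
#' (purity 100) and pure adulterant profiles (purity 0) can be appended.
#'
#' @param main_profiles,adulterant_profiles `profile_matrix` objects with
#'   identical variable columns (typically cultivar averages).
#' @param purity_levels Blend purities in percent, distinct, within
#'   (0, 100).
#' @param include_pure_main,include_pure_adulterant Append the pure
#'   profiles with y = 100 / y = 0.
#' @return A `blend_set` list: `X` (blend matrix), `y` (purity percent per
#'   row), `provenance` (data frame `main_id`, `adulterant_id`, `purity`).
#' @export
generate_blends <- function(main_profiles, adulterant_profiles,
                            purity_levels = c(95, 90, 80),
                            include_pure_main = TRUE,
                            include_pure_adulterant = TRUE) {
  stopifnot(inherits(main_profiles, "profile_matrix"),
            inherits(adulterant_profiles, "profile_matrix"))
  if (!identical(colnames(main_profiles$values),
                 colnames(adulterant_profiles$values)))
    stop("main and adulterant profiles must share identical variable columns")
  A <- main_profiles$values; B <- adulterant_profiles$values
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty profile set")
  purity_levels <- as.numeric(purity_levels)
  if (anyDuplicated(purity_levels) || any(purity_levels <= 0 | purity_levels >= 100))
    stop("purity levels must be distinct and strictly between 0 and 100")
  n_blend <- nrow(A) * nrow(B) * length(purity_levels)
  n_pure <- include_pure_main * nrow(A) + include_pure_adulterant * nrow(B)
  X <- matrix(NA_real_, n_blend + n_pure, ncol(A),
              dimnames = list(NULL, colnames(A)))
  y <- numeric(n_blend + n_pure)
  main_id <- adulterant_id <- character(n_blend + n_pure)
  k <- 0L
  for (p in purity_levels) {
    f <- p / 100
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      k <- k + 1L
      X[k, ] <- f * A[i, ] + (1 - f) * B[j, ]
      y[k] <- p
      main_id[k] <- rownames(A)[i]; adulterant_id[k] <- rownames(B)[j]
    }
  }
  if (include_pure_main) for (i in seq_len(nrow(A))) {
    k <- k + 1L
    X[k, ] <- A[i, ]; y[k] <- 100
    main_id[k] <- rownames(A)[i]; adulterant_id[k] <- NA_character_
  }
  if (include_pure_adulterant) for (j in seq_len(nrow(B))) {
    k <- k + 1L
    X[k, ] <- B[j, ]; y[k] <- 0
    main_id[k] <- NA_character_; adulterant_id[k] <- rownames(B)[j]
  }
  structure(list(X = X, y = y,
                 provenance = data.frame(main_id = main_id,
                                         adulterant_id = adulterant_id,
                                         purity = y,
                                         stringsAsFactors = FALSE)),
            class = "blend_set")
}

#' @export
print.blend_set <- function(x, ...) {
  cat(sprintf("<blend_set: %d rows x %d variables; purity levels %s>\n",
              nrow(x$X), ncol(x$X),
              paste(sort(unique(x$y), decreasing = TRUE), collapse = "/")))
  invisible(x)
}

#' Train a purity recognition model
#'
#' Fits the PLS1 purity model of a scenario on a training blend set:
#' variables are restricted to the scenario's marker compounds, the
#' predictor block is autoscaled and the purity response centred, the
#' component count is selected by full (leave-one-out) cross-validation,
#' and the scenario's published decision rule is attached.
#'
#' @param blends A `blend_set` from [generate_blends()] whose columns
#'   include the scenario variables.
#' @param scenario Scenario name (see [scenario_spec()]).
#' @param max_components Upper bound for the component search (default:
#'   number of variables).
#' @return A `purity_model` list: `scenario`, `variables`, `fit`
#'   (the [fit_pls1()] object), `scaling`, `mean_y`, `n_components`,
#'   `rmsecv` (at the selected count), `rmsecv_path`, `decision`.
#' @export
train_purity_model <- function(blends, scenario, max_components = NULL) {
  stopifnot(inherits(blends, "blend_set"))
  spec <- scenario_spec(scenario)
  missing_vars <- setdiff(spec$variables, colnames(blends$X))
  if (length(missing_vars) > 0)
    stop("blend set lacks required variable(s): ",
         paste(missing_vars, collapse = ", "))
  X <- blends$X[, spec$variables, drop = FALSE]
  y <- blends$y
  if (is.null(max_components)) max_components <- ncol(X)
  cv <- cross_validate(X, y, max_components)
  a <- cv$suggested
  sc <- autoscale(X)
  if (length(sc$dropped) > 0)
    stop("constant marker variable(s): ", paste(sc$dropped, collapse = ", "))
  fit <- fit_pls1(sc$scaled, y - mean(y), a)
  structure(list(scenario = spec$scenario, variables = spec$variables,
                 fit = fit, scaling = sc[c("means", "sds")],
                 mean_y = mean(y), n_components = fit$n_components,
                 rmsecv = cv$rmsecv[a], rmsecv_path = cv$rmsecv,
                 decision = spec$decision),
            class = "purity_model")
}

#' @export
print.purity_model <- function(x, ...) {
  cat(sprintf(paste0("<purity_model: %s; %d latent variable(s); RMSECV ",
                     "%.3f%%; authentic >= %g%%, fraud < %g%%>\n"),
              x$scenario, x$n_components, x$rmsecv,
              x$decision$authentic_min, x$decision$fraud_max))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Predict purity for new samples
#'
#' Applies the model's autoscaling and regression coefficients to new
#' rows.  Predicted purity (PP) is reported raw and unclipped; values
#' above 100 or below 0 percent are legitimate model outputs for samples
#' outside the training cloud.
#'
#' @param model A `purity_model`.
#' @param newdata Matrix, data frame or `blend_set` containing the model
#'   variables.
#' @return Numeric vector of PP in percent.
#' @export
predict_purity <- function(model, newdata) {
  stopifnot(inherits(model, "purity_model"))
  X <- if (inherits(newdata, "blend_set")) newdata$X
       else if (inherits(newdata, "profile_matrix")) newdata$values
       else as.matrix(newdata)
  if (is.null(dim(X))) X <- matrix(X, 1L, dimnames = list(NULL, names(newdata)))
  missing_vars <- setdiff(model$variables, colnames(X))
  if (length(missing_vars) > 0)
    stop("newdata lacks model variable(s): ",
         paste(missing_vars, collapse = ", "))
  Xs <- apply_scaling(X[, model$variables, drop = FALSE],
                      model$scaling$means, model$scaling$sds)
  unname(model$mean_y + drop(Xs %*% model$fit$coefficients))
}

#' Evaluate a purity model on a test blend set
#'
#' @param model A `purity_model`.
#' @param test A `blend_set` with reference purities.
#' @return List with `rmsep` (root mean square error of prediction,
#'   percent purity), `r_squared` (Pearson R^2 of PP vs reference, `NA`
#'   with a single test row), and `level_ranges` (data frame of min/max PP
#'   per reference purity level).
#' @export
evaluate_model <- function(model, test) {
  stopifnot(inherits(test, "blend_set"))
  pp <- predict_purity(model, test)
  err <- pp - test$y
  rmsep <- sqrt(mean(err^2))
  r2 <- if (length(pp) < 2L || stats::sd(test$y) == 0) NA_real_
        else stats::cor(pp, test$y)^2
  lv <- sort(unique(test$y), decreasing = TRUE)
  level_ranges <- data.frame(
    purity = lv,
    n = vapply(lv, function(l) sum(test$y == l), integer(1)),
    pp_min = vapply(lv, function(l) min(pp[test$y == l]), numeric(1)),
    pp_max = vapply(lv, function(l) max(pp[test$y == l]), numeric(1)))
  list(rmsep = rmsep, r_squared = r2, level_ranges = level_ranges)
}

#' Conservative grapefruit assessment with unknown pomelo subgroup
#'
#' When the pomelo subgroup that may have been added to a grapefruit
#' juice is not declared, both subgroup models are applied and the worst
#' (most suspicious) label is reported, avoiding false authentication.
#'
#' @param pp_sg,pp_wg Predicted purities from the SG and WG models.
#' @return Combined label per sample: the more severe of the two verdicts
#'   (`fraudulent` > `indeterminate` > `authentic`).
#' @export
classify_grapefruit_conservative <- function(pp_sg, pp_wg) {
  lab_sg <- classify_label(pp_sg, scenario_spec("grapefruit_vs_SG")$decision)
  lab_wg <- classify_label(pp_wg, scenario_spec("grapefruit_vs_WG")$decision)
  severity <- c(authentic = 1, indeterminate = 2, fraudulent = 3)
  worst <- pmax(severity[lab_sg], severity[lab_wg])
  names(severity)[match(worst, severity)]
}
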