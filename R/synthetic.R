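#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   bit-reproducible.
#' @param n_cultivars Cultivars simulated per species.
#' @param replicates Juice samples per cultivar.
#' @param cv Within-species coefficient of variation of each compound
#'   (lognormal), default 0.25.
#' @param rt_jitter_sd Retention-time jitter (minutes) in simulated
#'   chromatograms.
#' @param noise_sd Detector noise standard deviation (response units).
#' @param correlation Share of the lognormal variance carried by a common
#'   per-cultivar factor (0 = compound-independent draws, the default; a
#'   positive value emulates cultivars that are globally rich or poor in
#'   OHAs).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_cultivars = 10L, replicates = 1L,
                       cv = 0.25, rt_jitter_sd = 0, noise_sd = 0,
                       correlation = 0) {
  if (cv <= 0) stop("cv must be positive")
  if (correlation < 0 || correlation >= 1) stop("correlation must be in [0, 1)")
  structure(list(seed = as.integer(seed), n_cultivars = as.integer(n_cultivars),
                 replicates = as.integer(replicates), cv = cv,
                 rt_jitter_sd = rt_jitter_sd, noise_sd = noise_sd,
                 correlation = correlation),
            class = "sim_config")
}

#' Species concentration templates
#'
#' Loads the packaged species templates: synthetic per-compound mean
#' concentrations (mg/L of juice; response areas for uncalibrated
#' candidates) for sweet orange, mandarin, grapefruit and the two pomelo
#' subgroups, together with each species' hot-spot compound set.  The
#' template magnitudes are this package's own synthetic choices; they are
#' designed so that (a) expected total OHA content falls in the reported
#' per-species ranges (orange < 5 mg/L, mandarin 5--10 mg/L, grapefruit
#' and pomelo 5--100 mg/L), (b) the species hot-spot patterns follow the
#' published qualitative profiles, and (c) the scenario marker compounds
#' separate main species from adulterant.
#'
#' @param path Template CSV (columns `species`, `compound`, `mean`,
#'   `value_kind`, `hot_spot`, `cv_scale`); default the packaged file.
#' @param catalog Catalog used to validate compound names.
#' @return Named list of `species_template` objects, each with `species`,
#'   `subgroup`, `means` (named vector over the union of template
#'   compounds), `cv_scale` (per-compound multiplier on the configured
#'   coefficient of variation, capturing compounds whose content varies
#'   strongly across cultivars), `value_kind`, `hot_spots` and
#'   `total_range` (mg/L).
#' @export
default_templates <- function(path = system.file("extdata",
                                                 "species_templates.csv",
                                                 package = "citrusOHA"),
                              catalog = load_catalog()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "compound", "mean", "value_kind", "hot_spot",
                  "cv_scale") %in% names(df)))
  unknown <- setdiff(df$compound, c(catalog$name, catalog$id))
  if (length(unknown) > 0)
    stop("template compounds missing from catalog: ",
         paste(unknown, collapse = ", "))
  compounds <- unique(df$compound)
  kind <- stats::setNames(rep("concentration", length(compounds)), compounds)
  kind[unique(df$compound[df$value_kind == "area"])] <- "area"
  ranges <- list(orange = c(0, 5), mandarin = c(5, 10),
                 grapefruit = c(5, 100), `pomelo-SG` = c(5, 100),
                 `pomelo-WG` = c(5, 100))
  out <- lapply(split(df, df$species), function(d) {
    means <- stats::setNames(rep(0, length(compounds)), compounds)
    means[d$compound] <- d$mean
    cv_scale <- stats::setNames(rep(1, length(compounds)), compounds)
    cv_scale[d$compound] <- d$cv_scale
    sp <- sub("-(SG|WG)$", "", d$species[1])
    structure(list(species = sp,
                   subgroup = if (grepl("-SG$", d$species[1])) "SG"
                              else if (grepl("-WG$", d$species[1])) "WG"
                              else "none",
                   label = d$species[1],
                   means = means, cv_scale = cv_scale, value_kind = kind,
                   hot_spots = d$compound[d$hot_spot == 1],
                   total_range = ranges[[d$species[1]]]),
              class = "species_template")
  })
  out[c("orange", "mandarin", "grapefruit", "pomelo-SG", "pomelo-WG")]
}

#' Draw synthetic juice profiles from a species template
#'
#' Per-compound concentrations are lognormal with expectation equal to the
#' template mean and coefficient of variation `config$cv`; compounds
#' absent from the template stay 0.  Draws are independent across
#' compounds unless `config$correlation` > 0, in which case a shared
#' per-cultivar lognormal factor induces positive covariance (cultivars
#' globally rich or poor in OHAs).  Replicates of a cultivar share its
#' cultivar-level factor.
#'
#' @param template A `species_template` from [default_templates()].
#' @param config A [sim_config()].
#' @param cultivar_prefix Prefix for the synthetic cultivar names.
#' @return A `profile_matrix` with synthetic metadata.
#' @export
sample_profiles <- function(template, config, cultivar_prefix = NULL) {
  stopifnot(inherits(template, "species_template"), inherits(config, "sim_config"))
  withr_seed(config$seed, {
    n_row <- config$n_cultivars * config$replicates
    compounds <- names(template$means)
    cv_scale <- if (is.null(template$cv_scale)) rep(1, length(compounds))
                else template$cv_scale
    sdlog <- sqrt(log(1 + (config$cv * cv_scale)^2))
    meanlog <- ifelse(template$means > 0,
                      log(template$means) - sdlog^2 / 2, -Inf)
    rho <- config$correlation
    z <- stats::rnorm(config$n_cultivars)            # cultivar factor
    vals <- matrix(0, n_row, length(compounds),
                   dimnames = list(NULL, compounds))
    row <- 0L
    for (cu in seq_len(config$n_cultivars)) for (r in seq_len(config$replicates)) {
      row <- row + 1L
      eps <- stats::rnorm(length(compounds))
      lx <- meanlog + sdlog * (sqrt(rho) * z[cu] + sqrt(1 - rho) * eps)
      vals[row, ] <- ifelse(is.finite(meanlog), exp(lx), 0)
    }
    prefix <- if (is.null(cultivar_prefix)) template$label else cultivar_prefix
    cult <- rep(sprintf("%s_cv%02d", prefix, seq_len(config$n_cultivars)),
                each = config$replicates)
    ids <- sprintf("%s_r%d", cult,
                   rep(seq_len(config$replicates), config$n_cultivars))
    meta <- sample_meta(ids, template$species, template$subgroup,
                        cultivar = cult, region = "synthetic",
                        harvest_year = 2021L)
    profile_matrix(meta, vals, template$value_kind)
  })
}

#' Default synthetic alkylarylketone ladder
#'
#' Retention times for the C8--C14 anchor ketones under the standard
#' gradient, chosen so that bracketed interpolation reproduces the
#' retention indices of the catalogued screened candidates to about one
#' index unit.  Optional seeded jitter perturbs the times reproducibly.
#'
#' @param rt_jitter_sd Gaussian jitter (minutes) applied to the anchor
#'   times (spacing is re-checked).
#' @param seed Seed for the jitter.
#' @return An [anchor_series()] with seven anchors.
#' @export
synth_anchor_series <- function(rt_jitter_sd = 0, seed = 1L) {
  rt <- c(8.60, 16.91, 26.20, 36.20, 38.22, 42.35, 47.35)
  if (rt_jitter_sd > 0)
    rt <- withr_seed(seed, rt + stats::rnorm(7, 0, rt_jitter_sd))
  anchor_series(8:14, rt)
}

# Psoralen internal standard: 5 mg/L spiked into every extract.
psoralen_is <- function() {
  list(name = "psoralen", rt = 12.60, nominal_mg_l = 5, uv_slope = 4.0,
       uv_maxima = c(246, 290, 328), emission_max = 410, family = "coumarin")
}

#' Simulate a chromatogram peak table from a juice profile
#'
#' Inverts the quantitation model: every non-zero compound of the profile
#' row yields one peak at the catalog retention time (plus seeded jitter)
#' whose area on the quantitation channel is `concentration x 9 x slope`
#' (plus detector noise); remaining UV channels follow the compound's
#' modelled UV spectrum, and fluorescence heights follow its catalogued
#' peak-height ratio.  Uncalibrated candidates contribute their response
#' area directly.  A psoralen internal-standard peak is injected at its
#' nominal response.  `is_drift` models a multiplicative detector response
#' drift applied to every peak, analytes and internal standard alike,
#' which the IS correction cancels again at quantitation time.
#'
#' @param profile_row Named concentration vector (mg/L; response areas for
#'   `area`-kind compounds), names matching catalog compound names.
#' @param catalog An `oha_catalog`.
#' @param config A [sim_config()] (uses `rt_jitter_sd`, `noise_sd`,
#'   `seed`).
#' @param is_drift Multiplicative detector response drift (1 = none).
#' @param value_kind Named `"concentration"`/`"area"` vector for the
#'   profile entries (default: all concentration).
#' @param concentration_factor Extract enrichment factor (default 9).
#' @return List with `peaks` (list of [chromatogram_peak()]), `is_peak`
#'   (the internal-standard peak) and `table` (a peak-table data frame
#'   with per-channel areas/heights).
#' @export
synth_chromatogram <- function(profile_row, catalog, config = sim_config(),
                               is_drift = 1, value_kind = NULL,
                               concentration_factor = 9) {
  stopifnot(is.numeric(profile_row), !is.null(names(profile_row)))
  if (is.null(value_kind))
    value_kind <- stats::setNames(rep("concentration", length(profile_row)),
                                  names(profile_row))
  withr_seed(config$seed, {
    peaks <- list()
    rows <- list()
    for (nm in names(profile_row)) {
      conc <- profile_row[[nm]]
      if (conc <= 0) next
      hit <- which(catalog$name == nm | catalog$id == nm)
      if (length(hit) != 1L) {
        warning("profile compound not in catalog, skipped: ", nm)
        next
      }
      rec <- catalog[hit, ]
      if (is.na(rec$rt_min)) { warning("no retention time for ", nm); next }
      rt <- rec$rt_min + if (config$rt_jitter_sd > 0)
        stats::rnorm(1, 0, config$rt_jitter_sd) else 0
      uv_sp <- uv_spectrum_from_maxima(rec$uv_maxima[[1]], rec$family)
      em_sp <- if (rec$fluoresces) emission_spectrum_from_max(rec$emission_max)
               else NULL
      noise <- function() if (config$noise_sd > 0)
        stats::rnorm(1, 0, config$noise_sd) else 0
      if (value_kind[[nm]] == "concentration") {
        ch <- quant_channel_for(rec)
        side <- if (ch$detector == "UV") "uv" else "fl"
        slope <- rec[[paste0(side, "_slope")]]
        if (is.na(slope)) { warning("no calibration for ", nm); next }
        ref <- conc * concentration_factor * slope * is_drift
      } else {
        ch <- list(detector = "FL", wavelength = rec$fl_monitor_high)
        ref <- conc * is_drift
      }
      # UV areas follow the modelled spectrum's relative intensities
      uv_int <- stats::approx(uv_sp$wavelengths, uv_sp$intensities,
                              xout = c(250, 270, 330))$y
      if (ch$detector == "UV") {
        at_q <- stats::approx(uv_sp$wavelengths, uv_sp$intensities,
                              xout = ch$wavelength)$y
        uv_areas <- pmax(ref * uv_int / at_q + c(noise(), noise(), noise()), 0)
      } else {
        uv_areas <- pmax(ref * 0.2 * uv_int + c(noise(), noise(), noise()), 0)
      }
      names(uv_areas) <- c("uv250", "uv270", "uv330")
      # fluorescence heights reproduce the catalogued peak-height ratio
      fl_h <- c(fl400 = 0, fl450 = 0, fl500 = 0)
      if (rec$fluoresces && !is.na(rec$fl_ratio)) {
        h_high <- if (ch$detector == "FL") ref else ref * 0.5
        fl_h[paste0("fl", rec$fl_monitor_high)] <- h_high
        fl_h[paste0("fl", rec$fl_monitor_second)] <- h_high / rec$fl_ratio
        third <- setdiff(c(400, 450, 500),
                         c(rec$fl_monitor_high, rec$fl_monitor_second))
        fl_h[paste0("fl", third)] <- h_high / rec$fl_ratio / 2.5
      }
      pk <- chromatogram_peak(rt, areas = uv_areas, heights = fl_h,
                              uv_spectrum = uv_sp, em_spectrum = em_sp)
      peaks[[length(peaks) + 1L]] <- pk
      rows[[length(rows) + 1L]] <-
        data.frame(rt_min = rt, t(uv_areas), t(fl_h), compound = nm,
                   stringsAsFactors = FALSE)
    }
    is_ <- psoralen_is()
    is_resp <- is_$nominal_mg_l * concentration_factor * is_$uv_slope * is_drift
    is_sp <- uv_spectrum_from_maxima(is_$uv_maxima, is_$family)
    is_int <- stats::approx(is_sp$wavelengths, is_sp$intensities,
                            xout = c(250, 270, 330))$y
    at330 <- stats::approx(is_sp$wavelengths, is_sp$intensities, xout = 330)$y
    is_areas <- stats::setNames(is_resp * is_int / at330,
                                c("uv250", "uv270", "uv330"))
    is_peak <- chromatogram_peak(is_$rt, areas = is_areas,
                                 heights = c(fl400 = is_resp * 0.3,
                                             fl450 = is_resp * 0.15,
                                             fl500 = is_resp * 0.05),
                                 uv_spectrum = is_sp,
                                 em_spectrum = emission_spectrum_from_max(is_$emission_max))
    tab <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(rt_min = numeric(0))
    list(peaks = peaks, is_peak = is_peak, table = tab)
  })
}

#' Identify and quantify a simulated (or imported) peak list
#'
#' Runs the identification gates over every peak, computes the
#' internal-standard correction from the psoralen peak, and quantifies
#' each uniquely matched peak on its quantitation channel.  Peaks matching
#' an uncalibrated candidate are reported with their response area.
#'
#' @param peaks List of [chromatogram_peak()] objects.
#' @param is_peak The internal-standard peak (or `NULL` for no
#'   correction).
#' @param catalog,anchors,gates Passed to [identify_peak()].
#' @param concentration_factor Extract enrichment factor.
#' @return Data frame with one row per peak: `rt`, `compound_id`, `value`
#'   (mg/L in juice, or response area for candidates), `kind`, `flags`.
#' @export
quantify_chromatogram <- function(peaks, is_peak, catalog, anchors,
                                  gates = match_gates(),
                                  concentration_factor = 9) {
  is_ratio <- 1
  if (!is.null(is_peak)) {
    is_ <- psoralen_is()
    nominal <- is_$nominal_mg_l * concentration_factor * is_$uv_slope
    observed <- is_peak$areas[["uv330"]]
    if (is.na(observed) || observed <= 0) stop("internal-standard peak has no response")
    is_ratio <- nominal / observed
  }
  out <- lapply(peaks, function(pk) {
    idres <- identify_peak(pk, catalog, anchors, gates)
    if (is.na(idres$matched_id))
      return(data.frame(rt = pk$rt, compound_id = NA_character_,
                        value = NA_real_, kind = NA_character_,
                        flags = if (idres$ambiguous) "ambiguous" else "unmatched",
                        deduced_class = idres$deduced_class,
                        stringsAsFactors = FALSE))
    rec <- catalog_records(catalog, idres$matched_id)
    if (is.na(rec$uv_slope) && is.na(rec$fl_slope)) {
      # screened candidate: report response peak area on its FL channel
      value <- pk$heights[[paste0("fl", rec$fl_monitor_high)]]
      return(data.frame(rt = pk$rt, compound_id = rec$id, value = value,
                        kind = "area", flags = "", deduced_class = NA_character_,
                        stringsAsFactors = FALSE))
    }
    ch <- quant_channel_for(rec)
    area <- if (ch$detector == "UV") pk$areas[[paste0("uv", ch$wavelength)]]
            else pk$heights[[paste0("fl", ch$wavelength)]]
    qr <- quantify_peak(area, rec, is_ratio, concentration_factor)
    data.frame(rt = pk$rt, compound_id = rec$id, value = qr$concentration,
               kind = "concentration", flags = paste(qr$flags, collapse = ";"),
               deduced_class = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a complete purity-model study
#'
#' End-to-end scenario simulation used for model validation: draws
#' cultivar-level profiles for the main species and the adulterant from
#' the default templates, splits cultivars disjointly into training and
#' test sets, builds exhaustive virtual blends at the scenario purity
#' levels (plus pure juices), trains the purity model on the training
#' blends and evaluates it on the held-out-cultivar blends.
#'
#' @param scenario Scenario name (see [scenario_spec()]).
#' @param n_train,n_test Cultivars per species in the training and test
#'   split (test cultivars are entirely unseen during training).
#' @param cv Within-species coefficient of variation.
#' @param seed Integer seed.
#' @param correlation Passed to [sim_config()].
#' @param templates Template list (default [default_templates()]).
#' @return List with `model` (a `purity_model`), `evaluation` (from
#'   [evaluate_model()]), `train_blends`, `test_blends`.
#' @export
simulate_purity_study <- function(scenario, n_train = 20L, n_test = 10L,
                                  cv = 0.25, seed = 1L, correlation = 0,
                                  templates = default_templates()) {
  spec <- scenario_spec(scenario)
  tmpl_main <- templates[[if (spec$main_species == "orange") "orange"
                          else "grapefruit"]]
  tmpl_adu <- templates[[switch(spec$adulterant, mandarin = "mandarin",
                                `pomelo-SG` = "pomelo-SG",
                                `pomelo-WG` = "pomelo-WG")]]
  draw <- function(tmpl, n, seed, tag)
    sample_profiles(tmpl, sim_config(seed = seed, n_cultivars = n, cv = cv,
                                     correlation = correlation),
                    cultivar_prefix = paste0(tmpl$label, "_", tag))
  main_tr <- draw(tmpl_main, n_train, seed, "train")
  adu_tr <- draw(tmpl_adu, n_train, seed + 1L, "train")
  main_te <- draw(tmpl_main, n_test, seed + 2L, "test")
  adu_te <- draw(tmpl_adu, n_test, seed + 3L, "test")
  train <- generate_blends(main_tr, adu_tr, spec$purity_levels,
                           include_pure_main = TRUE,
                           include_pure_adulterant = spec$include_pure_adulterant)
  test <- generate_blends(main_te, adu_te, spec$purity_levels,
                          include_pure_main = TRUE,
                          include_pure_adulterant = spec$include_pure_adulterant)
  model <- train_purity_model(train, scenario)
  list(model = model, evaluation = evaluate_model(model, test),
       train_blends = train, test_blends = test)
}
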