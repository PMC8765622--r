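# End-to-end pipeline on a synthetic world: clean occurrences, filter
# predictors, build the pseudo-absence design, fit the gated ensemble, build
# per-scenario consensus climates, project suitability, apply the edaphic
# rules, zone the landscape and account the areas.

#' Run the full adaptation-zoning pipeline on a synthetic world
#'
#' @param world a [simulate_world()] result (generated from `config` when
#'   `NULL`).
#' @param config a [world_config()] used when `world` is `NULL`.
#' @param predictors predictor set used for modelling. The default forces the
#'   six named bioclimatic variables the study design fixes (mean diurnal
#'   range, isothermality, mean temperatures of the wettest and driest
#'   quarters, precipitation of the driest month, precipitation seasonality);
#'   `NULL` uses whatever [correlation_filter()] keeps. The filter is computed
#'   and recorded either way; forced names missing from the stack fall back to
#'   the filter outcome.
#' @param learners learner names for the ensemble.
#' @param n_pseudo_absences pseudo-absences to sample (default 300).
#' @param train_fraction training fraction (default 0.75).
#' @param tss_gate ensemble TSS gate (default 0.7).
#' @param sre_q surface-range-envelope trim quantile (default 0.025).
#' @param anova_n cells sampled for the territory/scenario ANOVA.
#' @param seed integer seed for every stochastic stage downstream of the
#'   generator.
#' @return An `adaptation_zoning` list: the inputs plus `selection`,
#'   `ensemble`, `suitability` (per scenario), `soil_mask`, `prevalence`,
#'   `zone_maps`, `zone_table`, `change_stats`, `anova`, `importance`.
#' @export
run_zoning_pipeline <- function(world = NULL, config = world_config(),
                                predictors = c("bio2", "bio3", "bio8", "bio9",
                                               "bio14", "bio15"),
                                learners = c("sre", "linear", "flexible",
                                             "smooth"),
                                n_pseudo_absences = 300,
                                train_fraction = 0.75, tss_gate = 0.7,
                                sre_q = 0.025, anova_n = 1000,
                                seed = config$seed) {
  if (is.null(world)) world <- simulate_world(config)
  grid <- world$current$grid

  occ <- clean_occurrences(world$occurrences, grid = grid)
  selection <- correlation_filter(world$current)
  use <- if (!is.null(predictors) &&
             all(predictors %in% names(world$current$layers))) {
    canonical_order(predictors)
  } else selection$kept
  current_sel <- select_layers(world$current, use)

  envelope <- fit_envelope(occ, current_sel, q = sre_q)
  pa <- sample_pseudo_absences(envelope, current_sel, occ,
                               n = n_pseudo_absences, seed = seed)
  ensemble <- fit_sdm_ensemble(pa, learners = learners,
                               train_fraction = train_fraction,
                               tss_gate = tss_gate, sre_q = sre_q, seed = seed)

  suitability <- list(current = predict(ensemble, current_sel,
                                        scenario_label = "current"))
  for (sc in names(world$future)) {
    consensus <- gcm_consensus(lapply(world$future[[sc]], select_layers,
                                      keep = use),
                               source_label = sc)
    suitability[[sc]] <- predict(ensemble, consensus, scenario_label = sc)
  }

  soil_mask <- soil_suitability_mask(world$soil, world$territory,
                                     world$protected)
  prevalence <- classify_prevalence(world$production)

  zone_maps <- list(current = build_zone_map(suitability$current, NULL,
                                             prevalence, world$municipalities,
                                             soil_mask, "current"))
  for (sc in setdiff(names(suitability), "current")) {
    zone_maps[[sc]] <- build_zone_map(suitability$current, suitability[[sc]],
                                      prevalence, world$municipalities,
                                      soil_mask, sc)
  }
  ztab <- tabulate_zones(zone_maps, grid)
  cstats <- derived_change_stats(ztab)

  # per-cell suitability on the soil mask, by territory and scenario
  mask_cells <- which(soil_mask$values == 1)
  set.seed(seed)
  cells <- if (length(mask_cells) > anova_n) sample(mask_cells, anova_n) else
    mask_cells
  terr <- world$territory$categories[world$territory$values[cells]]
  samples <- do.call(rbind, lapply(names(suitability), function(sc)
    data.frame(value = suitability[[sc]]$values[cells], territory = terr,
               scenario = sc)))
  anova <- suitability_anova(samples)

  importance <- variable_importance(ensemble, current_sel, seed = seed)

  structure(list(world = world, occurrences = occ, selection = selection,
                 envelope = envelope, pa = pa, ensemble = ensemble,
                 suitability = suitability, soil_mask = soil_mask,
                 prevalence = prevalence, zone_maps = zone_maps,
                 zone_table = ztab, change_stats = cstats, anova = anova,
                 importance = importance, seed = seed),
            class = "adaptation_zoning")
}

#' @export
print.adaptation_zoning <- function(x, ...) {
  cat("<adaptation_zoning>\n")
  cat("  predictors used:", paste(x$ensemble$predictors, collapse = ", "), "\n")
  ev <- x$ensemble$evaluations
  cat("  ensemble members:",
      paste(sprintf("%s (TSS %.2f)", ev$learner[ev$included],
                    ev$tss[ev$included]), collapse = ", "), "\n")
  cat("  suitable soil:", format(attr(x$zone_table, "total_km2")), "km2\n")
  cat("  combined intensification+expansion share by scenario:\n")
  print(x$change_stats$per_scenario[, c("scenario", "intensification_expansion")],
        row.names = FALSE)
  invisible(x)
}

#' Reference zone-area accounting for the Brazilian Amazon cocoa analysis
#'
#' The published km2 areas of the five adaptation zones over the suitable-soil
#' mask of the Brazilian Amazon biome, for current conditions and the 2050
#' RCP4.5 / RCP8.5 consensus climates. Used as the replay input for
#' [zone_table_from_areas()] and [derived_change_stats()].
#'
#' @return Data frame `scenario`, `zone`, `area_km2` (15 rows).
#' @export
reference_zone_areas <- function() {
  path <- system.file("extdata", "amazon_cocoa_zone_areas.csv",
                      package = "cocoazone", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
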