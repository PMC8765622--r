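# Area accounting per zone and scenario, derived change statistics on the
# printed scale, and the territory-by-scenario analysis of variance.

#' Tabulate zone areas per scenario
#'
#' Areas come from the constant per-cell area; percentages are taken against
#' the common mask total and rounded half-up to 2 decimals. All five zones are
#' reported for every scenario, zeros included. All zone maps must cover the
#' identical mask.
#'
#' @param zone_maps named list (scenario -> `zone_map`).
#' @param grid the shared [grid_spec()].
#' @return A `zone_table` data frame (`scenario`, `zone`, `area_km2`,
#'   `percent`) with a `total_km2` attribute.
#' @export
tabulate_zones <- function(zone_maps, grid) {
  stopifnot(length(zone_maps) >= 1)
  ref_mask <- !is.na(zone_maps[[1]]$values)
  rows <- list()
  for (sc in names(zone_maps)) {
    zm <- zone_maps[[sc]]
    if (!same_grid(grid, zm$grid)) stop("zone map '", sc, "' on a different grid")
    if (!identical(!is.na(zm$values), ref_mask))
      stop("zone map '", sc, "' covers a different mask")
    counts <- tabulate(zm$values[!is.na(zm$values)], nbins = length(ZONES))
    area <- counts * grid$cell_area_km2
    total <- sum(area)
    rows[[sc]] <- data.frame(scenario = sc, zone = ZONES, area_km2 = area,
                             percent = round_half_up(100 * area / total, 2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, total_km2 = sum(ref_mask) * grid$cell_area_km2,
            class = c("zone_table", "data.frame"))
}

#' Assemble a zone table from per-zone areas
#'
#' The replay path: printed or externally computed areas (km2) per scenario
#' and zone are turned into the same `zone_table` that [tabulate_zones()]
#' produces, with percentages recomputed from the areas.
#'
#' @param areas data frame `scenario`, `zone`, `area_km2`; zones missing for a
#'   scenario are filled with 0.
#' @return A `zone_table`.
#' @export
zone_table_from_areas <- function(areas) {
  stopifnot(all(c("scenario", "zone", "area_km2") %in% names(areas)))
  bad <- setdiff(unique(areas$zone), ZONES)
  if (length(bad)) stop("unknown zones: ", paste(bad, collapse = ", "))
  scen <- unique(areas$scenario)
  rows <- lapply(scen, function(sc) {
    a <- areas[areas$scenario == sc, ]
    full <- stats::setNames(rep(0, length(ZONES)), ZONES)
    full[a$zone] <- a$area_km2
    data.frame(scenario = sc, zone = ZONES, area_km2 = as.numeric(full),
               percent = round_half_up(100 * full / sum(full), 2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  totals <- vapply(scen, function(sc)
    sum(out$area_km2[out$scenario == sc]), 0)
  structure(out, total_km2 = unname(totals[1]),
            class = c("zone_table", "data.frame"))
}

zt_share <- function(tab, scenario, zones) {
  # combined share of one or more zones, from summed areas, half-up 2 dp
  sel <- tab$scenario == scenario
  round_half_up(100 * sum(tab$area_km2[sel & tab$zone %in% zones]) /
                  sum(tab$area_km2[sel]), 2)
}

#' Derived change statistics between scenarios
#'
#' Everything is expressed on the printed scale (percent of the suitable-soil
#' area, half-up to 2 decimals) and all differences are percentage points of
#' those shares, not relative changes. Combined shares (e.g. intensification +
#' expansion) are computed from summed areas before rounding; differences are
#' taken between the rounded shares.
#'
#' @param tab a `zone_table` containing a `"current"` scenario and at least
#'   one future scenario.
#' @return A `change_stats` list: `per_scenario` (combined
#'   intensification+expansion and diversification+conversion shares, the
#'   not-recommended share), `vs_current` (percentage-point drops in
#'   intensification+expansion and rises in not-recommended per future
#'   scenario) and `between_futures` (per-zone share gaps for each pair of
#'   future scenarios).
#' @export
derived_change_stats <- function(tab) {
  scen <- unique(tab$scenario)
  if (!"current" %in% scen) stop("table must contain a 'current' scenario")
  futures <- setdiff(scen, "current")
  per_scenario <- do.call(rbind, lapply(scen, function(sc) data.frame(
    scenario = sc,
    intensification_expansion = zt_share(tab, sc, c("intensification", "expansion")),
    diversification_conversion = zt_share(tab, sc, c("diversification", "conversion")),
    not_recommended = zt_share(tab, sc, "not_recommended"))))
  cur <- per_scenario[per_scenario$scenario == "current", ]
  vs_current <- do.call(rbind, lapply(futures, function(sc) {
    f <- per_scenario[per_scenario$scenario == sc, ]
    data.frame(
      scenario = sc,
      intensification_expansion_drop_pp =
        round_half_up(cur$intensification_expansion - f$intensification_expansion, 2),
      not_recommended_rise_pp =
        round_half_up(f$not_recommended - cur$not_recommended, 2))
  }))
  between_futures <- NULL
  if (length(futures) >= 2) {
    pairs <- utils::combn(futures, 2, simplify = FALSE)
    between_futures <- do.call(rbind, lapply(pairs, function(p) {
      do.call(rbind, lapply(ZONES, function(z) data.frame(
        scenario_a = p[1], scenario_b = p[2], zone = z,
        share_gap_pp = round_half_up(zt_share(tab, p[1], z) -
                                       zt_share(tab, p[2], z), 2))))
    }))
  }
  structure(list(per_scenario = per_scenario, vs_current = vs_current,
                 between_futures = between_futures),
            class = "change_stats")
}

#' @export
print.change_stats <- function(x, ...) {
  cat("Combined zone shares (% of suitable-soil area):\n")
  print(x$per_scenario, row.names = FALSE)
  cat("\nChange vs current (percentage points):\n")
  print(x$vs_current, row.names = FALSE)
  if (!is.null(x$between_futures)) {
    cat("\nGaps between future scenarios (percentage points):\n")
    print(x$between_futures, row.names = FALSE)
  }
  invisible(x)
}

#' Two-way ANOVA of suitability over territories and scenarios
#'
#' Fixed-effects two-way analysis of variance without interaction
#' (`value ~ territory + scenario`), the standard test for whether suitability
#' differs between planning territories and between climate scenarios.
#'
#' @param samples data frame with numeric `value` and factors `territory`
#'   and `scenario`; a factor with a single level is dropped, degenerating to
#'   the classical one-way analysis (both single-level is an error). Each
#'   factor combination needs at least two observations.
#' @return An `anova_result` data frame: `term`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic`, `p_value` (one row per factor plus residuals). Constant
#'   responses carry no evidence against either factor and report F = 0,
#'   p = 1.
#' @export
suitability_anova <- function(samples) {
  stopifnot(all(c("value", "territory", "scenario") %in% names(samples)))
  samples$territory <- factor(samples$territory)
  samples$scenario <- factor(samples$scenario)
  terms <- c("territory", "scenario")[c(nlevels(samples$territory) > 1,
                                        nlevels(samples$scenario) > 1)]
  if (length(terms) == 0) stop("need >= 2 levels for at least one factor")
  if (any(table(samples$territory, samples$scenario) < 2))
    stop("need >= 2 observations per factor combination")
  fit <- stats::aov(stats::as.formula(paste("value ~",
                                            paste(terms, collapse = " + "))),
                    data = samples)
  s <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(s)), df = s$Df,
                    sum_sq = s$`Sum Sq`, mean_sq = s$`Mean Sq`,
                    statistic = s$`F value`, p_value = s$`Pr(>F)`,
                    row.names = NULL)
  if (sum(out$sum_sq) < 1e-12) {  # constant response: no effect, no evidence
    eff <- out$term != "Residuals"
    out$statistic[eff] <- 0
    out$p_value[eff] <- 1
  }
  structure(out, class = c("anova_result", "data.frame"))
}
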