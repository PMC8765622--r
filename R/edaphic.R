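# Soil-by-infrastructure suitability: stoniness, fertility, territory and
# protected-area exclusions combined into one boolean mask.

#' Bundle soil attribute layers into a soil map
#'
#' @param reference_group categorical `ec_layer` with categories
#'   `Acrisol`, `Fluvisol`, `Nitosol`, `Ferralsol`, `Other`.
#' @param trophic categorical `ec_layer` with categories `eutrophic`,
#'   `dystrophic` (at least 50% vs less of the cation exchange capacity
#'   occupied by nutrient cations).
#' @param stoniness categorical `ec_layer` with categories `low`, `high`.
#' @return A `soil_map` carrying the three aligned attribute layers.
#' @export
soil_map <- function(reference_group, trophic, stoniness) {
  g <- reference_group$grid
  if (!same_grid(g, trophic$grid) || !same_grid(g, stoniness$grid))
    stop("soil attribute layers are not aligned")
  for (l in list(reference_group, trophic, stoniness)) {
    if (is.null(l$categories)) stop("soil attribute '", l$name,
                                    "' must be categorical")
  }
  structure(list(grid = g, reference_group = reference_group,
                 trophic = trophic, stoniness = stoniness),
            class = "soil_map")
}

#' Soil-by-infrastructure suitability mask
#'
#' A cell is suitable for cocoa iff its soil reference group is one of
#' Acrisol, Fluvisol, Nitosol or Ferralsol, stoniness is low, and either the
#' soil is eutrophic (high fertility, viable in every territory) or it is
#' dystrophic but lies in the network territory (where infrastructure keeps
#' fertilizer and transport costs viable) - and the cell is not inside a
#' protected area (indigenous lands and conservation units, merged).
#'
#' @param soil a [soil_map()].
#' @param territory categorical `ec_layer` with categories `network`,
#'   `border`, `zone`.
#' @param protected boolean `ec_layer` (1 = protected).
#' @return An `ec_layer` whose values are 1 (suitable) / 0, `NA` where any
#'   input is nodata.
#' @export
soil_suitability_mask <- function(soil, territory, protected) {
  g <- soil$grid
  if (!same_grid(g, territory$grid) || !same_grid(g, protected$grid))
    stop("layers are not aligned")
  lab <- function(layer) {
    m <- layer$values
    matrix(layer$categories[m], nrow(m), ncol(m))
  }
  ref <- lab(soil$reference_group)
  tro <- lab(soil$trophic)
  sto <- lab(soil$stoniness)
  ter <- lab(territory)
  prot <- protected$values
  suitable <- (ref %in% c("Acrisol", "Fluvisol", "Nitosol", "Ferralsol")) &
    (sto == "low") &
    ((tro == "eutrophic") | (tro == "dystrophic" & ter == "network")) &
    !(prot == 1)
  out <- matrix(as.numeric(suitable), g$n_rows, g$n_cols)
  out[is.na(ref) | is.na(tro) | is.na(sto) | is.na(ter) | is.na(prot)] <- NA
  new_layer(g, "soil_suitable", out)
}

#' Summarise a suitability mask
#'
#' @param mask boolean `ec_layer` from [soil_suitability_mask()].
#' @param grid the shared [grid_spec()].
#' @return List with `suitable_km2` and `percent_of_grid` (of non-nodata
#'   cells, half-up to 2 decimals).
#' @export
soil_summary <- function(mask, grid) {
  suit <- total_area_km2(mask, grid)
  tot <- sum(!is.na(mask$values)) * grid$cell_area_km2
  list(suitable_km2 = suit,
       percent_of_grid = round_half_up(100 * suit / tot, 2))
}
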