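# Suitability-class discretization, crop-prevalence classification from
# production rankings, and the decision table assigning adaptation zones.

SUITABILITY_CLASSES <- c("VL", "LM", "MH")   # <20%, 20-50%, >50%
PREVALENCE_CLASSES <- c("dominant", "present", "absent")
ZONES <- c("intensification", "expansion", "diversification", "conversion",
           "not_recommended")

#' Discretize suitability into three classes
#'
#' Cuts at 0.20 and 0.50: values below 0.20 are very low (`VL`), values from
#' 0.20 to 0.50 inclusive are low-to-medium (`LM`), values above 0.50 are
#' medium-to-high (`MH`). Both boundary values fall in `LM`.
#'
#' @param x a `suitability_map` / `ec_layer`, or a numeric vector, with values
#'   in \[0,1\] (`NA` passed through).
#' @return For a layer input, a categorical `ec_layer` with categories
#'   `VL`, `LM`, `MH`; for a vector, a factor with those levels.
#' @export
classify_suitability <- function(x) {
  if (inherits(x, "ec_layer")) {
    v <- x$values
    cls <- classify_suitability(as.vector(v))
    return(new_layer(x$grid, paste0(x$name, "_class"),
                     matrix(as.integer(cls), nrow(v), ncol(v)),
                     categories = SUITABILITY_CLASSES))
  }
  v <- as.numeric(x)
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("suitability outside [0,1]")
  factor(ifelse(v < 0.20, "VL", ifelse(v <= 0.50, "LM", "MH")),
         levels = SUITABILITY_CLASSES)
}

#' Classify municipal cocoa prevalence from production rankings
#'
#' Crops are ranked within each municipality by production value, descending,
#' ties sharing the better (minimum) rank. Cocoa ranked first or second with
#' positive production is `dominant`; ranked third or below with positive
#' production is `present`; zero production or no cocoa row is `absent`.
#'
#' @param production data frame `municipality_id`, `crop_name`,
#'   `production_value` (non-negative; at most one row per municipality-crop).
#' @return Named factor (levels `dominant`, `present`, `absent`) indexed by
#'   municipality id.
#' @export
classify_prevalence <- function(production) {
  stopifnot(all(c("municipality_id", "crop_name", "production_value")
                %in% names(production)))
  if (any(production$production_value < 0)) stop("negative production values")
  if (anyDuplicated(production[, c("municipality_id", "crop_name")]))
    stop("more than one row per (municipality, crop)")
  out <- tapply(seq_len(nrow(production)), production$municipality_id,
                function(i) {
    vals <- production$production_value[i]
    crops <- production$crop_name[i]
    cocoa <- vals[crops == "cocoa"]
    if (length(cocoa) == 0 || cocoa == 0) return("absent")
    rk <- rank(-vals, ties.method = "min")[crops == "cocoa"]
    if (rk <= 2) "dominant" else "present"
  })
  stats::setNames(factor(unlist(out), levels = PREVALENCE_CLASSES), names(out))
}

#' Assign adaptation zones from current/future suitability and prevalence
#'
#' The decision table, checked in order:
#' 1. future `MH`, current `MH`, prevalence dominant -> intensification;
#' 2. future `MH`, current `MH`, prevalence present/absent -> expansion;
#' 3. future `LM`, current `LM`/`MH`, prevalence dominant/present ->
#'    diversification;
#' 4. future `VL`, current `LM`/`MH`, prevalence dominant/present ->
#'    conversion;
#' 5. future `VL`, prevalence absent -> not recommended;
#' 6. completion for the remaining combinations: future `MH` -> expansion
#'    unless current is `VL` (then not recommended); future `LM` or `VL` ->
#'    not recommended.
#'
#' The function is total: every (current, future, prevalence) triple yields
#' exactly one zone. Cells resolved by the completion rule are flagged in the
#' `completion_fired` attribute so its footprint is auditable.
#'
#' @param current,future suitability classes (`VL`/`LM`/`MH`), recycled to a
#'   common length.
#' @param prevalence prevalence classes (`dominant`/`present`/`absent`).
#' @return Factor of zones with attribute `completion_fired` (logical).
#' @export
assign_zone <- function(current, future, prevalence) {
  n <- max(length(current), length(future), length(prevalence))
  cur <- as.character(rep_len(current, n))
  fut <- as.character(rep_len(future, n))
  prev <- as.character(rep_len(prevalence, n))
  stopifnot(all(cur %in% SUITABILITY_CLASSES | is.na(cur)),
            all(fut %in% SUITABILITY_CLASSES | is.na(fut)),
            all(prev %in% PREVALENCE_CLASSES | is.na(prev)))
  zone <- rep(NA_character_, n)
  completion <- rep(FALSE, n)
  open <- function() is.na(zone) & !is.na(cur) & !is.na(fut) & !is.na(prev)
  r1 <- open() & fut == "MH" & cur == "MH" & prev == "dominant"
  zone[r1] <- "intensification"
  r2 <- open() & fut == "MH" & cur == "MH"
  zone[r2] <- "expansion"
  r3 <- open() & fut == "LM" & cur %in% c("LM", "MH") & prev != "absent"
  zone[r3] <- "diversification"
  r4 <- open() & fut == "VL" & cur %in% c("LM", "MH") & prev != "absent"
  zone[r4] <- "conversion"
  r5 <- open() & fut == "VL" & prev == "absent"
  zone[r5] <- "not_recommended"
  r6 <- open()
  completion[r6] <- TRUE
  zone[r6 & fut == "MH" & cur != "VL"] <- "expansion"
  zone[r6 & fut == "MH" & cur == "VL"] <- "not_recommended"
  zone[r6 & fut %in% c("LM", "VL")] <- "not_recommended"
  structure(factor(zone, levels = ZONES), completion_fired = completion)
}

#' Current-scenario zoning from a single suitability column
#'
#' Single-period variant used for the current-conditions map: `MH` + dominant
#' -> intensification; `MH` + present/absent -> expansion; `LM` +
#' dominant/present -> diversification; `VL` + dominant/present -> conversion;
#' `LM`/`VL` + absent -> not recommended.
#'
#' @param current suitability classes.
#' @param prevalence prevalence classes.
#' @return Factor of zones.
#' @export
current_zoning <- function(current, prevalence) {
  n <- max(length(current), length(prevalence))
  cur <- as.character(rep_len(current, n))
  prev <- as.character(rep_len(prevalence, n))
  zone <- rep(NA_character_, n)
  ok <- !is.na(cur) & !is.na(prev)
  zone[ok & cur == "MH" & prev == "dominant"] <- "intensification"
  zone[ok & cur == "MH" & prev != "dominant"] <- "expansion"
  zone[ok & cur == "LM" & prev != "absent"] <- "diversification"
  zone[ok & cur == "VL" & prev != "absent"] <- "conversion"
  zone[ok & cur %in% c("LM", "VL") & prev == "absent"] <- "not_recommended"
  factor(zone, levels = ZONES)
}

#' Build a zone map over the suitable-soil mask
#'
#' Per cell on the soil mask: the cell's municipality prevalence is looked up
#' (undefined municipalities are treated as absent and reported), both
#' suitability maps are discretized, and the decision table is applied -
#' [current_zoning()] when `scenario_label` is `"current"`, [assign_zone()]
#' otherwise. Cells off the mask are nodata.
#'
#' @param suit_current current-scenario `suitability_map`.
#' @param suit_future future-scenario `suitability_map` (ignored for the
#'   current-scenario map; may be `NULL` then).
#' @param prevalence named factor from [classify_prevalence()].
#' @param municipalities categorical `ec_layer` of municipality ids.
#' @param soil_mask boolean `ec_layer` from [soil_suitability_mask()].
#' @param scenario_label scenario of the map (`"current"` selects the
#'   single-column table).
#' @return A `zone_map`: categorical `ec_layer` (codes 1..5 =
#'   intensification, expansion, diversification, conversion,
#'   not_recommended) with the scenario label and a `completion_n` attribute.
#' @export
build_zone_map <- function(suit_current, suit_future, prevalence,
                           municipalities, soil_mask, scenario_label) {
  g <- suit_current$grid
  for (l in list(municipalities, soil_mask))
    if (!same_grid(g, l$grid)) stop("layers are not aligned")
  if (!identical(scenario_label, "current")) {
    if (is.null(suit_future)) stop("future suitability required")
    if (!same_grid(g, suit_future$grid)) stop("layers are not aligned")
  }
  mun_ids <- municipalities$categories[as.vector(municipalities$values)]
  prev <- as.character(prevalence[mun_ids])
  undefined <- !is.na(mun_ids) & (is.na(prev) | !mun_ids %in% names(prevalence))
  if (any(undefined)) {
    message(length(unique(mun_ids[undefined])),
            " municipality(ies) without prevalence treated as absent")
    prev[undefined] <- "absent"
  }
  cur_cls <- classify_suitability(as.vector(suit_current$values))
  on_mask <- as.vector(soil_mask$values) == 1 & !is.na(as.vector(soil_mask$values))
  completion_n <- 0L
  if (identical(scenario_label, "current")) {
    zone <- current_zoning(cur_cls, prev)
  } else {
    fut_cls <- classify_suitability(as.vector(suit_future$values))
    zone <- assign_zone(cur_cls, fut_cls, prev)
    completion_n <- sum(attr(zone, "completion_fired")[on_mask], na.rm = TRUE)
    if (completion_n > 0)
      message("completion rule fired on ", completion_n, " masked cell(s) [",
              scenario_label, "]")
  }
  codes <- as.integer(zone)
  codes[!on_mask] <- NA_integer_
  out <- new_layer(g, paste0("zones_", scenario_label),
                   matrix(codes, g$n_rows, g$n_cols), categories = ZONES)
  out$scenario_label <- scenario_label
  attr(out, "completion_n") <- completion_n
  class(out) <- c("zone_map", class(out))
  out
}
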