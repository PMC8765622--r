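# Self-contained synthetic world with known true suitability: correlated
# bioclimatic layers, occurrences drawn from the truth, future scenarios built
# from reported per-variable climate deltas, and the categorical context
# (soil, territories, municipalities, production, protected areas) that the
# edaphic and zoning rules consume.

# Default per-variable climate shifts by 2050: mean diurnal range (bio2, deg C),
# mean temperature of wettest (bio8) and driest (bio9) quarters (deg C),
# precipitation of the driest month (bio14, mm/month), precipitation
# seasonality (bio15, CV units).
default_scenario_deltas <- function() {
  list(
    "RCP4.5" = c(bio2 = 0.25, bio8 = 1.45, bio9 = 2.00, bio14 = -9.0,  bio15 = 4.0),
    "RCP8.5" = c(bio2 = 0.31, bio8 = 2.94, bio9 = 2.67, bio14 = -19.6, bio15 = 7.7)
  )
}

# Plausible climatological scales for the six variables that drive the truth;
# every other bioclim layer gets a generic scale.
default_layer_stats <- function(codes) {
  key <- list(bio2  = c(10, 1.5), bio3 = c(80, 8), bio8 = c(26, 1.5),
              bio9  = c(25, 2.0), bio14 = c(30, 15), bio15 = c(60, 15))
  out <- lapply(codes, function(cd) key[[cd]] %||% c(50, 10))
  names(out) <- codes
  out
}

#' Configuration of the synthetic world
#'
#' Defaults define the reference study conditions: a 120x120 equal-area grid of
#' 25 km2 cells, 19 bioclimatic layers mixed from 6 latent smooth fields, 300
#' occurrences drawn from a known logistic suitability surface, and 5
#' pseudo-GCMs per future scenario shifted by reported warming/drying deltas.
#'
#' @param grid a [grid_spec()].
#' @param n_bioclim number of bioclimatic layers (`bio1..bioN`).
#' @param latent_dim number of independent latent fields; the first
#'   `latent_dim` entries of `names(true_coefficients)` become (near-)pure
#'   copies of them, the remaining layers are strongly loaded mixtures, which
#'   guarantees the collinearity filter real work.
#' @param occurrence_n number of occurrence points.
#' @param true_coefficients named weights of the true suitability function
#'   (logistic in the standardized named layers). Signs encode cocoa ecology:
#'   suitability falls with a hotter dry season and rises with a wetter driest
#'   month, so the default future deltas reduce suitability. Magnitudes are
#'   set so the niche is sharply structured rather than diffuse.
#' @param true_intercept intercept of the logistic truth; the default -4
#'   makes high suitability a minority feature of the landscape (about a
#'   quarter of cells above 0.5), as for a crop with a well-defined niche.
#' @param scenario_deltas named list (scenario -> named additive shifts).
#' @param n_gcms pseudo-GCMs per scenario.
#' @param gcm_noise_sd per-cell standard deviation of GCM disagreement, in the
#'   native units of each variable.
#' @param n_municipalities number of Voronoi municipalities.
#' @param seed integer seed; all generator output is reproducible given
#'   (config, seed).
#' @return A `world_config` list.
#' @export
world_config <- function(grid = grid_spec(120, 120, cell_size = 5),
                         n_bioclim = 19,
                         latent_dim = 6,
                         occurrence_n = 300,
                         true_coefficients = c(bio2 = -2.4, bio3 = 1.8,
                                               bio8 = -1.5, bio9 = -3.0,
                                               bio14 = 3.6, bio15 = -2.1),
                         true_intercept = -4,
                         scenario_deltas = default_scenario_deltas(),
                         n_gcms = 5,
                         gcm_noise_sd = 0.25,
                         n_municipalities = 30,
                         seed = 1L) {
  stopifnot(latent_dim <= n_bioclim, n_gcms >= 1, occurrence_n >= 1,
            n_bioclim >= 1, n_municipalities >= 1)
  structure(list(grid = grid, n_bioclim = n_bioclim, latent_dim = latent_dim,
                 occurrence_n = occurrence_n,
                 true_coefficients = true_coefficients,
                 true_intercept = true_intercept,
                 scenario_deltas = scenario_deltas, n_gcms = n_gcms,
                 gcm_noise_sd = gcm_noise_sd,
                 n_municipalities = n_municipalities, seed = as.integer(seed)),
            class = "world_config")
}

# Smooth standardized random field: white noise low-pass filtered with a
# separable Gaussian kernel of width ~ grid/10 (spatial autocorrelation scale).
smooth_field <- function(n_rows, n_cols, kernel_width = max(n_rows, n_cols) / 10) {
  sigma <- kernel_width / 2
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  smat <- function(n) {
    s <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, i - r):pmin(n, i + r)
      w <- k[j - i + r + 1]
      s[i, j] <- w / sum(w)
    }
    s
  }
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  f <- smat(n_rows) %*% z %*% t(smat(n_cols))
  (f - mean(f)) / stats::sd(f)
}

#' Generate the correlated bioclimatic stack
#'
#' Builds `n_bioclim` layers as linear mixtures of `latent_dim` smooth latent
#' fields plus smooth noise. The layers named by `true_coefficients` are
#' near-pure latents (pairwise low correlation); every other layer loads 0.9 on
#' one latent, so at default settings the stack contains pairs with
#' |Pearson r| > 0.7 for the collinearity filter to remove.
#'
#' @param config a [world_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return An `env_stack` labelled `"current"` with layers `bio1..bioN` in
#'   canonical order, scaled to plausible climatological means and spreads.
#' @export
make_bioclim <- function(config, seed = config$seed) {
  g <- config$grid
  if (config$latent_dim > config$n_bioclim) stop("latent_dim > n_bioclim")
  set.seed(seed)
  codes <- paste0("bio", seq_len(config$n_bioclim))
  pure <- names(config$true_coefficients)
  pure <- pure[pure %in% codes][seq_len(min(config$latent_dim, length(pure)))]
  if (length(pure) < config$latent_dim)
    pure <- c(pure, setdiff(codes, pure)[seq_len(config$latent_dim - length(pure))])
  latents <- lapply(seq_len(config$latent_dim),
                    function(i) smooth_field(g$n_rows, g$n_cols))
  stats_by_code <- default_layer_stats(codes)
  mixture_codes <- setdiff(codes, pure)
  fields <- vector("list", length(codes)); names(fields) <- codes
  for (i in seq_along(pure)) {
    eps <- smooth_field(g$n_rows, g$n_cols)
    fields[[pure[i]]] <- sqrt(1 - 0.3^2) * latents[[i]] + 0.3 * eps
  }
  for (j in seq_along(mixture_codes)) {
    l <- ((j - 1) %% config$latent_dim) + 1
    eps <- smooth_field(g$n_rows, g$n_cols)
    fields[[mixture_codes[j]]] <- 0.9 * latents[[l]] + sqrt(1 - 0.9^2) * eps
  }
  layers <- lapply(canonical_order(codes), function(cd) {
    ms <- stats_by_code[[cd]]
    z <- fields[[cd]]
    new_layer(g, cd, ms[1] + ms[2] * (z - mean(z)) / stats::sd(z))
  })
  align_stack(layers, source_label = "current")
}

#' Build per-GCM future climate stacks for one scenario
#'
#' Each pseudo-GCM equals the current stack plus the scenario's per-variable
#' additive shift plus zero-mean per-cell Gaussian disagreement noise, so the
#' cross-GCM mean converges to `current + delta` as `noise_sd -> 0`.
#'
#' @param current the current `env_stack`.
#' @param deltas named additive shifts; names must be layer names.
#' @param n_gcms number of stacks to generate.
#' @param noise_sd per-cell noise standard deviation (native units).
#' @param seed integer seed.
#' @param scenario_label label prefixed to each stack's source label.
#' @return A list of `n_gcms` `env_stack`s.
#' @export
make_future <- function(current, deltas, n_gcms = 5, noise_sd = 0.25,
                        seed = 1L, scenario_label = "future") {
  unknown <- setdiff(names(deltas), names(current$layers))
  if (length(unknown))
    stop("unknown layer key in deltas: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  g <- current$grid
  lapply(seq_len(n_gcms), function(gcm) {
    layers <- lapply(names(current$layers), function(nm) {
      d <- if (nm %in% names(deltas)) deltas[[nm]] else 0
      v <- current$layers[[nm]] + d
      if (noise_sd > 0)  # disagreement noise applies to every modelled layer
        v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), nrow(v), ncol(v))
      new_layer(g, nm, v)
    })
    align_stack(layers, source_label = paste0(scenario_label, "/GCM", gcm))
  })
}

#' True suitability surface and occurrences drawn from it
#'
#' True suitability is `plogis()` of `true_intercept` plus a linear form in
#' the standardized layers named by `true_coefficients` (so with all-zero
#' coefficients and zero intercept the surface is uniformly 0.5); occurrences
#' are cells sampled without
#' replacement with probability proportional to true suitability, reported as
#' cell-centre coordinates.
#'
#' @param stack the current `env_stack`.
#' @param config a [world_config()].
#' @param seed seed; defaults to `config$seed`.
#' @return A list with `truth` (an `ec_layer` in \[0,1\]) and `occurrences`
#'   (a data frame `longitude`, `latitude`, `source`).
#' @export
make_truth_and_occurrences <- function(stack, config, seed = config$seed) {
  coefs <- config$true_coefficients
  missing <- setdiff(names(coefs), names(stack$layers))
  if (length(missing))
    stop("true_coefficients reference unknown layers: ",
         paste(missing, collapse = ", "))
  g <- stack$grid
  eta <- matrix(config$true_intercept %||% 0, g$n_rows, g$n_cols)
  for (nm in names(coefs)) {
    v <- stack$layers[[nm]]
    mu <- mean(v, na.rm = TRUE); sd <- stats::sd(as.vector(v), na.rm = TRUE)
    eta <- eta + coefs[[nm]] * (v - mu) / sd
  }
  suit <- stats::plogis(eta)
  truth <- new_layer(g, "true_suitability", suit)
  ok <- which(!is.na(suit))
  if (config$occurrence_n > length(ok))
    stop("occurrence_n exceeds the number of available cells")
  set.seed(seed)
  cells <- sample(ok, config$occurrence_n, prob = suit[ok])
  rc <- arrayInd(cells, dim(suit))
  xy <- cell_centres(g, rc[, 1], rc[, 2])
  occ <- data.frame(longitude = xy$x, latitude = xy$y, source = "synthetic")
  list(truth = truth, occurrences = occ)
}

#' Categorical context layers: soil, territories, municipalities, production,
#' protected areas
#'
#' Soil cells carry a reference group (Acrisol/Fluvisol/Nitosol/Ferralsol/
#' Other), trophic status (eutrophic/dystrophic) and stoniness (low/high) from
#' thresholded smooth fields. Territories are a contiguous three-band
#' network/border/zone partition with smoothly wavering boundaries;
#' municipalities are the Voronoi cells of random seed points; the production
#' table gives each municipality >= 3 perennial crops with values engineered so
#' dominant, present and absent prevalence all occur; the protected mask covers
#' about 10% of cells.
#'
#' @param grid a [grid_spec()].
#' @param seed integer seed.
#' @param n_municipalities number of municipalities.
#' @return A list `soil`, `territory`, `municipalities`, `production`,
#'   `protected`.
#' @export
make_context_layers <- function(grid, seed = 1L, n_municipalities = 30) {
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  qcut <- function(f, probs, labels) {
    cuts <- stats::quantile(f, cumsum(probs)[-length(probs)])
    m <- matrix(findInterval(f, cuts) + 1L, nr, nc)
    new_layer(grid, "tmp", m, categories = labels)
  }
  ref <- qcut(smooth_field(nr, nc), c(0.25, 0.20, 0.15, 0.15, 0.25),
              c("Acrisol", "Fluvisol", "Nitosol", "Ferralsol", "Other"))
  ref$name <- "reference_group"
  trophic <- qcut(smooth_field(nr, nc), c(0.40, 0.60),
                  c("eutrophic", "dystrophic"))
  trophic$name <- "trophic"
  stony <- qcut(smooth_field(nr, nc), c(0.70, 0.30), c("low", "high"))
  stony$name <- "stoniness"
  soil <- soil_map(ref, trophic, stony)

  # three contiguous longitudinal bands with smoothly wavering boundaries:
  # network (consolidated occupation) | border (transitional) | zone (preserved)
  wig1 <- smooth_field(nr, 1, kernel_width = nr / 6)
  wig2 <- smooth_field(nr, 1, kernel_width = nr / 6)
  b1 <- pmin(pmax(round(nc / 3 + 4 * wig1), 2L), nc - 2L)
  b2 <- pmin(pmax(round(2 * nc / 3 + 4 * wig2), b1 + 1L), nc - 1L)
  terr <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    terr[i, ] <- ifelse(seq_len(nc) <= b1[i], 1L,
                        ifelse(seq_len(nc) <= b2[i], 2L, 3L))
  }
  territory <- new_layer(grid, "territory", terr,
                         categories = c("network", "border", "zone"))

  # municipalities: nearest-seed (Voronoi) partition in cell space
  seeds <- cbind(sample(nr, n_municipalities, replace = TRUE),
                 sample(nc, n_municipalities, replace = TRUE))
  seeds <- unique(seeds)
  while (nrow(seeds) < n_municipalities) {
    seeds <- unique(rbind(seeds, c(sample(nr, 1), sample(nc, 1))))
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc); mun <- matrix(0L, nr, nc)
  for (k in seq_len(n_municipalities)) {
    d <- (rows - seeds[k, 1])^2 + (cols - seeds[k, 2])^2
    upd <- d < best
    best[upd] <- d[upd]; mun[upd] <- k
  }
  municipalities <- new_layer(grid, "municipality", mun,
                              categories = sprintf("M%02d", seq_len(n_municipalities)))

  crops <- c("acai", "banana", "coffee", "black_pepper")
  kind <- sample(c("dominant", "present", "absent"), n_municipalities,
                 replace = TRUE, prob = c(0.40, 0.35, 0.25))
  kind[1:3] <- c("dominant", "present", "absent")  # all three classes occur
  production <- do.call(rbind, lapply(seq_len(n_municipalities), function(k) {
    others <- sort(stats::runif(length(crops), 50, 200), decreasing = TRUE)
    cocoa <- switch(kind[k],
                    dominant = others[1] * stats::runif(1, 1.1, 1.5),
                    present  = others[3] * stats::runif(1, 0.3, 0.8),
                    absent   = 0)
    data.frame(municipality_id = sprintf("M%02d", k),
               crop_name = c("cocoa", crops),
               production_value = c(cocoa, others))
  }))
  rownames(production) <- NULL

  prot_f <- smooth_field(nr, nc)
  protected <- new_layer(grid, "protected",
                         (prot_f > stats::quantile(prot_f, 0.9)) * 1)
  list(soil = soil, territory = territory, municipalities = municipalities,
       production = production, protected = protected)
}

#' Generate a complete synthetic world
#'
#' Runs [make_bioclim()], [make_truth_and_occurrences()], [make_future()] for
#' every configured scenario, and [make_context_layers()], all seeded from
#' `config$seed` (sub-stages use fixed offsets of it).
#'
#' @param config a [world_config()].
#' @return A `synthetic_world` list: `config`, `current`, `future` (scenario ->
#'   list of per-GCM stacks), `truth`, `occurrences`, `soil`, `territory`,
#'   `municipalities`, `production`, `protected`.
#' @export
simulate_world <- function(config = world_config()) {
  current <- make_bioclim(config)
  to <- make_truth_and_occurrences(current, config, seed = config$seed + 1L)
  future <- list()
  for (i in seq_along(config$scenario_deltas)) {
    sc <- names(config$scenario_deltas)[i]
    future[[sc]] <- make_future(current, config$scenario_deltas[[sc]],
                                n_gcms = config$n_gcms,
                                noise_sd = config$gcm_noise_sd,
                                seed = config$seed + 10L + i,
                                scenario_label = sc)
  }
  ctx <- make_context_layers(config$grid, seed = config$seed + 2L,
                             n_municipalities = config$n_municipalities)
  structure(c(list(config = config, current = current, future = future,
                   truth = to$truth, occurrences = to$occurrences), ctx),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", x$config$grid$n_rows, "x", x$config$grid$n_cols,
      " grid, ", length(x$current$layers), " bioclim layers, ",
      nrow(x$occurrences), " occurrences, scenarios: ",
      paste(names(x$future), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to a directory
#'
#' Rasters as ESRI ASCII grids, point/production tables as CSV, plus a JSON
#' manifest recording the configuration and seed.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(world$current$layers)) {
    write_raster(new_layer(world$current$grid, nm, world$current$layers[[nm]]),
                 file.path(dir, paste0("current_", nm, ".asc")))
  }
  for (sc in names(world$future)) {
    for (g in seq_along(world$future[[sc]])) {
      st <- world$future[[sc]][[g]]
      for (nm in names(st$layers)) {
        write_raster(new_layer(st$grid, nm, st$layers[[nm]]),
                     file.path(dir, sprintf("%s_gcm%d_%s.asc",
                                            gsub("[^A-Za-z0-9]", "", sc), g, nm)))
      }
    }
  }
  write_raster(world$truth, file.path(dir, "true_suitability.asc"))
  write_raster(world$soil$reference_group, file.path(dir, "soil_reference_group.asc"))
  write_raster(world$soil$trophic, file.path(dir, "soil_trophic.asc"))
  write_raster(world$soil$stoniness, file.path(dir, "soil_stoniness.asc"))
  write_raster(world$territory, file.path(dir, "territory.asc"))
  write_raster(world$municipalities, file.path(dir, "municipalities.asc"))
  write_raster(world$protected, file.path(dir, "protected.asc"))
  utils::write.csv(world$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(world$production, file.path(dir, "production.csv"),
                   row.names = FALSE)
  cfg <- world$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_bioclim = cfg$n_bioclim, latent_dim = cfg$latent_dim,
         occurrence_n = cfg$occurrence_n, n_gcms = cfg$n_gcms,
         gcm_noise_sd = cfg$gcm_noise_sd,
         grid = cfg$grid[c("n_rows", "n_cols", "origin_x", "origin_y",
                           "cell_size", "cell_area_km2")],
         scenario_deltas = cfg$scenario_deltas,
         true_coefficients = as.list(cfg$true_coefficients)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
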