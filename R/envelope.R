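# Surface Range Envelope, pseudo-absence design, and the train/test split.

#' Fit a surface range envelope to presence points
#'
#' Per selected variable, the envelope bounds are the \[q, 1-q\] empirical
#' quantiles of the presence-cell values; with `q = 0` every presence cell lies
#' inside the envelope on all variables. Presences falling on nodata cells are
#' skipped with a warning.
#'
#' @param occurrences data frame with `longitude`, `latitude` (map units of
#'   the stack's grid).
#' @param stack an `env_stack` restricted to the selected predictors.
#' @param q trim quantile (default 0.025).
#' @return An `sre_envelope`: data frame (`variable`, `lower`, `upper`) plus
#'   the trim quantile.
#' @export
fit_envelope <- function(occurrences, stack, q = 0.025) {
  stopifnot(q >= 0, q <= 0.5)
  rc <- points_to_cells(stack$grid, occurrences$longitude, occurrences$latitude)
  idx <- (rc$col - 1L) * stack$grid$n_rows + rc$row
  X <- stack_matrix(stack)[idx, , drop = FALSE]
  on_nodata <- !stats::complete.cases(X) | is.na(idx)
  if (any(on_nodata)) {
    warning(sum(on_nodata), " presence point(s) on nodata cells skipped")
    X <- X[!on_nodata, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("need at least 2 presence points on data cells")
  bounds <- apply(X, 2, stats::quantile, probs = c(q, 1 - q), names = FALSE)
  structure(list(bounds = data.frame(variable = names(stack$layers),
                                     lower = bounds[1, ], upper = bounds[2, ],
                                     row.names = NULL),
                 q = q),
            class = "sre_envelope")
}

#' @export
print.sre_envelope <- function(x, ...) {
  cat("<sre_envelope> q =", x$q, "\n")
  print(x$bounds)
  invisible(x)
}

# Logical vector: does each row of X (columns = envelope variables) lie inside
# the envelope on every variable?
in_envelope <- function(envelope, X) {
  b <- envelope$bounds
  X <- as.matrix(X)[, b$variable, drop = FALSE]
  inside <- rep(TRUE, nrow(X))
  for (j in seq_len(nrow(b))) {
    inside <- inside & X[, j] >= b$lower[j] & X[, j] <= b$upper[j]
  }
  inside & stats::complete.cases(X)
}

#' Sample pseudo-absences outside the presence envelope
#'
#' Eligible cells have data, are not presence cells, and lie outside the
#' envelope (at least one variable beyond its bounds). `n` cells are drawn
#' uniformly without replacement; if fewer than `n` are eligible, all are
#' returned with a `shortfall` flag; zero eligible cells is an error (a
#' smaller trim quantile `q` widens the envelope's complement).
#'
#' @param envelope an [fit_envelope()] result.
#' @param stack the `env_stack` used to fit the envelope.
#' @param occurrences presence points (map units).
#' @param n pseudo-absences requested (default 300).
#' @param seed integer seed.
#' @return A `pa_set` data frame: `row`, `col`, `x`, `y`, one column per
#'   predictor, and `label` in `{presence, pseudo_absence}`; attributes
#'   `n_presence`, `n_pseudo`, `shortfall`, `seed`.
#' @export
sample_pseudo_absences <- function(envelope, stack, occurrences, n = 300,
                                   seed = 1L) {
  g <- stack$grid
  X <- stack_matrix(stack)
  rc <- points_to_cells(g, occurrences$longitude, occurrences$latitude)
  pres_idx <- unique((rc$col - 1L) * g$n_rows + rc$row)
  pres_idx <- pres_idx[!is.na(pres_idx)]
  pres_idx <- pres_idx[stats::complete.cases(X[pres_idx, , drop = FALSE])]
  has_data <- stats::complete.cases(X)
  outside <- has_data & !in_envelope(envelope, X)
  eligible <- setdiff(which(outside), pres_idx)
  if (length(eligible) == 0)
    stop("no cells outside the presence envelope; refit with a smaller q")
  shortfall <- length(eligible) < n
  set.seed(seed)
  abs_idx <- if (shortfall) eligible else sample(eligible, n)
  idx <- c(pres_idx, abs_idx)
  rcs <- arrayInd(idx, dim(stack$layers[[1]]))
  xy <- cell_centres(g, rcs[, 1], rcs[, 2])
  out <- data.frame(row = rcs[, 1], col = rcs[, 2], x = xy$x, y = xy$y,
                    X[idx, , drop = FALSE],
                    label = factor(rep(c("presence", "pseudo_absence"),
                                       c(length(pres_idx), length(abs_idx))),
                                   levels = c("presence", "pseudo_absence")))
  structure(out, n_presence = length(pres_idx), n_pseudo = length(abs_idx),
            shortfall = shortfall, seed = seed,
            predictors = names(stack$layers),
            class = c("pa_set", "data.frame"))
}

#' Stratified train/test split of a presence/pseudo-absence set
#'
#' @param pa a `pa_set`.
#' @param train_fraction fraction used for training (default 0.75); per label,
#'   the train count is the fraction rounded to the nearest integer, clamped so
#'   both halves keep both labels.
#' @param seed integer seed.
#' @return A `split_plan`: disjoint `train_rows` and `test_rows` covering all
#'   rows.
#' @export
split_pa <- function(pa, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0)
  if (train_fraction >= 1) stop("train_fraction must leave a non-empty test set")
  labs <- pa$label
  set.seed(seed)
  train <- integer(0)
  for (lv in levels(labs)) {
    rows <- which(labs == lv)
    if (length(rows) < 2) stop("label '", lv, "' has fewer than 2 rows")
    k <- min(max(round(length(rows) * train_fraction), 1L), length(rows) - 1L)
    train <- c(train, sample(rows, k))
  }
  train <- sort(train)
  structure(list(train_rows = train,
                 test_rows = setdiff(seq_len(nrow(pa)), train),
                 train_fraction = train_fraction, seed = seed),
            class = "split_plan")
}
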