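# Occurrence cleaning and collinearity-based predictor selection.

#' Clean raw occurrence records
#'
#' Removes records with miswritten coordinates first (non-numeric, non-finite,
#' or out of range), then collapses exact coordinate duplicates to their first
#' appearance, preserving input order. Both counts are reported in a
#' provenance log.
#'
#' @param records data frame with columns `longitude`, `latitude` and
#'   optionally `source`.
#' @param grid optional [grid_spec()]; when given, valid coordinates are those
#'   inside the grid extent (projected worlds). Otherwise geographic bounds
#'   (\[-180,180\] x \[-90,90\]) apply.
#' @return An `occurrence_set`: the surviving records, with a
#'   `provenance_log` attribute counting `input`, `invalid`, `duplicate`
#'   and `kept`.
#' @export
clean_occurrences <- function(records, grid = NULL) {
  stopifnot(all(c("longitude", "latitude") %in% names(records)))
  if (!"source" %in% names(records))
    records$source <- rep(NA_character_, nrow(records))
  n_in <- nrow(records)
  if (n_in == 0) warning("empty occurrence input")
  lon <- suppressWarnings(as.numeric(records$longitude))
  lat <- suppressWarnings(as.numeric(records$latitude))
  if (is.null(grid)) {
    ok <- is.finite(lon) & is.finite(lat) &
      lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  } else {
    xmax <- grid$origin_x + grid$n_cols * grid$cell_size
    ymax <- grid$origin_y + grid$n_rows * grid$cell_size
    ok <- is.finite(lon) & is.finite(lat) &
      lon >= grid$origin_x & lon < xmax & lat >= grid$origin_y & lat < ymax
  }
  ok[is.na(ok)] <- FALSE
  n_invalid <- sum(!ok)
  kept <- records[ok, , drop = FALSE]
  kept$longitude <- lon[ok]; kept$latitude <- lat[ok]
  dup <- duplicated(kept[, c("longitude", "latitude")])
  n_dup <- sum(dup)
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            provenance_log = c(input = n_in, invalid = n_invalid,
                               duplicate = n_dup, kept = nrow(out)),
            class = c("occurrence_set", "data.frame"))
}

#' Greedy collinearity filter on an environmental stack
#'
#' Pearson correlations are computed over all cells where every layer has
#' data. Constant layers are excluded up front. Then, repeatedly, the pair
#' with the largest |r| above the threshold is found and the member with the
#' larger mean |r| against all currently kept layers is dropped (ties drop the
#' later name in canonical `bio1..bio19` order), until all kept pairs satisfy
#' |r| <= threshold. The result is independent of layer insertion order.
#'
#' @param stack an `env_stack` with >= 2 layers.
#' @param threshold collinearity bound on |Pearson r| (default 0.7).
#' @return A `predictor_selection`: `kept` layer names (canonical order),
#'   `dropped` data frame (`name`, `reason`, `max_abs_r`), and `threshold`.
#' @export
correlation_filter <- function(stack, threshold = 0.7) {
  nms <- canonical_order(names(stack$layers))
  if (length(nms) < 2) stop("need at least 2 layers")
  X <- stack_matrix(select_layers(stack, nms))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  dropped <- data.frame(name = character(), reason = character(),
                        max_abs_r = numeric())
  sds <- apply(X, 2, stats::sd)
  const <- nms[sds == 0 | !is.finite(sds)]
  if (length(const)) {
    dropped <- rbind(dropped, data.frame(name = const, reason = "constant",
                                         max_abs_r = NA_real_))
    nms <- setdiff(nms, const)
  }
  kept <- nms
  repeat {
    if (length(kept) < 2) break
    R <- abs(stats::cor(X[, kept, drop = FALSE]))
    diag(R) <- 0
    mx <- max(R)
    if (mx <= threshold) break
    idx <- which(R == mx, arr.ind = TRUE)[1, ]
    pair <- kept[idx]
    mean_r <- vapply(pair, function(nm) mean(R[nm, setdiff(kept, nm)]), 0)
    drop <- if (abs(diff(mean_r)) > 1e-12) {
      pair[which.max(mean_r)]
    } else {
      # tie: drop the later name in canonical order
      canonical_order(pair)[2]
    }
    dropped <- rbind(dropped, data.frame(name = drop, reason = "collinear",
                                         max_abs_r = mx))
    kept <- setdiff(kept, drop)
  }
  structure(list(kept = kept, dropped = dropped, threshold = threshold),
            class = "predictor_selection")
}

#' @export
print.predictor_selection <- function(x, ...) {
  cat("<predictor_selection> kept ", length(x$kept), " layer(s) at |r| <= ",
      x$threshold, ": ", paste(x$kept, collapse = ", "), "\n", sep = "")
  if (nrow(x$dropped))
    cat("dropped:", paste(x$dropped$name, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a predictor selection as JSON
#'
#' @param selection a `predictor_selection`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `predictor_selection` (read).
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(kept = selection$kept,
                            dropped = selection$dropped,
                            threshold = selection$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dropped <- as.data.frame(x$dropped)
  structure(x, class = "predictor_selection")
}
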