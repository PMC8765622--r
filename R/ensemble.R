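# TSS/AUC evaluation, the gated ensemble model object, suitability projection,
# permutation variable importance, and the GCM consensus.

# True Skill Statistic maximized over all candidate thresholds (midpoints of
# sorted unique scores). Presence is predicted when score > threshold.
tss_stats <- function(scores, labels) {
  pres <- labels == "presence"
  u <- sort(unique(scores))
  if (length(u) < 2)
    return(list(tss = 0, threshold = u[1] %||% NA_real_))
  # midpoints plus one cut beyond each extreme (the no-skill classifiers)
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- -Inf; best_cut <- cuts[1]
  for (ct in cuts) {
    sens <- mean(scores[pres] > ct)
    spec <- mean(scores[!pres] <= ct)
    t <- sens + spec - 1
    if (t > best) { best <- t; best_cut <- ct }
  }
  list(tss = best, threshold = best_cut)
}

# Tie-corrected rank AUC: probability a random presence outscores a random
# pseudo-absence, ties counted half.
rank_auc <- function(scores, labels) {
  pres <- labels == "presence"
  n1 <- sum(pres); n0 <- sum(!pres)
  if (n1 == 0 || n0 == 0) stop("one-class test set")
  r <- rank(scores)
  (sum(r[pres]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted learner on held-out rows
#'
#' TSS is the maximum of sensitivity + specificity - 1 over all candidate
#' thresholds (midpoints of sorted unique scores); AUC is the tie-corrected
#' rank statistic. A learner joins the ensemble when its TSS exceeds the gate.
#'
#' @param model an `sdm_learner`.
#' @param test data frame of held-out rows with both labels.
#' @param tss_gate ensemble-membership gate on TSS (default 0.7).
#' @return A `model_evaluation` one-row data frame: `learner`, `tss`,
#'   `tss_threshold`, `auc`, `included`.
#' @export
evaluate_learner <- function(model, test, tss_gate = 0.7) {
  if (nlevels(droplevels(test$label)) < 2) stop("one-class test set")
  s <- predict(model, test)
  ts <- tss_stats(s, test$label)
  structure(data.frame(learner = model$name, tss = ts$tss,
                       tss_threshold = ts$threshold,
                       auc = rank_auc(s, test$label),
                       included = ts$tss > tss_gate),
            class = c("model_evaluation", "data.frame"))
}

#' Fit a TSS-gated ensemble of suitability learners
#'
#' Splits the presence/pseudo-absence set (stratified by label), fits each
#' registered learner on the training rows, evaluates TSS and AUC on the test
#' rows, and records which learners pass the TSS gate. Projection averages the
#' passing learners' scores cell by cell; projecting with no passing learner
#' fails loudly, listing every learner's TSS.
#'
#' @param pa a [sample_pseudo_absences()] design.
#' @param learners learner names from the registry.
#' @param train_fraction training fraction of the stratified split.
#' @param tss_gate ensemble membership gate on test TSS (default 0.7).
#' @param sre_q trim quantile for the `"sre"` learner.
#' @param seed integer seed driving the split and any stochastic learner.
#' @return An `sdm_ensemble` with `models`, `evaluations`, `split`,
#'   `predictors`, `tss_gate`.
#' @export
fit_sdm_ensemble <- function(pa,
                             learners = c("sre", "linear", "flexible", "smooth"),
                             train_fraction = 0.75, tss_gate = 0.7,
                             sre_q = 0.025, seed = 1L) {
  split <- split_pa(pa, train_fraction, seed = seed)
  train <- pa[split$train_rows, , drop = FALSE]
  test <- pa[split$test_rows, , drop = FALSE]
  predictors <- attr(pa, "predictors") %||%
    setdiff(names(pa), c("label", "row", "col", "x", "y"))
  models <- lapply(learners, function(nm)
    fit_learner(nm, train, predictors = predictors, seed = seed, sre_q = sre_q))
  names(models) <- learners
  evaluations <- do.call(rbind, lapply(models, evaluate_learner, test = test,
                                       tss_gate = tss_gate))
  rownames(evaluations) <- NULL
  structure(list(models = models, evaluations = evaluations, split = split,
                 predictors = predictors, tss_gate = tss_gate, seed = seed),
            class = "sdm_ensemble")
}

ensemble_members <- function(object) {
  object$evaluations$learner[object$evaluations$included]
}

#' Project ensemble suitability
#'
#' Per cell (or row), suitability is the unweighted arithmetic mean of the
#' scores of the learners whose test TSS exceeded the gate.
#'
#' @param object an `sdm_ensemble`.
#' @param newdata an `env_stack` (returns a `suitability_map` layer) or a data
#'   frame / matrix of predictor columns (returns a numeric vector).
#' @param scenario_label label attached to a projected map.
#' @param ... unused.
#' @return A `suitability_map` or numeric scores in \[0,1\].
#' @export
predict.sdm_ensemble <- function(object, newdata, scenario_label = NULL, ...) {
  members <- ensemble_members(object)
  if (length(members) == 0) {
    ev <- object$evaluations
    stop("no learner passed the TSS gate (", object$tss_gate, "): ",
         paste(sprintf("%s=%.3f", ev$learner, ev$tss), collapse = ", "))
  }
  if (inherits(newdata, "env_stack")) {
    X <- as.data.frame(stack_matrix(select_layers(newdata, object$predictors)))
    s <- rowMeans(do.call(cbind, lapply(object$models[members], predict, newdata = X)))
    g <- newdata$grid
    structure(list(grid = g, name = "suitability",
                   values = matrix(s, g$n_rows, g$n_cols),
                   categories = NULL,
                   scenario_label = scenario_label %||% newdata$source_label,
                   member_learners = members),
              class = c("suitability_map", "ec_layer"))
  } else {
    rowMeans(do.call(cbind, lapply(object$models[members], predict,
                                   newdata = as.data.frame(newdata))))
  }
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat("<sdm_ensemble> ", length(x$models), " learner(s), TSS gate ",
      x$tss_gate, "\n", sep = "")
  print(x$evaluations)
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  ev <- object$evaluations
  cat("TSS-gated suitability ensemble\n")
  cat("  training rows:", length(object$split$train_rows),
      " test rows:", length(object$split$test_rows),
      sprintf(" (train fraction %.2f)\n", object$split$train_fraction))
  cat("  predictors:", paste(object$predictors, collapse = ", "), "\n")
  print(ev)
  cat("  ensemble members (TSS >", object$tss_gate, "):",
      paste(ensemble_members(object), collapse = ", "), "\n")
  invisible(ev)
}

#' Plot ensemble evaluations
#'
#' Bar chart of per-learner test TSS with the gate drawn as a reference line.
#'
#' @param x an `sdm_ensemble`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sdm_ensemble <- function(x, ...) {
  ev <- x$evaluations
  bp <- graphics::barplot(ev$tss, names.arg = ev$learner, ylim = c(0, 1),
                          ylab = "test TSS", ...)
  graphics::abline(h = x$tss_gate, lty = 2)
  invisible(bp)
}

#' Permutation variable importance of an ensemble
#'
#' For each predictor, importance is one minus the Pearson correlation between
#' ensemble scores on the original cells and on cells with that predictor's
#' values permuted, averaged over permutations; an unused predictor scores
#' about zero, a fully score-determining one near one.
#'
#' @param object a fitted `sdm_ensemble`.
#' @param stack the `env_stack` to measure importance on.
#' @param n_permutations permutations per variable (default 3).
#' @param seed integer seed.
#' @return Named numeric importances, sorted decreasing.
#' @export
variable_importance <- function(object, stack, n_permutations = 3, seed = 1L) {
  X <- as.data.frame(stack_matrix(select_layers(stack, object$predictors)))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  base <- predict(object, X)
  set.seed(seed)
  imp <- vapply(object$predictors, function(v) {
    mean(vapply(seq_len(n_permutations), function(i) {
      Xp <- X
      Xp[[v]] <- sample(Xp[[v]])
      r <- suppressWarnings(stats::cor(base, predict(object, Xp)))
      if (is.na(r)) r <- 0  # constant permuted scores carry no signal
      1 - r
    }, 0))
  }, 0)
  sort(imp, decreasing = TRUE)
}

#' Consensus of several aligned climate stacks
#'
#' Per layer and cell, the arithmetic mean across stacks (one value per GCM);
#' a cell is nodata in the consensus wherever any member is nodata.
#'
#' @param stacks list of `env_stack`s with identical grids and layer names.
#' @param source_label label for the consensus stack.
#' @return An `env_stack`.
#' @export
gcm_consensus <- function(stacks, source_label = "consensus") {
  stopifnot(length(stacks) >= 1)
  nms <- names(stacks[[1]]$layers)
  g <- stacks[[1]]$grid
  for (s in stacks) {
    if (!setequal(names(s$layers), nms))
      stop("mismatched layer sets across stacks")
    if (!same_grid(g, s$grid)) stop("mismatched grids across stacks")
  }
  layers <- lapply(nms, function(nm) {
    acc <- Reduce(`+`, lapply(stacks, function(s) s$layers[[nm]]))
    new_layer(g, nm, acc / length(stacks))
  })
  align_stack(layers, source_label = source_label)
}

#' Plot a suitability map
#'
#' @param x a `suitability_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.suitability_map <- function(x, ...) {
  g <- x$grid
  graphics::image(
    x = g$origin_x + (seq_len(g$n_cols) - 0.5) * g$cell_size,
    y = g$origin_y + (seq_len(g$n_rows) - 0.5) * g$cell_size,
    z = t(x$values[g$n_rows:1, , drop = FALSE]),
    zlim = c(0, 1), xlab = "x", ylab = "y",
    main = paste("suitability:", x$scenario_label), ...)
  invisible(x)
}
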