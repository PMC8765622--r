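# Shared fixtures, all generated in code.

# Small grid for unit tests.
tiny_grid <- function(n = 10, cell_size = 1) grid_spec(n, n, cell_size = cell_size)

# Constant-valued layer.
const_layer <- function(grid, name, value) {
  new_layer(grid, name, matrix(value, grid$n_rows, grid$n_cols))
}

# Deterministic pseudo-random layer.
rand_layer <- function(grid, name, seed = 1) {
  set.seed(seed)
  new_layer(grid, name, matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                               grid$n_rows, grid$n_cols))
}

# Small synthetic world config for pipeline-level tests (full default size is
# exercised in the acceptance suite).
small_world_config <- function(seed = 1) {
  world_config(grid = grid_spec(60, 60, cell_size = 5),
               occurrence_n = 150, n_gcms = 3, seed = seed)
}

# Build a labelled presence/pseudo-absence table directly (for learner and
# evaluation tests that do not need a raster world).
toy_pa <- function(n_per_class = 60, separation = 3, seed = 1) {
  set.seed(seed)
  x1 <- c(stats::rnorm(n_per_class, separation), stats::rnorm(n_per_class, 0))
  x2 <- c(stats::rnorm(n_per_class, -separation), stats::rnorm(n_per_class, 0))
  structure(
    data.frame(v1 = x1, v2 = x2,
               label = factor(rep(c("presence", "pseudo_absence"),
                                  each = n_per_class),
                              levels = c("presence", "pseudo_absence"))),
    predictors = c("v1", "v2"), class = c("pa_set", "data.frame"))
}

# Independent brute-force oracles for TSS and AUC.
brute_tss <- function(scores, labels) {
  pres <- labels == "presence"
  cuts <- sort(unique(scores))
  cuts <- unique(c(cuts - 1e-9, (cuts[-1] + cuts[-length(cuts)]) / 2,
                   cuts + 1e-9))
  best <- 0
  for (ct in cuts) {
    sens <- mean(scores[pres] > ct)
    spec <- mean(scores[!pres] <= ct)
    best <- max(best, sens + spec - 1)
  }
  best
}

brute_auc <- function(scores, labels) {
  p <- scores[labels == "presence"]
  a <- scores[labels == "pseudo_absence"]
  tot <- 0
  for (i in seq_along(p)) for (j in seq_along(a)) {
    tot <- tot + (p[i] > a[j]) + 0.5 * (p[i] == a[j])
  }
  tot / (length(p) * length(a))
}
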