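# One 3-layer stack with presences placed by hand, reused across SRE tests.
env_world <- function(n = 20, seed = 3) {
  g <- tiny_grid(n)
  st <- align_stack(list(rand_layer(g, "bio1", seed), rand_layer(g, "bio2", seed + 1)))
  st
}

test_that("envelope bounds are presence quantiles", {
  g <- grid_spec(1, 3)
  st <- align_stack(list(new_layer(g, "bio1", matrix(c(1, 2, 3), 1))))
  occ <- data.frame(longitude = c(0.5, 1.5, 2.5), latitude = 0.5)
  env0 <- fit_envelope(occ, st, q = 0)
  expect_equal(env0$bounds$lower, 1)
  expect_equal(env0$bounds$upper, 3)
  env5 <- fit_envelope(occ, st, q = 0.5)
  expect_equal(env5$bounds$lower, env5$bounds$upper)   # degenerate at median
  expect_equal(env5$bounds$lower, 2)
})

test_that("with q = 0.025 about 5% of presences fall outside on one variable", {
  g <- grid_spec(50, 50)
  set.seed(8)
  st <- align_stack(list(rand_layer(g, "bio1", 8)))
  cells <- sample(2500, 400)
  rc <- arrayInd(cells, c(50, 50))
  xy <- cocoazone:::cell_centres(g, rc[, 1], rc[, 2])
  occ <- data.frame(longitude = xy$x, latitude = xy$y)
  env <- fit_envelope(occ, st, q = 0.025)
  X <- cocoazone:::stack_matrix(st)[cells, , drop = FALSE]
  frac_out <- mean(!cocoazone:::in_envelope(env, X))
  expect_gt(frac_out, 0.01); expect_lt(frac_out, 0.12)
})

test_that("presences on nodata cells are skipped with a warning", {
  st <- env_world()
  st$layers$bio1[1, 1] <- NA
  occ <- data.frame(longitude = c(0.5, 3.5, 5.5), latitude = c(19.5, 2.5, 9.5))
  expect_warning(env <- fit_envelope(occ, st, q = 0), "nodata")
  expect_s3_class(env, "sre_envelope")
})

test_that("pseudo-absences come from exactly the cells outside the envelope", {
  g <- grid_spec(1, 4)
  st <- align_stack(list(new_layer(g, "bio1", matrix(c(1, 2, 9, 10), 1))))
  occ <- data.frame(longitude = c(0.5, 1.5), latitude = 0.5)
  env <- fit_envelope(occ, st, q = 0)          # bounds (1,2): cells 3,4 outside
  pa <- sample_pseudo_absences(env, st, occ, n = 2, seed = 1)
  ab <- pa[pa$label == "pseudo_absence", ]
  expect_setequal(ab$bio1, c(9, 10))
  expect_false(attr(pa, "shortfall"))

  short <- sample_pseudo_absences(env, st, occ, n = 5, seed = 1)
  expect_true(attr(short, "shortfall"))
  expect_equal(attr(short, "n_pseudo"), 2)
})

test_that("an all-covering envelope yields a hard error", {
  st <- env_world()
  g <- st$grid
  rc <- arrayInd(seq_len(400), c(20, 20))
  xy <- cocoazone:::cell_centres(g, rc[, 1], rc[, 2])
  occ <- data.frame(longitude = xy$x, latitude = xy$y)  # presences everywhere
  env <- fit_envelope(occ, st, q = 0)
  expect_error(sample_pseudo_absences(env, st, occ, n = 10, seed = 1),
               "smaller q")
})

test_that("pseudo-absence sampling and splitting are seed-reproducible", {
  cfg <- small_world_config()
  w <- simulate_world(cfg)
  sel <- c("bio2", "bio3", "bio8", "bio9", "bio14", "bio15")
  st <- cocoazone:::select_layers(w$current, sel)
  env <- fit_envelope(w$occurrences, st)
  pa1 <- sample_pseudo_absences(env, st, w$occurrences, n = 100, seed = 5)
  pa2 <- sample_pseudo_absences(env, st, w$occurrences, n = 100, seed = 5)
  expect_identical(pa1, pa2)
  # every sampled pseudo-absence lies outside the envelope
  ab <- pa1[pa1$label == "pseudo_absence", ]
  expect_false(any(cocoazone:::in_envelope(env, ab[, sel])))

  sp1 <- split_pa(pa1, seed = 2)
  sp2 <- split_pa(pa1, seed = 2)
  expect_identical(sp1, sp2)
  expect_length(intersect(sp1$train_rows, sp1$test_rows), 0)
  expect_equal(sort(c(sp1$train_rows, sp1$test_rows)), seq_len(nrow(pa1)))
  for (rows in list(sp1$train_rows, sp1$test_rows))
    expect_setequal(unique(as.character(pa1$label[rows])),
                    c("presence", "pseudo_absence"))
})

test_that("split honours per-label fractions and rejects empty test sets", {
  pa <- toy_pa(n_per_class = 100)
  extra <- pa[pa$label == "pseudo_absence", ]
  pa2 <- rbind(pa, extra, extra)   # 100 presences + 300 pseudo-absences
  attr(pa2, "predictors") <- c("v1", "v2")
  sp <- split_pa(pa2, train_fraction = 0.75, seed = 1)
  labs <- pa2$label[sp$train_rows]
  expect_equal(sum(labs == "presence"), 75)
  expect_equal(sum(labs == "pseudo_absence"), 225)
  expect_error(split_pa(pa, train_fraction = 1.0), "non-empty test")
})

test_that("learner registry enforces names and class balance", {
  pa <- toy_pa()
  expect_error(fit_learner("xgbfoo", pa), "unknown learner")
  single <- pa[pa$label == "presence", ]
  expect_error(fit_learner("linear", single), "degenerate")

  sre <- fit_learner("sre", pa)
  expect_true(all(predict(sre, pa) %in% c(0, 1)))
})

test_that("the linear learner separates linearly separable data perfectly", {
  pa <- toy_pa(separation = 8, seed = 2)
  sp <- split_pa(pa, seed = 1)
  m <- fit_learner("linear", pa[sp$train_rows, ])
  ev <- evaluate_learner(m, pa[sp$test_rows, ])
  expect_equal(ev$tss, 1)
  expect_equal(ev$auc, 1)
  expect_true(ev$included)
})

test_that("all four learners respect the score contract", {
  pa <- toy_pa(n_per_class = 80, separation = 2, seed = 4)
  sp <- split_pa(pa, seed = 1)
  for (nm in c("sre", "linear", "flexible", "smooth")) {
    m <- fit_learner(nm, pa[sp$train_rows, ], seed = 9)
    s <- predict(m, pa[sp$test_rows, ])
    expect_true(all(s >= 0 & s <= 1), info = nm)
    m2 <- fit_learner(nm, pa[sp$train_rows, ], seed = 9)
    expect_equal(predict(m2, pa[sp$test_rows, ]), s, info = nm)
  }
})

test_that("evaluation reproduces hand-enumerable TSS and AUC cases", {
  mk_eval <- function(scores, labels) {
    cocoazone:::tss_stats(scores, factor(labels,
                                         levels = c("presence", "pseudo_absence")))
  }
  lab4 <- c("presence", "presence", "pseudo_absence", "pseudo_absence")
  # brute-force over the 3 midpoints gives TSS 0.5; pair counting gives 0.75
  ts <- mk_eval(c(0.9, 0.6, 0.7, 0.2), lab4)
  expect_equal(ts$tss, 0.5)
  expect_equal(cocoazone:::rank_auc(c(0.9, 0.6, 0.7, 0.2),
                                    factor(lab4)), 0.75)
  # perfect separation
  ts2 <- mk_eval(c(0.9, 0.8, 0.3, 0.1), lab4)
  expect_equal(ts2$tss, 1)
  expect_equal(cocoazone:::rank_auc(c(0.9, 0.8, 0.3, 0.1), factor(lab4)), 1)
  # constant scores: no skill
  ts3 <- mk_eval(rep(0.4, 4), lab4)
  expect_equal(ts3$tss, 0)
  expect_equal(cocoazone:::rank_auc(rep(0.4, 4), factor(lab4)), 0.5)
})

test_that("TSS and AUC match brute-force oracles on random score sets", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- factor(sample(c("presence", "pseudo_absence"), n, replace = TRUE),
                     levels = c("presence", "pseudo_absence"))
    if (nlevels(droplevels(labels)) < 2) next
    scores <- round(stats::runif(n), 2)   # provoke ties
    expect_equal(cocoazone:::tss_stats(scores, labels)$tss,
                 brute_tss(scores, labels))
    expect_equal(cocoazone:::rank_auc(scores, labels),
                 brute_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  labels <- factor(rep(c("presence", "pseudo_absence"), each = 20),
                   levels = c("presence", "pseudo_absence"))
  scores <- stats::runif(40)
  a1 <- cocoazone:::rank_auc(scores, labels)
  expect_equal(cocoazone:::rank_auc(stats::qlogis(scores * 0.98 + 0.01), labels), a1)
  expect_equal(cocoazone:::rank_auc(scores^3, labels), a1)
})

test_that("the ensemble averages only gate-passing members", {
  pa <- toy_pa(n_per_class = 80, separation = 4, seed = 6)
  ens <- fit_sdm_ensemble(pa, learners = c("sre", "linear"), seed = 1)
  members <- ens$evaluations$learner[ens$evaluations$included]
  X <- pa[, c("v1", "v2")]
  s <- predict(ens, X)
  per <- vapply(ens$models[members], predict, numeric(nrow(X)), newdata = X)
  expect_equal(s, rowMeans(per))
  expect_true(all(s >= apply(per, 1, min) - 1e-12 &
                  s <= apply(per, 1, max) + 1e-12))
})

test_that("projection fails loudly when no learner passes the gate", {
  pa <- toy_pa(n_per_class = 40, separation = 0, seed = 3)  # no signal
  ens <- fit_sdm_ensemble(pa, learners = c("sre", "linear"), seed = 1,
                          tss_gate = 0.99)
  expect_error(predict(ens, pa[, c("v1", "v2")]), "no learner passed.*sre=")
})

test_that("permutation importance flags used and ignores unused predictors", {
  g <- grid_spec(40, 40)
  st <- align_stack(list(rand_layer(g, "v1", 1), rand_layer(g, "v2", 2)))
  # truth depends only on v1
  suit <- stats::plogis(4 * st$layers$v1)
  set.seed(4)
  cells <- sample(1600, 120, prob = suit)
  rc <- arrayInd(cells, c(40, 40))
  xy <- cocoazone:::cell_centres(g, rc[, 1], rc[, 2])
  occ <- data.frame(longitude = xy$x, latitude = xy$y)
  env <- fit_envelope(occ, st, q = 0.025)
  pa <- sample_pseudo_absences(env, st, occ, n = 120, seed = 1)
  ens <- fit_sdm_ensemble(pa, learners = "linear", tss_gate = 0, seed = 1)
  imp <- variable_importance(ens, st, seed = 2)
  expect_gt(imp[["v1"]], 0.3)
  expect_lt(imp[["v2"]], 0.1)
  expect_identical(variable_importance(ens, st, seed = 2), imp)
})

test_that("gcm consensus is the exact per-cell mean with nodata propagation", {
  g <- tiny_grid(5)
  stacks <- lapply(1:5, function(i)
    align_stack(list(const_layer(g, "bio14", i)), source_label = paste0("g", i)))
  cons <- gcm_consensus(stacks)
  expect_true(all(cons$layers$bio14 == 3))

  one <- gcm_consensus(stacks[3])
  expect_equal(one$layers, stacks[[3]]$layers)

  s2 <- stacks[1:2]
  s2[[2]]$layers$bio14[2, 2] <- NA
  cons2 <- gcm_consensus(s2)
  expect_true(is.na(cons2$layers$bio14[2, 2]))
  expect_equal(sum(is.na(cons2$layers$bio14)), 1)

  # idempotent on identical stacks; commutes with layer selection
  st <- align_stack(list(rand_layer(g, "a", 1), rand_layer(g, "b", 2)))
  expect_equal(gcm_consensus(list(st, st))$layers, st$layers)
  both <- gcm_consensus(list(st, st))
  expect_equal(cocoazone:::select_layers(both, "a")$layers,
               gcm_consensus(list(cocoazone:::select_layers(st, "a"),
                                  cocoazone:::select_layers(st, "a")))$layers)

  bad <- align_stack(list(rand_layer(g, "c", 3)))
  expect_error(gcm_consensus(list(st, bad)), "mismatched layer sets")
})
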