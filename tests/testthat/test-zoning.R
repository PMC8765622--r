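test_that("suitability classes follow the 20%/50% cuts with both bounds in LM", {
  expect_equal(as.character(classify_suitability(c(0.55, 0.50, 0.19, 0.20, 0))),
               c("MH", "LM", "VL", "LM", "VL"))
  expect_error(classify_suitability(1.2), "outside")
  g <- grid_spec(1, 3)
  lay <- classify_suitability(new_layer(g, "s", matrix(c(0.1, 0.3, 0.9), 1)))
  expect_equal(lay$categories[as.vector(lay$values)], c("VL", "LM", "MH"))
})

test_that("prevalence follows the production ranking with min-rank ties", {
  prod <- data.frame(
    municipality_id = c(rep("A", 3), rep("B", 4), rep("C", 2), rep("D", 3),
                        rep("E", 2)),
    crop_name = c("cocoa", "acai", "pepper",
                  "cocoa", "acai", "banana", "coffee",
                  "acai", "banana",
                  "cocoa", "acai", "banana",
                  "cocoa", "acai"),
    production_value = c(100, 80, 50,       # A: cocoa rank 1 -> dominant
                         10, 50, 40, 30,    # B: cocoa rank 4 -> present
                         5, 2,              # C: no cocoa row -> absent
                         50, 50, 60,        # D: tie at 50 -> rank 2 -> dominant
                         0, 10))            # E: zero production -> absent
  prev <- classify_prevalence(prod)
  expect_equal(as.character(prev[c("A", "B", "C", "D", "E")]),
               c("dominant", "present", "absent", "dominant", "absent"))
  expect_error(classify_prevalence(transform(prod, production_value = -1)),
               "negative")
})

test_that("the decision table is total and matches its enumerated rows", {
  grid <- expand.grid(current = c("VL", "LM", "MH"),
                      future = c("VL", "LM", "MH"),
                      prevalence = c("dominant", "present", "absent"),
                      stringsAsFactors = FALSE)
  z <- assign_zone(grid$current, grid$future, grid$prevalence)
  expect_equal(length(z), 27)
  expect_false(any(is.na(z)))          # total function: one zone per triple

  want <- function(cur, fut, prev, zone) {
    expect_equal(as.character(assign_zone(cur, fut, prev)), zone,
                 label = paste(cur, fut, prev))
  }
  # the 14 literally tabulated combinations
  want("MH", "MH", "dominant", "intensification")
  want("MH", "MH", "present", "expansion")
  want("MH", "MH", "absent", "expansion")
  for (cur in c("LM", "MH")) for (prev in c("dominant", "present")) {
    want(cur, "LM", prev, "diversification")
    want(cur, "VL", prev, "conversion")
  }
  for (cur in c("VL", "LM", "MH")) want(cur, "VL", "absent", "not_recommended")

  # completion rule for combinations the table leaves open
  want("VL", "MH", "dominant", "not_recommended")
  want("LM", "MH", "dominant", "expansion")
  want("LM", "MH", "absent", "expansion")
  want("MH", "LM", "absent", "not_recommended")
  want("VL", "LM", "present", "not_recommended")
  want("VL", "VL", "dominant", "not_recommended")
  fired <- attr(z, "completion_fired")
  expect_equal(sum(fired), 27 - 14)
})

test_that("worsening the future class never rescues a cell", {
  rank <- c(intensification = 1, expansion = 1, diversification = 2,
            conversion = 3, not_recommended = 3)
  for (cur in c("VL", "LM", "MH")) for (prev in c("dominant", "present", "absent")) {
    zs <- as.character(assign_zone(rep(cur, 3), c("MH", "LM", "VL"), rep(prev, 3)))
    expect_true(all(diff(rank[zs]) >= 0),
                label = paste("future degradation at", cur, prev))
  }
})

test_that("the current-conditions table covers all nine combinations", {
  want <- function(cur, prev, zone)
    expect_equal(as.character(current_zoning(cur, prev)), zone,
                 label = paste(cur, prev))
  want("MH", "dominant", "intensification")
  want("MH", "present", "expansion")
  want("MH", "absent", "expansion")
  want("LM", "dominant", "diversification")
  want("LM", "present", "diversification")
  want("VL", "dominant", "conversion")
  want("VL", "present", "conversion")
  want("LM", "absent", "not_recommended")
  want("VL", "absent", "not_recommended")
})

test_that("a hand-enumerated 3x3 world maps exactly", {
  g <- grid_spec(3, 3)
  suit_cur <- structure(list(grid = g, name = "s",
                             values = matrix(c(0.9, 0.9, 0.9,
                                               0.3, 0.3, 0.1,
                                               0.9, 0.1, 0.6), 3, byrow = TRUE),
                             categories = NULL, scenario_label = "current"),
                        class = c("suitability_map", "ec_layer"))
  suit_fut <- suit_cur
  suit_fut$values <- matrix(c(0.9, 0.3, 0.1,
                              0.3, 0.1, 0.9,
                              0.1, 0.1, 0.55), 3, byrow = TRUE)
  # municipality 1 = left column (dominant), 2 = middle (present),
  # 3 = right (absent)
  mun <- new_layer(g, "mun", matrix(rep(1:3, 3), 3, byrow = TRUE),
                   categories = c("M1", "M2", "M3"))
  prev <- stats::setNames(factor(c("dominant", "present", "absent"),
                                 levels = c("dominant", "present", "absent")),
                          c("M1", "M2", "M3"))
  mask <- new_layer(g, "mask", matrix(1, 3, 3))
  mask$values[3, 2] <- 0                      # one cell off the soil mask
  zm <- build_zone_map(suit_cur, suit_fut, prev, mun, mask, "RCP4.5")
  # hand enumeration, row by row:
  # (MH,MH,dom)->int  (MH,LM,pres)->div   (MH,VL,abs)->not_rec
  # (LM,LM,dom)->div  (LM,VL,pres)->conv  (VL,MH,abs)->completion: not_rec
  # (MH,VL,dom)->conv  off-mask           (MH,MH,abs)->exp
  zones <- zm$categories[as.vector(t(zm$values))]
  expect_equal(zones, c("intensification", "diversification", "not_recommended",
                        "diversification", "conversion", "not_recommended",
                        "conversion", NA, "expansion"))

  cur_map <- build_zone_map(suit_cur, NULL, prev, mun, mask, "current")
  zc <- cur_map$categories[as.vector(t(cur_map$values))]
  # current column: MH/dom->int, MH/pres->exp, MH/abs->exp, LM/dom->div,
  # LM/pres->div, VL/abs->not_rec, MH/dom->int, off, MH/abs->exp
  expect_equal(zc, c("intensification", "expansion", "expansion",
                     "diversification", "diversification", "not_recommended",
                     "intensification", NA, "expansion"))
})

test_that("constant worlds and empty masks behave as forced", {
  g <- grid_spec(4, 4)
  mh <- structure(list(grid = g, name = "s", values = matrix(0.8, 4, 4),
                       categories = NULL, scenario_label = "x"),
                  class = c("suitability_map", "ec_layer"))
  mun <- new_layer(g, "mun", matrix(1, 4, 4), categories = "M1")
  prev <- stats::setNames(factor("dominant",
                                 levels = c("dominant", "present", "absent")), "M1")
  mask <- new_layer(g, "mask", matrix(1, 4, 4))
  zm <- build_zone_map(mh, mh, prev, mun, mask, "RCP8.5")
  expect_true(all(zm$categories[zm$values] == "intensification"))

  empty <- new_layer(g, "mask", matrix(0, 4, 4))
  zm0 <- build_zone_map(mh, mh, prev, mun, empty, "RCP8.5")
  expect_true(all(is.na(zm0$values)))
})

test_that("municipalities without prevalence fall back to absent with a note", {
  g <- grid_spec(2, 2)
  mh <- structure(list(grid = g, name = "s", values = matrix(0.8, 2, 2),
                       categories = NULL, scenario_label = "x"),
                  class = c("suitability_map", "ec_layer"))
  mun <- new_layer(g, "mun", matrix(c(1, 1, 2, 2), 2), categories = c("M1", "M2"))
  prev <- stats::setNames(factor("dominant",
                                 levels = c("dominant", "present", "absent")), "M1")
  mask <- new_layer(g, "mask", matrix(1, 2, 2))
  expect_message(zm <- build_zone_map(mh, mh, prev, mun, mask, "RCP4.5"),
                 "without prevalence")
  zones <- zm$categories[zm$values]
  expect_setequal(unique(zones), c("intensification", "expansion"))
})
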