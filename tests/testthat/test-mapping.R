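reg <- load_registry()

test_that("the HT-8 rule reproduces the worked configuration", {
  hand <- ht8_worked_hand()
  p <- apply_rule(rules_for(reg, "HT-8", "front"), hand)
  # base = 10, origin = (9, 0), projected 2 units toward (5, -20)
  expect_equal(p, c(8.6078, -1.9612), tolerance = 1e-4)
})

test_that("HT-8 offset-to-base ratio is exactly 1/5 on any non-degenerate hand", {
  set.seed(11)
  rule <- rules_for(reg, "HT-8", "front")
  for (i in 1:20) {
    hand <- gen_hand_landmarks("front", scale = runif(1, 0.5, 2),
                               rotation = runif(1, -180, 180),
                               jitter_sd = 1.5, seed = i)
    p <- apply_rule(rule, hand)
    origin <- midpoint(hand$points[13 + 1, 1:2], hand$points[17 + 1, 1:2])[1:2]
    base <- euclidean_distance(hand$points[5 + 1, 1:2], hand$points[17 + 1, 1:2])
    expect_equal(euclidean_distance(p, origin) / base, 0.2, tolerance = 1e-9)
  }
})

test_that("anchor rules return the landmark and missing slots are named", {
  hand <- gen_hand_landmarks("front")
  anchor_rule <- list(steps = list(list(op = "anchor", lm = 4)))
  expect_equal(apply_rule(anchor_rule, hand), unname(hand$points[4 + 1, 1:2]))
  hand$points[13 + 1, ] <- NA
  expect_error(apply_rule(rules_for(reg, "HT-8", "front"), hand), "slot 13",
               class = "acumap_rule_error")
})

test_that("map_acupoints returns registry-ordered predictions with posture gating", {
  hand <- gen_hand_landmarks("front")
  preds <- map_acupoints(hand, reg)
  expect_equal(nrow(preds), 18L)
  expect_equal(preds$code, registry_summary(reg)$code[1:18])
  expect_true(all(preds$posture == "front"))
  # palmar-side codes are visible in the front view, dorsal-only ones are not
  expect_true(all(c("HT-7", "HT-8", "LU-9", "PC-9") %in% preds$code[preds$visible]))
  expect_false(any(c("LI-4", "TE-3") %in% preds$code[preds$visible]))
  expect_true(all(is.na(preds$x[!preds$visible])))
  expect_true(all(is.finite(preds$x[preds$visible])))

  face <- gen_face_landmarks("center")
  pf <- map_acupoints(face, reg)
  expect_equal(nrow(pf), 20L)
  expect_equal(sum(pf$visible), 20L)  # center pose shows the full face set
  # only midline points survive a left-turned pose (left side authored)
  pl <- map_acupoints(gen_face_landmarks("left"), reg)
  expect_setequal(pl$code[pl$visible], c("CV-24", "GV-25", "GV-26", "GV-27"))

  empty <- reg; empty$entries <- list()
  expect_equal(nrow(map_acupoints(hand, empty)), 0L)
})

test_that("predictions are equivariant under similarity transforms", {
  set.seed(23)
  hand <- gen_hand_landmarks("front", jitter_sd = 1, seed = 5)
  base <- map_acupoints(hand, reg)
  for (i in 1:8) {
    ang <- runif(1, -180, 180); sc <- runif(1, 0.5, 2); sh <- c(runif(2, -30, 30), 0)
    moved <- transform_hand(hand, rot3("z", ang), scale = sc, shift = sh)
    got <- map_acupoints(moved, reg)
    expect_equal(got$visible, base$visible)
    # transform the baseline predictions with the same similarity map
    center <- c(320, 240)
    xy <- cbind(base$x - center[1], base$y - center[2], 0)[base$visible, , drop = FALSE]
    xy <- xy %*% t(rot3("z", ang)) * sc
    want_x <- xy[, 1] + center[1] + sh[1]
    want_y <- xy[, 2] + center[2] + sh[2]
    scale_ref <- max(abs(c(want_x, want_y)))
    expect_lt(max(abs(got$x[got$visible] - want_x)) / scale_ref, 1e-6)
    expect_lt(max(abs(got$y[got$visible] - want_y)) / scale_ref, 1e-6)
  }
})

test_that("mapping commutes with mirroring and is deterministic", {
  for (posture in c("front", "back")) {
    hand <- gen_hand_landmarks(posture, rotation = 9, jitter_sd = 0.5, seed = 3)
    direct <- map_acupoints(hand, reg)
    mirrored <- map_acupoints(mirror_landmarks(hand), reg)
    expect_equal(mirrored$visible, direct$visible)
    expect_equal(640 - mirrored$x[mirrored$visible], direct$x[direct$visible],
                 tolerance = 1e-9)
    expect_equal(mirrored$y, direct$y, tolerance = 1e-9)
  }
  hand <- gen_hand_landmarks("front")
  expect_identical(map_acupoints(hand, reg), map_acupoints(hand, reg))
})

test_that("mirror_landmarks is an involutive isometry and needs image_size", {
  hand <- gen_hand_landmarks("inside", rotation = -4)
  twice <- mirror_landmarks(mirror_landmarks(hand))
  expect_equal(twice$points, hand$points, tolerance = 1e-9)
  expect_equal(twice$handedness, hand$handedness)
  m <- mirror_landmarks(hand)
  expect_equal(m$handedness, "left")
  expect_equal(as.matrix(dist(m$points)), as.matrix(dist(hand$points)),
               tolerance = 1e-9)
  # midline point keeps its x
  hand$points[1, 1] <- 320
  expect_equal(unname(mirror_landmarks(hand)$points[1, 1]), 320)
  hand$image_size <- NULL
  expect_error(mirror_landmarks(hand), class = "acumap_invalid_input")
})

test_that("overlay_predictions draws visible dots and skips out-of-bounds", {
  img <- matrix(0, 40, 60)
  hand <- gen_hand_landmarks("front")
  preds <- data.frame(code = c("A", "B", "C"), x = c(10, 999, 20), y = c(10, 10, NA),
                      posture = "front", visible = c(TRUE, TRUE, FALSE), confidence = 1)
  expect_warning(out <- overlay_predictions(img, preds, radius = 1), "out-of-bounds")
  expect_equal(out[11, 11], 1)      # dot at (10, 10)
  expect_gt(sum(out), 0)
  expect_identical(overlay_predictions(img, preds[0, ]), img)
  # invisible rows are never rendered
  out2 <- overlay_predictions(img, data.frame(code = "C", x = 5, y = 5,
                                              posture = "front", visible = FALSE,
                                              confidence = 1))
  expect_identical(out2, img)
})
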