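test_that("calibration truncates at 4 decimals and converts to mm", {
  calib <- calibrate_from_reference(80, 1488)
  expect_identical(calib$cm_per_pixel, 0.0537)     # 80/1488 = 0.05376..., truncated
  expect_equal(calib$raw_cm_per_pixel, 80 / 1488)
  expect_equal(pixels_to_mm(10, calib), 5.37)
  expect_equal(calibrate_from_reference(100, 100)$cm_per_pixel, 1)
  expect_equal(pixels_to_mm(0, calib), 0)
  expect_equal(pixels_to_mm(1, calibrate_from_reference(100, 100)), 10)
  expect_error(calibrate_from_reference(80, 0), class = "acumap_invalid_input")
  expect_error(pixels_to_mm(-1, calib), class = "acumap_invalid_input")
  # mm errors are a constant multiple of pixel errors: ordering preserved
  e <- c(3, 1, 10, 7)
  expect_equal(order(pixels_to_mm(e, calib)), order(e))
})

test_that("distance_error matches codes and is translation invariant", {
  p <- list(code = "LI-4", x = 0, y = 0, image_id = 1L)
  g <- list(code = "LI-4", x = 3, y = 4, image_id = 1L)
  expect_equal(distance_error(p, g), 5)
  expect_equal(distance_error(list(code = "A", x = 1, y = 1), list(code = "A", x = 1, y = 1)), 0)
  p2 <- p; g2 <- g
  p2$x <- p$x + 17; p2$y <- p$y - 4; g2$x <- g$x + 17; g2$y <- g$y - 4
  expect_equal(distance_error(p2, g2), 5)
  expect_error(distance_error(p, list(code = "TE-3", x = 0, y = 0)),
               class = "acumap_pairing_error")
})

test_that("oks obeys its closed form and monotonicity", {
  params <- oks_params(k = 0.02, s = 150)
  expect_equal(oks(0, params), 1)
  expect_equal(oks(params$s * params$k * sqrt(2 * log(2)), params), 0.5)
  d <- seq(0, 30, by = 0.5)
  expect_true(all(diff(oks(d, params)) < 0))
  expect_true(all(oks(d, params) > 0 & oks(d, params) <= 1))
  # invariance to joint rescaling of (d, s)
  expect_equal(oks(7, params), oks(7 * 3, oks_params(k = 0.02, s = 150 * 3)))
  expect_error(oks_params(k = 0, s = 1), class = "acumap_invalid_input")
  expect_error(oks(-1, params), class = "acumap_invalid_input")
})

test_that("precision_recall handles degenerate denominators", {
  expect_equal(precision_recall(9, 1, 3), c(precision = 90, recall = 75))
  pr <- precision_recall(0, 0, 5)
  expect_true(is.na(pr[["precision"]]))
  expect_equal(pr[["recall"]], 0)
  expect_equal(precision_recall(5, 0, 0), c(precision = 100, recall = 100))
})

test_that("match_by_oks greedy matching and tie-breaking", {
  gts <- data.frame(x = c(0, 100), y = c(0, 0), s = c(50, 50))
  perfect <- data.frame(x = c(0, 100), y = c(0, 0), confidence = c(1, 1))
  m <- match_by_oks(perfect, gts, threshold = 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  m0 <- match_by_oks(perfect[0, ], gts)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 2L))
  # one prediction equidistant in OKS to two ground truths: first gt wins
  tie <- data.frame(x = 50, y = 0, confidence = 1)
  mt <- match_by_oks(tie, gts, threshold = 0)
  expect_equal(mt$matches$gt, 1L)
  # below threshold: unmatched on both sides
  far <- data.frame(x = 1e4, y = 0, confidence = 1)
  mf <- match_by_oks(far, gts, threshold = 0.5)
  expect_equal(c(mf$tp, mf$fp, mf$fn), c(0L, 1L, 2L))
})

test_that("mean_ap averages categories", {
  expect_equal(mean_ap(c(A = 0.8, B = 0.6)), 0.7)
  expect_equal(mean_ap(c(1, 1, 1)), 1)
  expect_error(mean_ap(numeric(0)), class = "acumap_invalid_input")
})

test_that("summarize_errors gives the normal-approximation CI", {
  s <- summarize_errors(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$ci, c(5, 5))
  expect_equal(summarize_errors(c(0, 10))$mean, 5)
  expect_equal(summarize_errors(3)$ci, c(3, 3))  # degenerate at n = 1
  expect_error(summarize_errors(numeric(0)), class = "acumap_invalid_input")
  # CI coverage: ~95% of seeded replicates contain the true mean
  set.seed(99)
  hits <- mean(replicate(400, {
    s <- summarize_errors(rnorm(100, mean = 5.58, sd = 1))
    s$ci[1] <= 5.58 && 5.58 <= s$ci[2]
  }))
  expect_gt(hits, 0.9); expect_lt(hits, 0.99)
})

test_that("KS statistic matches brute-force enumeration and known cases", {
  x <- c(1, 2, 3)
  expect_equal(ks_axis_test(x, x)$statistic, 0)
  expect_equal(ks_axis_test(x, x)$p_value, 1)
  expect_equal(ks_axis_test(c(1, 2), c(10, 11))$statistic, 1)
  expect_equal(ks_axis_test(c(1, 2, 3), c(1, 2, 4))$statistic, 1 / 3)
  set.seed(42)
  for (i in 1:40) {
    a <- sample(1:10, sample(1:8, 1), replace = TRUE)
    b <- sample(1:10, sample(1:8, 1), replace = TRUE)
    expect_equal(ks_axis_test(a, b)$statistic, ks_brute_force(a, b))
  }
  # asymptotic p agrees with the reference implementation on large samples
  set.seed(1); a <- rnorm(300); b <- rnorm(300, 0.1)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  got <- ks_axis_test(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-5)
  expect_error(ks_axis_test(numeric(0), 1), class = "acumap_invalid_input")
})

test_that("evaluate_predictions attains ideal values when predictions equal ground truth", {
  reg <- load_registry()
  scene <- gen_eval_scene(scene_spec(5, "hand", jitter_sd = 0, seed = 8), reg)
  preds <- map_scene_predictions(scene, reg)
  rep <- evaluate_predictions(preds, scene$gt)
  expect_equal(rep$mean_distance$mean, 0)
  expect_equal(rep$precision, 100)
  expect_equal(rep$recall, 100)
  expect_equal(rep$map50, 1)
  expect_equal(rep$map5095, 1)
  expect_equal(rep$ks_x$statistic, 0)
  expect_equal(rep$ks_y$statistic, 0)
  expect_equal(unname(rep$counts[["FP"]]), 0)
})

test_that("empty prediction sets produce an FN-only report with absent precision", {
  reg <- load_registry()
  scene <- gen_eval_scene(scene_spec(2, "hand", jitter_sd = 0, seed = 9), reg)
  rep <- evaluate_predictions(NULL, scene$gt)
  expect_equal(unname(rep$counts[["TP"]]), 0)
  expect_equal(unname(rep$counts[["FN"]]), nrow(scene$gt))
  expect_true(is.na(rep$precision))
  expect_equal(rep$recall, 0)
})

test_that("jittered scenes recover the Rayleigh mean within the simulation CI", {
  reg <- load_registry()
  sigma <- 3
  scene <- gen_eval_scene(scene_spec(60, "hand", jitter_sd = sigma, seed = 12), reg)
  preds <- map_scene_predictions(scene, reg)
  rep <- evaluate_predictions(preds, scene$gt,
                              calib = calibrate_from_reference(80, 1488))
  n <- rep$mean_distance$n
  expect_gt(n, 400)  # ~500 error samples, the scaled-down design size
  rayleigh_mean <- sigma * sqrt(pi / 2)
  rayleigh_se <- sigma * sqrt((4 - pi) / 2) / sqrt(n)
  expect_lt(abs(rep$mean_distance$mean - rayleigh_mean), 3 * rayleigh_se)
  # calibrated errors are the constant multiple of pixel errors
  expect_equal(mean(rep$calibrated_errors_mm),
               rep$mean_distance$mean * 0.0537 * 10)
})
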