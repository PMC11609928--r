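reg <- load_registry()

test_that("generators honor the requested label and schema at zero jitter", {
  for (posture in c("front", "back", "inside", "outside")) {
    for (hd in c("right", "left")) {
      set <- gen_hand_landmarks(posture, hd, seed = 1)
      expect_equal(nrow(set$points), 21L)
      expect_equal(set$handedness, hd)
      expect_equal(classify_hand_posture(set)$label, posture)
    }
  }
  for (pose in c("center", "left", "right")) {
    set <- gen_face_landmarks(pose, seed = 1)
    expect_equal(nrow(set$points), 468L)
    expect_true(all(is.finite(set$points)))  # every slot populated
    expect_equal(classify_face_pose(set)$label, pose)
  }
})

test_that("generators are deterministic per seed and respect the caller's RNG", {
  a <- gen_hand_landmarks("front", jitter_sd = 2, seed = 7)
  b <- gen_hand_landmarks("front", jitter_sd = 2, seed = 7)
  expect_identical(a$points, b$points)
  c <- gen_hand_landmarks("front", jitter_sd = 2, seed = 8)
  expect_false(identical(a$points, c$points))
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_face_landmarks("center", jitter_sd = 1, seed = 99))
  expect_identical(runif(1), before)  # caller's stream untouched
})

test_that("jitter displacement follows the Rayleigh mean", {
  clean <- gen_hand_landmarks("front", jitter_sd = 0)
  sds <- numeric(0)
  disp <- numeric(0)
  for (i in 1:60) {
    noisy <- gen_hand_landmarks("front", jitter_sd = 2, seed = 1000 + i)
    disp <- c(disp, sqrt(rowSums((noisy$points[, 1:2] - clean$points[, 1:2])^2)))
  }
  n <- length(disp)
  expect_equal(mean(disp), 2 * sqrt(pi / 2),
               tolerance = 3 * sqrt((4 - pi) / 2) * 2 / sqrt(n) / (2 * sqrt(pi / 2)))
})

test_that("scene generation closes the loop at zero jitter and writes valid files", {
  out_dir <- tempfile("scene")
  scene <- gen_eval_scene(scene_spec(4, "hand", jitter_sd = 0, seed = 5), reg,
                          out_dir = out_dir)
  expect_length(scene$landmark_files, 4L)
  expect_true(file.exists(scene$gt_file))
  # ground truth equals the mapping output exactly
  for (i in 1:4) {
    preds <- map_acupoints(read_landmarks(scene$landmark_files[i]), reg)
    vis <- preds[preds$visible, ]
    gt_i <- scene$gt[scene$gt$image_id == i, ]
    expect_equal(vis$code, gt_i$code)
    expect_equal(vis$x, gt_i$x)
    expect_equal(vis$y, gt_i$y)
  }
  # the COCO file round-trips the same annotations
  gt_read <- read_coco_ground_truth(scene$gt_file, reg)
  expect_equal(nrow(gt_read), nrow(scene$gt))
  expect_equal(gt_read$x, scene$gt$x)
  # byte-identical regeneration under the same seed
  out_dir2 <- tempfile("scene")
  gen_eval_scene(scene_spec(4, "hand", jitter_sd = 0, seed = 5), reg, out_dir = out_dir2)
  for (f in list.files(out_dir)) {
    expect_identical(readLines(file.path(out_dir, f)),
                     readLines(file.path(out_dir2, f)))
  }
})

test_that("face scenes and empty scenes are schema-valid", {
  scene <- gen_eval_scene(scene_spec(3, "face", jitter_sd = 0, seed = 2), reg,
                          out_dir = tempfile())
  expect_equal(nrow(scene$images), 3L)
  expect_true(all(scene$gt$code %in% registry_summary(reg)$code))
  empty <- gen_eval_scene(scene_spec(0, "hand", seed = 1), reg, out_dir = tempfile())
  expect_equal(nrow(empty$gt), 0L)
  expect_equal(nrow(read_coco_ground_truth(empty$gt_file, reg)), 0L)
})

test_that("scene_spec validates its ranges", {
  expect_error(scene_spec(3, "hand", scale_range = c(2, 1)), class = "acumap_invalid_input")
  expect_error(scene_spec(-1, "hand"), class = "acumap_invalid_input")
  expect_error(scene_spec(3, "hand", posture_mix = c(upside_down = 1)),
               class = "acumap_invalid_input")
})
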