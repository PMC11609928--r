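# Shared fixtures and independent oracles. Everything is generated in code;
# no stored binary data.

# Brute-force two-sample KS statistic: evaluate both empirical CDFs on the
# pooled sample and take the largest absolute difference. Deliberately naive,
# independent of the package's ECDF-based implementation.
ks_brute_force <- function(x, y) {
  grid <- sort(c(x, y))
  d <- vapply(grid, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1))
  max(d)
}

# 3D rotation matrices (independent of the package's internal helper).
rot3 <- function(axis, deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
         y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
         z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
}

# Apply a rotation (about the template center) + scale + translation to an
# existing pixel-space hand set, preserving metadata.
transform_hand <- function(set, rot = diag(3), scale = 1, shift = c(0, 0, 0)) {
  center <- c(set$image_size / 2, 0)
  pts <- sweep(set$points, 2, center)
  pts <- pts %*% t(rot) * scale
  pts <- sweep(pts, 2, center + shift, "+")
  landmark_set(set$region, pts, handedness = set$handedness,
               image_size = set$image_size)
}

# A minimal hand set where only the slots of the HT-8 rule are placed,
# mirroring the worked configuration: slot5 (0,0), slot17 (10,0),
# slot13 (8,0), slot0 (5,-20).
ht8_worked_hand <- function() {
  pts <- matrix(NA_real_, 21, 3)
  pts[0 + 1, ] <- c(5, -20, 0)
  pts[5 + 1, ] <- c(0, 0, 0)
  pts[13 + 1, ] <- c(8, 0, 0)
  pts[17 + 1, ] <- c(10, 0, 0)
  landmark_set("hand", pts, handedness = "right")
}

# Verbatim catalogue of the 38 shipped acupoints (code, full name, meridian).
expected_acupoint_table <- function() {
  hand <- data.frame(rbind(
    c("HT-7", "Shenmen", "Heart"),
    c("HT-8", "Shaofu", "Heart"),
    c("HT-9", "Shaochong", "Heart"),
    c("LI-1", "Shangyang", "Large intestine"),
    c("LI-2", "Erjian", "Large intestine"),
    c("LI-3", "Sanjian", "Large intestine"),
    c("LI-4", "Hegu", "Large intestine"),
    c("LU-11", "Shaoshang", "Lung"),
    c("LU-9", "Taiyuan", "Lung"),
    c("PC-9", "Zhongchong", "Pericardium"),
    c("SI-1", "Shaoze", "Small intestine"),
    c("SI-2", "Qiangu", "Small intestine"),
    c("SI-3", "Houxi", "Small intestine"),
    c("SI-4", "Wangu", "Small intestine"),
    c("TE-1", "Guanchong", "Triple energizer"),
    c("TE-2", "Yemen", "Triple energizer"),
    c("TE-3", "Zhongzhu", "Triple energizer"),
    c("TE-4", "Yangchi", "Triple energizer")))
  face <- data.frame(rbind(
    c("CV-24", "Chengjiang", "Conception vessel"),
    c("BL-1", "Jingming", "Bladder"),
    c("BL-2", "Cuanzhu", "Bladder"),
    c("GB-1", "Tongziliao", "Gallbladder"),
    c("GB-2", "Tinghui", "Gallbladder"),
    c("GB-14", "Yangbai", "Gallbladder"),
    c("GV-25", "Suliao", "Governing vessel"),
    c("GV-26", "Shuigou", "Governing vessel"),
    c("GV-27", "Duiduan", "Governing vessel"),
    c("LI-19", "Kouheliao", "Large intestine"),
    c("LI-20", "Yingxiang", "Large intestine"),
    c("SI-18", "Quanliao", "Small intestine"),
    c("ST-1", "Chengqi", "Stomach"),
    c("ST-2", "Sibai", "Stomach"),
    c("ST-3", "Juliao", "Stomach"),
    c("ST-4", "Dicang", "Stomach"),
    c("ST-5", "Daying", "Stomach"),
    c("ST-6", "Jiache", "Stomach"),
    c("ST-7", "Xiaguan", "Stomach"),
    c("TE-23", "Sizhukong", "Triple energizer")))
  names(hand) <- names(face) <- c("code", "name", "meridian")
  hand$region <- "hand"
  face$region <- "face"
  rbind(hand, face)
}

# Scene predictions: map every generated landmark set, tagging image ids.
map_scene_predictions <- function(scene, registry) {
  do.call(rbind, lapply(seq_along(scene$landmarks), function(i) {
    p <- map_acupoints(scene$landmarks[[i]], registry)
    p$image_id <- i
    p
  }))
}
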