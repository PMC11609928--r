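# Seeded generators for hand/face landmark sets and annotated evaluation
# scenes. These stand in for real imagery: all downstream computation is
# relative geometry, so the templates only need anatomically plausible
# proportions, not photorealism.

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rot_mat <- function(axis, deg) {
  a <- deg * pi / 180
  c <- cos(a); s <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
         y = matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
         z = matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Canonical hand template
#'
#' A versioned 21-slot right-hand template, palm facing the viewer (front
#' posture), authored in hand units (hand length about 185) centered on the
#' palm, image convention (y down, fingertips up, thumb on the image left,
#' z slightly negative toward the viewer at the fingertips).
#'
#' @return A 21 x 3 numeric matrix, row `i` = slot `i - 1`.
#' @export
hand_template <- function() {
  m <- matrix(c(
      0,  90,   5,   # 0 wrist
    -35,  65,   0,   # 1 thumb CMC
    -60,  40,  -5,   # 2 thumb MCP
    -75,  20,  -8,   # 3 thumb IP
    -85,   5, -10,   # 4 thumb tip
    -40,   0,   0,   # 5 index MCP
    -45, -35,  -3,   # 6 index PIP
    -47, -60,  -5,   # 7 index DIP
    -48, -80,  -7,   # 8 index tip
    -13,  -5,   0,   # 9 middle MCP
    -14, -45,  -3,   # 10 middle PIP
    -15, -72,  -5,   # 11 middle DIP
    -15, -95,  -7,   # 12 middle tip
     13,  -2,   0,   # 13 ring MCP
     14, -40,  -3,   # 14 ring PIP
     15, -65,  -5,   # 15 ring DIP
     15, -88,  -7,   # 16 ring tip
     38,   5,   0,   # 17 pinky MCP
     42, -25,  -3,   # 18 pinky PIP
     44, -45,  -5,   # 19 pinky DIP
     46, -62,  -7),  # 20 pinky tip
    ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Canonical face template
#'
#' A 468-slot template in face units (face height about 160), centered,
#' facing the viewer (z negative toward the camera at the nose). The slots
#' referenced by the shipped rules and classifiers carry anatomically shaped
#' positions, authored on the subject's left side and mirrored to the right
#' via [face_mirror_pairs()]; all remaining slots are deterministic filler on
#' an ellipse so that every slot is populated.
#'
#' @return A 468 x 3 numeric matrix, row `i` = slot `i - 1`.
#' @export
face_template <- function() {
  n <- 468L
  ang <- 2 * pi * (seq_len(n) - 1) / n
  m <- cbind(x = 60 * cos(ang), y = 80 * sin(ang), z = 5)
  set_slot <- function(i, x, y, z) m[i + 1L, ] <<- c(x, y, z)
  # midline
  set_slot(0,    0,  38, -18)  # upper lip top
  set_slot(1,    0,   8, -30)  # nose tip
  set_slot(2,    0,  22, -22)  # subnasale
  set_slot(10,   0, -78,  -8)  # forehead top
  set_slot(17,   0,  55, -16)  # lower lip bottom
  set_slot(152,  0,  80, -12)  # chin
  set_slot(168,  0, -18, -18)  # nasion
  # subject-left side
  left <- list(
    `454` = c(58,   0,  10),   # contour at tragion level
    `263` = c(38, -15,  -8),   # outer canthus
    `362` = c(15, -15, -12),   # inner canthus
    `285` = c(12, -28, -12),   # eyebrow medial end
    `334` = c(30, -32, -10),   # eyebrow midpoint
    `300` = c(45, -28,  -8),   # eyebrow lateral end
    `288` = c(48,  35,   2),   # jaw below ear
    `291` = c(22,  45, -12),   # mouth corner
    `294` = c(12,  20, -18),   # nostril wing
    `330` = c(35,  18,  -8),   # cheek
    `361` = c(52,  20,   6),   # jawline near ear
    `365` = c(35,  58,  -2),   # lower jaw
    `374` = c(27, -10,  -9),   # lower eyelid center
    `436` = c(28,  38,  -8),   # lower cheek
    `447` = c(55,  -8,   8))   # upper contour near ear
  pairs <- face_mirror_pairs()
  for (nm in names(left)) {
    li <- as.integer(nm)
    p <- left[[nm]]
    set_slot(li, p[1], p[2], p[3])
    ri <- pairs[match(li, pairs[, "left"]), "right"]
    set_slot(ri, -p[1], p[2], p[3])
  }
  m
}

# Shared placement: rotate/scale/translate template rows into pixel space.
place_template <- function(template, pre_rot = NULL, rotation = 0, scale = 1,
                           image_size = c(640, 480)) {
  pts <- template
  if (!is.null(pre_rot)) pts <- pts %*% t(pre_rot)
  if (rotation != 0) pts <- pts %*% t(rot_mat("z", rotation))
  pts <- pts * scale
  pts[, 1] <- pts[, 1] + image_size[1] / 2
  pts[, 2] <- pts[, 2] + image_size[2] / 2
  pts
}

# Image-plane Gaussian jitter (x and y only): emulates 2D detection error,
# giving the Rayleigh closed form for Euclidean displacement. Slot-major
# draw order: all x offsets, then all y offsets.
add_jitter <- function(pts, jitter_sd) {
  if (jitter_sd > 0) {
    n <- nrow(pts)
    pts[, 1] <- pts[, 1] + stats::rnorm(n, 0, jitter_sd)
    pts[, 2] <- pts[, 2] + stats::rnorm(n, 0, jitter_sd)
  }
  pts
}

#' Generate a synthetic hand landmark set
#'
#' Rotates the canonical right-hand template so the posture classifier
#' recovers the requested label at zero jitter (front 0, inside +90, outside
#' -90, back 180 degrees about the vertical axis), applies the in-plane
#' rotation, scale and image-center translation, mirrors for left hands, and
#' adds image-plane Gaussian jitter. Deterministic for a given seed.
#'
#' @param posture Requested label: front, back, inside or outside.
#' @param handedness `"right"` (default) or `"left"`.
#' @param scale Uniform scale factor (1 spans about 185 px).
#' @param rotation In-plane rotation in degrees.
#' @param jitter_sd Per-coordinate Gaussian noise sd in pixels.
#' @param seed Optional integer seed (caller's RNG stream is preserved).
#' @param image_size `c(width, height)` pixels.
#' @return A pixel-space hand `acumap_landmarks`.
#' @export
gen_hand_landmarks <- function(posture = c("front", "back", "inside", "outside"),
                               handedness = c("right", "left"),
                               scale = 1, rotation = 0, jitter_sd = 0,
                               seed = NULL, image_size = c(640, 480)) {
  posture <- match.arg(posture)
  handedness <- match.arg(handedness)
  yaw <- switch(posture, front = 0, inside = 90, outside = -90, back = 180)
  pts <- place_template(hand_template(), pre_rot = rot_mat("y", yaw),
                        rotation = rotation, scale = scale, image_size = image_size)
  set <- landmark_set("hand", pts, handedness = "right", image_size = image_size)
  if (handedness == "left") set <- mirror_landmarks(set)
  got <- classify_hand_posture(set)$label
  if (got != posture) {
    abort_acumap(sprintf(
      "requested posture '%s' unreachable under rotation %g (classifier says '%s')",
      posture, rotation, got), "acumap_generation_error")
  }
  if (jitter_sd > 0) {
    set$points <- with_seed(seed, add_jitter(set$points, jitter_sd))
  }
  set
}

#' Generate a synthetic face landmark set
#'
#' Applies a yaw rotation to the canonical face template so the face-pose
#' classifier recovers the requested label at zero jitter (0 for center,
#' +30/-30 degrees with a fallback search for right/left), then scale,
#' translation and image-plane jitter as for hands.
#'
#' @param pose Requested label: center, left or right.
#' @inheritParams gen_hand_landmarks
#' @return A pixel-space face `acumap_landmarks` with all 468 slots populated.
#' @export
gen_face_landmarks <- function(pose = c("center", "left", "right"),
                               scale = 1, rotation = 0, jitter_sd = 0,
                               seed = NULL, image_size = c(640, 480)) {
  pose <- match.arg(pose)
  candidates <- switch(pose,
                       center = 0,
                       right = seq(30, 60, by = 5),
                       left = -seq(30, 60, by = 5))
  set <- NULL
  for (yaw in candidates) {
    pts <- place_template(face_template(), pre_rot = rot_mat("y", yaw),
                          rotation = rotation, scale = scale, image_size = image_size)
    cand <- landmark_set("face", pts, image_size = image_size)
    if (classify_face_pose(cand)$label == pose) { set <- cand; break }
  }
  if (is.null(set)) {
    abort_acumap(sprintf("requested pose '%s' unreachable by yaw search", pose),
                 "acumap_generation_error")
  }
  if (jitter_sd > 0) {
    set$points <- with_seed(seed, add_jitter(set$points, jitter_sd))
  }
  set
}

#' Specification of a synthetic evaluation scene
#'
#' @param n_images Number of images to synthesize.
#' @param region `"hand"` or `"face"`.
#' @param posture_mix Named probabilities over posture/pose labels; default
#'   uniform over the region's labels.
#' @param scale_range Length-2 range of uniform scale factors.
#' @param rotation_range Length-2 range of in-plane rotations (degrees).
#' @param jitter_sd Gaussian sd (pixels) applied to the ground-truth acupoint
#'   positions, emulating annotation noise.
#' @param seed Integer seed fixing the whole output stream.
#' @param image_size `c(width, height)` pixels.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_images, region = c("hand", "face"), posture_mix = NULL,
                       scale_range = c(0.8, 1.2), rotation_range = c(-15, 15),
                       jitter_sd = 0, seed = 1, image_size = c(640, 480)) {
  region <- match.arg(region)
  labels <- region_postures(region)
  if (is.null(posture_mix)) {
    posture_mix <- stats::setNames(rep(1 / length(labels), length(labels)), labels)
  }
  if (!all(names(posture_mix) %in% labels) || any(posture_mix < 0) ||
      sum(posture_mix) <= 0) {
    abort_invalid_input("posture_mix must be nonnegative weights over the region's labels")
  }
  if (n_images < 0 || jitter_sd < 0 || diff(scale_range) < 0 || any(scale_range <= 0)) {
    abort_invalid_input("invalid scene specification")
  }
  structure(list(n_images = as.integer(n_images), region = region,
                 posture_mix = posture_mix / sum(posture_mix),
                 scale_range = scale_range, rotation_range = rotation_range,
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 image_size = image_size),
            class = "scene_spec")
}

#' Generate an annotated evaluation scene
#'
#' For each image: draws a posture, scale, in-plane rotation (and handedness
#' for hands) from the spec, generates a clean landmark set, computes the
#' ground-truth acupoints with the mapping rules, and perturbs those
#' positions with Gaussian jitter of sd `spec$jitter_sd`. At zero jitter the
#' ground truth is exactly the mapping output, closing the loop for
#' self-consistency tests. With `out_dir`, landmark JSON files and one COCO
#' keypoint ground-truth JSON are written (byte-identical under a fixed
#' seed).
#'
#' @param spec A [scene_spec()].
#' @param registry An `acumap_registry`.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list: `landmarks` (list of sets), `images`
#'   (data.frame id/width/height/file_name), `gt` (data.frame image_id, code,
#'   x, y, bbox), and when `out_dir` is given, `landmark_files` and
#'   `gt_file`.
#' @export
gen_eval_scene <- function(spec, registry = load_registry(), out_dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  labels <- names(spec$posture_mix)
  with_seed(spec$seed, {
    landmarks <- vector("list", spec$n_images)
    gt_rows <- list()
    images <- data.frame(id = integer(0), width = numeric(0), height = numeric(0),
                         file_name = character(0))
    for (i in seq_len(spec$n_images)) {
      label <- sample(labels, 1, prob = spec$posture_mix)
      sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      rot <- stats::runif(1, spec$rotation_range[1], spec$rotation_range[2])
      set <- if (spec$region == "hand") {
        handed <- sample(c("right", "left"), 1)
        gen_hand_landmarks(label, handed, scale = sc, rotation = rot,
                           image_size = spec$image_size)
      } else {
        gen_face_landmarks(label, scale = sc, rotation = rot,
                           image_size = spec$image_size)
      }
      landmarks[[i]] <- set
      preds <- map_acupoints(set, registry)
      vis <- preds[preds$visible, , drop = FALSE]
      if (nrow(vis) > 0 && spec$jitter_sd > 0) {
        vis$x <- vis$x + stats::rnorm(nrow(vis), 0, spec$jitter_sd)
        vis$y <- vis$y + stats::rnorm(nrow(vis), 0, spec$jitter_sd)
      }
      xy <- set$points[, 1:2, drop = FALSE]
      bb <- c(min(xy[, 1]), min(xy[, 2]), diff(range(xy[, 1])), diff(range(xy[, 2])))
      images <- rbind(images, data.frame(
        id = i, width = spec$image_size[1], height = spec$image_size[2],
        file_name = sprintf("synthetic_%04d.json", i)))
      if (nrow(vis) > 0) {
        gt_rows[[i]] <- data.frame(
          image_id = i, code = vis$code, x = vis$x, y = vis$y,
          bbox_x = bb[1], bbox_y = bb[2], bbox_w = bb[3], bbox_h = bb[4])
      }
    }
    gt <- if (length(gt_rows)) do.call(rbind, gt_rows)
          else data.frame(image_id = integer(0), code = character(0),
                          x = numeric(0), y = numeric(0),
                          bbox_x = numeric(0), bbox_y = numeric(0),
                          bbox_w = numeric(0), bbox_h = numeric(0))
    out <- list(landmarks = landmarks, images = images, gt = gt, spec = spec)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- character(spec$n_images)
      for (i in seq_len(spec$n_images)) {
        files[i] <- file.path(out_dir, images$file_name[i])
        write_landmarks(landmarks[[i]], files[i])
      }
      gt_file <- file.path(out_dir, "ground_truth_coco.json")
      write_coco_ground_truth(gt, images, registry, gt_file, region = spec$region)
      out$landmark_files <- files
      out$gt_file <- gt_file
    }
    invisible(out)
  })
}
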