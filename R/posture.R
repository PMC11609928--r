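#' Hand posture and face pose classification
#'
#' Mapping rules are gated by view: a hand is classified into one of four
#' postures (front, back, inside, outside) from the angle between its palm
#' normal and the optical axis, and a face into one of three poses (center,
#' left, right) from a scale-invariant yaw proxy. The mechanisms follow the
#' landmark-pipeline design; the numeric cut-offs below are package
#' conventions (documented, config-overridable), not published values.
#'
#' @name posture
NULL

#' Default classifier thresholds
#'
#' * `hand_front_max_deg` (45): palm angles in `[0, 45)` degrees are `front`.
#' * `hand_back_min_deg` (135): angles in `[135, 180]` are `back`; the two
#'   bands split the sphere into four equal zones, the lateral zone resolved
#'   by the sign of the normal's x-component. Boundary values fall to the
#'   band whose closed end they touch (half-open intervals).
#' * `face_yaw_threshold` (0.2): |yaw proxy| below this is `center`.
#'
#' @return Named list of thresholds.
#' @export
posture_thresholds <- function() {
  list(hand_front_max_deg = 45, hand_back_min_deg = 135, face_yaw_threshold = 0.2)
}

#' Palm reference frame
#'
#' Three distinct landmark slots spanning the palm plane: a reference slot
#' and two secondary slots. The default (wrist 0, index-finger MCP 5, pinky
#' MCP 17) spans the palm in the 21-slot hand schema.
#'
#' @param reference_index,secondary_indices Slot indices (0-based).
#' @return A `palm_frame` list.
#' @export
palm_frame <- function(reference_index = 0L, secondary_indices = c(5L, 17L)) {
  idx <- c(reference_index, secondary_indices)
  if (length(idx) != 3L || anyDuplicated(idx)) {
    abort_invalid_input("palm frame needs three distinct landmark slots")
  }
  structure(list(reference_index = as.integer(reference_index),
                 secondary_indices = as.integer(secondary_indices)),
            class = "palm_frame")
}

#' Palm normal vector
#'
#' Vectors are taken from the frame's reference landmark to its two secondary
#' landmarks; their cross product is the palm plane normal. The sign is fixed
#' per handedness so that "palm facing the viewer" yields a normal of
#' approximately `(0, 0, -1)` for both hands.
#'
#' @param hand A hand `acumap_landmarks`.
#' @param frame A [palm_frame()]; default slots 0/5/17.
#' @param handedness `"left"` or `"right"`; defaults to the set's tag.
#' @return Unit normal vector (length-3 numeric).
#' @export
palm_normal <- function(hand, frame = palm_frame(), handedness = NULL) {
  stopifnot(inherits(hand, "acumap_landmarks"))
  if (hand$region != "hand") abort_invalid_input("palm_normal() needs a hand landmark set")
  handedness <- handedness %||% hand$handedness %||% "right"
  p0 <- lm_point(hand, frame$reference_index)
  p1 <- lm_point(hand, frame$secondary_indices[1])
  p2 <- lm_point(hand, frame$secondary_indices[2])
  n <- cross_product(p1 - p0, p2 - p0)
  nn <- vnorm(n)
  if (nn < 1e-12) abort_degenerate("palm frame landmarks are collinear")
  n <- n / nn
  # Raw cross product points +z (away from viewer) for a right palm facing
  # the camera and -z for a left palm; flip so both read (0,0,-1).
  if (handedness == "right") n <- -n
  n
}

#' Classify hand posture
#'
#' Computes the palm normal, takes its angle to the viewer-facing optical
#' axis `(0, 0, -1)` and applies the documented thresholds: `front` below 45
#' degrees, `back` at or above 135, otherwise `inside`/`outside` by the
#' lateral sign of the normal (convention flipped for left hands).
#'
#' @param hand A 21-slot hand `acumap_landmarks`.
#' @param handedness `"left"` or `"right"`; defaults to the set's tag, else
#'   `"right"`.
#' @param frame A [palm_frame()].
#' @param thresholds Named list, see [posture_thresholds()].
#' @return A `hand_posture` list: `label`, `palm_angle_deg` in `[0, 180]`,
#'   unit `normal`.
#' @export
classify_hand_posture <- function(hand, handedness = NULL, frame = palm_frame(),
                                  thresholds = posture_thresholds()) {
  handedness <- handedness %||% hand$handedness %||% "right"
  n <- palm_normal(hand, frame, handedness)
  angle_deg <- angle_between(n, c(0, 0, -1)) * 180 / pi
  if (angle_deg < thresholds$hand_front_max_deg) {
    label <- "front"
  } else if (angle_deg >= thresholds$hand_back_min_deg) {
    label <- "back"
  } else {
    lateral <- if (handedness == "right") n[1] < 0 else n[1] > 0
    label <- if (lateral) "inside" else "outside"
  }
  log_msg("debug", sprintf("hand posture %s (angle %.1f deg, nx %.3f)",
                           label, angle_deg, n[1]))
  structure(list(label = label, palm_angle_deg = angle_deg, normal = n),
            class = "hand_posture")
}

# Face slots used by the yaw proxy: nose tip and the two lateral contours.
face_yaw_slots <- function() c(nose = 1L, right = 234L, left = 454L)

#' Classify face pose
#'
#' The yaw proxy is the signed relative difference of the projected (2D)
#' nose-tip-to-contour distances on the two sides of the face:
#' `(d_left - d_right) / (d_left + d_right)`. Turning the head to the
#' subject's right foreshortens the right contour, driving the proxy
#' positive, hence the label names the direction the head is turned. The
#' ratio is invariant to translation and uniform scaling.
#'
#' @param face A 468-slot face `acumap_landmarks`.
#' @param thresholds Named list, see [posture_thresholds()].
#' @return A `face_pose` list: `label` in center/left/right and `yaw_proxy`.
#' @export
classify_face_pose <- function(face, thresholds = posture_thresholds()) {
  stopifnot(inherits(face, "acumap_landmarks"))
  if (face$region != "face") abort_invalid_input("classify_face_pose() needs a face landmark set")
  slots <- face_yaw_slots()
  nose <- lm_point(face, slots[["nose"]])[1:2]
  right <- lm_point(face, slots[["right"]])[1:2]
  left <- lm_point(face, slots[["left"]])[1:2]
  d_left <- euclidean_distance(nose, left)
  d_right <- euclidean_distance(nose, right)
  if (d_left + d_right == 0) abort_degenerate("degenerate face: contour slots coincide with nose")
  proxy <- (d_left - d_right) / (d_left + d_right)
  label <- if (abs(proxy) < thresholds$face_yaw_threshold) "center"
           else if (proxy > 0) "right" else "left"
  log_msg("debug", sprintf("face pose %s (yaw proxy %.3f)", label, proxy))
  structure(list(label = label, yaw_proxy = proxy), class = "face_pose")
}
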