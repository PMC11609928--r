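#' Landmark sets
#'
#' A landmark set holds the indexed anatomical keypoints detected for one hand
#' (21 slots) or one face (468 slots). Slots are 0-based, matching the
#' upstream landmark-provider schemas; internally they are rows `slot + 1` of
#' a numeric `n x 3` matrix (columns x, y, z; `NA` rows mark absent slots).
#' Coordinates are tagged with their space: `"pixel"` (origin top-left,
#' y down) or `"normalized"` (x, y in `[0, 1]`, scaled by image width/height
#' on conversion; z is scaled by width, following the usual provider
#' convention).
#'
#' @param region `"hand"` or `"face"`.
#' @param points Numeric matrix with one row per slot (21 or 468) and 2 or 3
#'   columns; a third column of zeros is added when absent.
#' @param space `"pixel"` (default) or `"normalized"`.
#' @param handedness For hands: `"left"` or `"right"`.
#' @param image_size Optional `c(width, height)` in pixels; required to
#'   convert between spaces and to mirror pixel-space sets.
#' @return An object of class `acumap_landmarks`.
#' @export
landmark_set <- function(region, points, space = c("pixel", "normalized"),
                         handedness = NULL, image_size = NULL) {
  space <- match.arg(space)
  n_slots <- region_slots(region)
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (ncol(points) != 3L) abort_invalid_input("points must have 2 or 3 columns")
  if (nrow(points) != n_slots) {
    abort_invalid_input(sprintf("%s landmark set must have %d slots, got %d",
                                region, n_slots, nrow(points)))
  }
  storage.mode(points) <- "double"
  present <- stats::complete.cases(points)
  if (any(!is.finite(points[present, ]))) {
    abort_invalid_input("landmark coordinates must be finite or wholly NA")
  }
  if (space == "normalized") {
    xy <- points[present, 1:2, drop = FALSE]
    if (length(xy) > 0 && (min(xy) < 0 || max(xy) > 1)) {
      abort_invalid_input("normalized coordinates must lie in [0, 1]")
    }
  }
  if (!is.null(handedness)) handedness <- match.arg(handedness, c("left", "right"))
  if (region == "face") handedness <- NULL
  if (!is.null(image_size)) {
    image_size <- as.numeric(image_size)
    if (length(image_size) != 2L || any(!is.finite(image_size)) || any(image_size <= 0)) {
      abort_invalid_input("image_size must be c(width, height) with positive values")
    }
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(region = region, handedness = handedness, points = points,
                 space = space, image_size = image_size),
            class = "acumap_landmarks")
}

# Fetch slot i (0-based) as a length-3 point; error if absent.
lm_point <- function(set, i) {
  p <- set$points[i + 1L, ]
  if (anyNA(p)) abort_rule(sprintf("landmark slot %d is absent", i))
  unname(p)
}

#' Convert a landmark set to pixel space
#'
#' Normalized x is scaled by image width, y by height, z by width. Pixel-space
#' sets are returned unchanged.
#'
#' @param set An `acumap_landmarks`.
#' @return The set in pixel space.
#' @export
to_pixel_space <- function(set) {
  stopifnot(inherits(set, "acumap_landmarks"))
  if (set$space == "pixel") return(set)
  if (is.null(set$image_size)) {
    abort_invalid_input("image_size is required to convert normalized coordinates to pixels")
  }
  w <- set$image_size[1]; h <- set$image_size[2]
  pts <- set$points
  pts[, 1] <- pts[, 1] * w
  pts[, 2] <- pts[, 2] * h
  pts[, 3] <- pts[, 3] * w
  landmark_set(set$region, pts, space = "pixel",
               handedness = set$handedness, image_size = set$image_size)
}

#' Left/right slot correspondences of the face schema
#'
#' The subset of 468-slot face landmarks this package references, paired
#' left/right. Mirroring swaps these pairs so slot semantics ("subject's
#' left cheek contour") stay attached to the correct physical side, exactly
#' as a landmark detector re-run on the mirrored image would report them.
#'
#' @return Integer matrix with columns `right` and `left` (0-based slots).
#' @export
face_mirror_pairs <- function() {
  matrix(c(234L, 454L,
           33L, 263L,
           133L, 362L,
           55L, 285L,
           105L, 334L,
           70L, 300L,
           58L, 288L,
           61L, 291L,
           64L, 294L,
           101L, 330L,
           132L, 361L,
           136L, 365L,
           145L, 374L,
           216L, 436L,
           227L, 447L),
         ncol = 2, byrow = TRUE, dimnames = list(NULL, c("right", "left")))
}

#' Mirror a landmark set about the vertical image midline
#'
#' X-coordinates are reflected about the image midline. For hands the
#' handedness tag is flipped; for faces the known left/right slot pairs are
#' swapped so that, e.g., the subject's-left contour slot still holds the
#' subject's-left contour after mirroring (see [face_mirror_pairs()]).
#' Mirroring twice returns the original set.
#'
#' @param set An `acumap_landmarks`. Pixel-space sets require `image_size`.
#' @return The mirrored `acumap_landmarks`.
#' @export
mirror_landmarks <- function(set) {
  stopifnot(inherits(set, "acumap_landmarks"))
  if (set$space == "pixel" && is.null(set$image_size)) {
    abort_invalid_input("mirroring a pixel-space set requires image_size")
  }
  width <- if (set$space == "pixel") set$image_size[1] else 1
  pts <- set$points
  pts[, 1] <- width - pts[, 1]
  if (set$region == "face") {
    pairs <- face_mirror_pairs()
    tmp <- pts[pairs[, 1] + 1L, , drop = FALSE]
    pts[pairs[, 1] + 1L, ] <- pts[pairs[, 2] + 1L, , drop = FALSE]
    pts[pairs[, 2] + 1L, ] <- tmp
  }
  handedness <- set$handedness
  if (set$region == "hand" && !is.null(handedness)) {
    handedness <- if (handedness == "left") "right" else "left"
  }
  landmark_set(set$region, pts, space = set$space,
               handedness = handedness, image_size = set$image_size)
}

#' @export
print.acumap_landmarks <- function(x, ...) {
  present <- sum(stats::complete.cases(x$points))
  cat(sprintf("<acumap_landmarks> %s%s, %d/%d slots, %s space%s\n",
              x$region,
              if (!is.null(x$handedness)) paste0(" (", x$handedness, ")") else "",
              present, nrow(x$points), x$space,
              if (!is.null(x$image_size))
                sprintf(", image %gx%g", x$image_size[1], x$image_size[2]) else ""))
  invisible(x)
}
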