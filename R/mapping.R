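#' Evaluate one mapping rule against a landmark set
#'
#' Steps are evaluated in order in 2D pixel space (z takes part in posture
#' classification only, never in rule projection); the final step's point is
#' the result. Evaluation is a pure function of the landmark set and the
#' rule, so identical inputs yield bit-identical outputs.
#'
#' @param rule An `acumap_rule` from [rules_for()], or a bare list with a
#'   `steps` field in the rule-table step language.
#' @param landmarks An `acumap_landmarks` in pixel space (normalized sets are
#'   converted when `image_size` is present).
#' @return Length-2 numeric `c(x, y)` in pixels.
#' @examples
#' reg <- load_registry()
#' hand <- gen_hand_landmarks("front", seed = 1)
#' apply_rule(rules_for(reg, "HT-8", "front"), hand)
#' @export
apply_rule <- function(rule, landmarks) {
  if (is_not_visible(rule)) abort_rule("rule is not visible for this posture")
  steps <- rule$steps
  if (length(steps) == 0) abort_rule("rule has no steps")
  landmarks <- to_pixel_space(landmarks)
  resolved <- vector("list", length(steps))
  resolve_ref <- function(ref, k) {
    if (!is.null(ref$lm)) return(lm_point(landmarks, as.integer(ref$lm))[1:2])
    if (!is.null(ref$step)) {
      s <- as.integer(ref$step)
      if (s < 1 || s >= k) abort_rule(sprintf("step %d references invalid step %d", k, s))
      return(resolved[[s]])
    }
    abort_rule(sprintf("step %d has an operand that is neither {lm} nor {step}", k))
  }
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    resolved[[k]] <- switch(
      st$op,
      anchor = lm_point(landmarks, as.integer(st$lm))[1:2],
      midpoint = midpoint(resolve_ref(st$a, k), resolve_ref(st$b, k))[1:2],
      fraction = fraction_point(resolve_ref(st$a, k), resolve_ref(st$b, k),
                                as.numeric(st$t))[1:2],
      toward = {
        base <- euclidean_distance(resolve_ref(st$base_a, k), resolve_ref(st$base_b, k))
        point_along(resolve_ref(st$origin, k), resolve_ref(st$target, k),
                    as.numeric(st$scale) * base)[1:2]
      },
      offset = {
        base <- euclidean_distance(resolve_ref(st$base_a, k), resolve_ref(st$base_b, k))
        from <- resolve_ref(st$from, k)
        dir <- resolve_ref(st$dir_b, k) - resolve_ref(st$dir_a, k)
        nd <- vnorm(dir)
        if (nd == 0) abort_degenerate("offset step has a zero direction vector")
        (from + as.numeric(st$scale) * base * dir / nd)[1:2]
      },
      abort_rule(sprintf("unknown step op '%s'", st$op))
    )
  }
  resolved[[length(steps)]]
}

#' Map all registry acupoints for a landmark set
#'
#' Classifies the hand posture (or face pose), then evaluates every registry
#' entry of the set's region under that label. Entries without a rule for the
#' label are returned with `visible = FALSE` and NA coordinates. Left hands
#' are mirrored to the right-hand rule frame, mapped, and mirrored back, so
#' one authored rule serves both hands. Output rows follow registry order;
#' coordinates are pixels.
#'
#' @param landmarks An `acumap_landmarks`.
#' @param registry An `acumap_registry`; default [load_registry()].
#' @param posture Optional label overriding the classifier.
#' @return A data.frame (`acumap_predictions`) with columns `code`, `x`, `y`,
#'   `posture`, `visible`, `confidence`; the classification result is
#'   attached as attribute `"classification"`.
#' @export
map_acupoints <- function(landmarks, registry = load_registry(), posture = NULL) {
  stopifnot(inherits(landmarks, "acumap_landmarks"))
  landmarks <- to_pixel_space(landmarks)
  mirrored <- FALSE
  classification <- NULL
  if (landmarks$region == "hand") {
    classification <- classify_hand_posture(landmarks)
    if (identical(landmarks$handedness, "left")) {
      if (is.null(landmarks$image_size)) {
        abort_invalid_input("mapping a left hand requires image_size for mirroring")
      }
      landmarks <- mirror_landmarks(landmarks)
      mirrored <- TRUE
    }
  } else {
    classification <- classify_face_pose(landmarks)
  }
  label <- posture %||% classification$label

  entries <- Filter(function(e) e$region == landmarks$region, registry$entries)
  n <- length(entries)
  out <- data.frame(code = character(n), x = rep(NA_real_, n), y = rep(NA_real_, n),
                    posture = rep(label, n), visible = rep(FALSE, n),
                    confidence = rep(1, n))
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    out$code[i] <- entry$code
    rule <- rules_for(registry, entry$code, label)
    if (is_not_visible(rule)) next
    p <- tryCatch(apply_rule(rule, landmarks), error = function(e) {
      abort_rule(sprintf("acupoint %s: %s", entry$code, conditionMessage(e)))
    })
    out$x[i] <- p[1]; out$y[i] <- p[2]; out$visible[i] <- TRUE
  }
  if (mirrored) {
    out$x[out$visible] <- landmarks$image_size[1] - out$x[out$visible]
  }
  attr(out, "classification") <- classification
  class(out) <- c("acumap_predictions", class(out))
  out
}

#' Draw predicted acupoints onto a raster image
#'
#' Pure function: returns a modified copy of `image` with a filled disc at
#' each visible prediction's rounded pixel. `image` is a numeric matrix
#' (height x width) or array (height x width x channels); pixel `(x, y)` maps
#' to row `round(y) + 1`, column `round(x) + 1`. Out-of-bounds predictions
#' are skipped with one warning.
#'
#' @param image Numeric matrix or 3D array.
#' @param predictions Data.frame from [map_acupoints()].
#' @param radius Dot radius in pixels.
#' @param value Intensity (matrix) or per-channel values (array) of the dots.
#' @return The annotated copy of `image`.
#' @export
overlay_predictions <- function(image, predictions, radius = 2, value = 1) {
  dims <- dim(image)
  if (is.null(dims) || !length(dims) %in% c(2L, 3L)) {
    abort_invalid_input("image must be a matrix or a 3D array")
  }
  h <- dims[1]; w <- dims[2]
  channels <- if (length(dims) == 3L) dims[3] else 1L
  value <- rep_len(value, channels)
  vis <- predictions[!is.na(predictions$x) & predictions$visible, , drop = FALSE]
  skipped <- 0L
  for (i in seq_len(nrow(vis))) {
    cx <- round(vis$x[i]); cy <- round(vis$y[i])
    if (cx < 0 || cx >= w || cy < 0 || cy >= h) {
      skipped <- skipped + 1L
      next
    }
    rows <- max(0, cy - radius):min(h - 1, cy + radius)
    cols <- max(0, cx - radius):min(w - 1, cx + radius)
    for (r in rows) for (cc in cols) {
      if ((r - cy)^2 + (cc - cx)^2 <= radius^2) {
        if (channels == 1L) image[r + 1, cc + 1] <- value
        else image[r + 1, cc + 1, ] <- value
      }
    }
  }
  if (skipped > 0) {
    warning(sprintf("skipped %d out-of-bounds prediction(s)", skipped))
  }
  image
}
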