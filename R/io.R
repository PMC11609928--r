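#' Read and write landmark sets (acumap-landmarks/1 JSON)
#'
#' The landmark file format is a small versioned JSON schema: `format`
#' (`"acumap-landmarks/1"`), `region`, optional `handedness`, `space`,
#' optional `image_size` `[width, height]`, and `points`, an array of
#' `{slot, x, y, z}` objects (absent slots omitted). Files round-trip:
#' `read_landmarks(write_landmarks(set, f))` equals `set`.
#'
#' @param path File path.
#' @return `read_landmarks()` returns an `acumap_landmarks`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("landmark file not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_parse(sprintf(
                    "%s: not valid JSON: %s", path, conditionMessage(e))))
  if (!identical(raw$format, "acumap-landmarks/1")) {
    abort_parse(sprintf("%s: $.format must be 'acumap-landmarks/1'", path))
  }
  region <- raw$region
  if (!identical(region, "hand") && !identical(region, "face")) {
    abort_parse(sprintf("%s: $.region must be 'hand' or 'face'", path))
  }
  space <- raw$space %||% "pixel"
  if (!space %in% c("pixel", "normalized")) {
    abort_parse(sprintf("%s: $.space must be 'pixel' or 'normalized'", path))
  }
  n_slots <- region_slots(region)
  pts <- matrix(NA_real_, nrow = n_slots, ncol = 3)
  for (j in seq_along(raw$points)) {
    p <- raw$points[[j]]
    slot <- p$slot
    if (is.null(slot) || slot < 0 || slot >= n_slots) {
      abort_parse(sprintf("%s: $.points[%d].slot out of range for %s schema",
                          path, j - 1L, region))
    }
    for (field in c("x", "y")) {
      if (is.null(p[[field]]) || !is.finite(as.numeric(p[[field]]))) {
        abort_parse(sprintf("%s: $.points[%d].%s missing or non-finite", path, j - 1L, field))
      }
    }
    pts[slot + 1L, ] <- c(as.numeric(p$x), as.numeric(p$y), as.numeric(p$z %||% 0))
  }
  image_size <- if (!is.null(raw$image_size)) as.numeric(unlist(raw$image_size))
  tryCatch(
    landmark_set(region, pts, space = space,
                 handedness = raw$handedness, image_size = image_size),
    acumap_invalid_input = function(e) abort_parse(sprintf("%s: %s", path, conditionMessage(e)))
  )
}

#' @rdname read_landmarks
#' @param set An `acumap_landmarks`.
#' @return `write_landmarks()` returns `path` invisibly.
#' @export
write_landmarks <- function(set, path) {
  stopifnot(inherits(set, "acumap_landmarks"))
  present <- which(stats::complete.cases(set$points))
  points <- lapply(present, function(r) {
    list(slot = r - 1L, x = set$points[r, 1], y = set$points[r, 2], z = set$points[r, 3])
  })
  out <- list(format = "acumap-landmarks/1", region = set$region)
  if (!is.null(set$handedness)) out$handedness <- set$handedness
  out$space <- set$space
  if (!is.null(set$image_size)) out$image_size <- I(set$image_size)
  out$points <- points
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# Ordered keypoint names (acupoint codes) for a region, registry order.
region_codes <- function(registry, region) {
  s <- registry_summary(registry)
  s$code[s$region == region]
}

#' Write COCO keypoint ground truth
#'
#' One category per region whose ordered keypoint names are the acupoint
#' codes in registry order; one annotation per image with `(x, y, v)`
#' triplets (v = 2 labeled-visible, 0 absent), a bounding box `[x, y, w, h]`
#' and its area.
#'
#' @param gt Data.frame: `image_id`, `code`, `x`, `y`, `bbox_x`, `bbox_y`,
#'   `bbox_w`, `bbox_h`.
#' @param images Data.frame: `id`, `width`, `height`, `file_name`.
#' @param registry An `acumap_registry`.
#' @param path Output path.
#' @param region `"hand"` or `"face"`.
#' @return `path`, invisibly.
#' @export
write_coco_ground_truth <- function(gt, images, registry, path, region = "hand") {
  codes <- region_codes(registry, region)
  annotations <- list()
  aid <- 0L
  for (img in images$id) {
    rows <- gt[gt$image_id == img, , drop = FALSE]
    if (nrow(rows) == 0) next
    kp <- numeric(3 * length(codes))
    for (r in seq_len(nrow(rows))) {
      ci <- match(rows$code[r], codes)
      if (is.na(ci)) abort_validation(sprintf("code '%s' not in %s category", rows$code[r], region))
      kp[(3 * (ci - 1) + 1):(3 * ci)] <- c(rows$x[r], rows$y[r], 2)
    }
    aid <- aid + 1L
    annotations[[aid]] <- list(
      id = aid, image_id = img, category_id = 1L,
      keypoints = I(kp), num_keypoints = nrow(rows),
      bbox = I(c(rows$bbox_x[1], rows$bbox_y[1], rows$bbox_w[1], rows$bbox_h[1])),
      area = rows$bbox_w[1] * rows$bbox_h[1], iscrowd = 0L)
  }
  out <- list(
    images = lapply(seq_len(nrow(images)), function(i) list(
      id = images$id[i], width = images$width[i], height = images$height[i],
      file_name = images$file_name[i])),
    categories = list(list(id = 1L, name = region, supercategory = "person",
                           keypoints = I(codes), skeleton = I(list()))),
    annotations = annotations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read COCO keypoint ground truth
#'
#' @param path COCO keypoint JSON file.
#' @param registry An `acumap_registry`; keypoint names must resolve to
#'   registry codes.
#' @return Data.frame with one row per (image, code) whose visibility flag
#'   is > 0: `image_id`, `code`, `x`, `y`, `bbox_x/y/w/h`.
#' @export
read_coco_ground_truth <- function(path, registry = load_registry()) {
  if (!file.exists(path)) abort_parse(sprintf("ground-truth file not found: %s", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_parse(sprintf(
                    "%s: not valid JSON: %s", path, conditionMessage(e))))
  if (is.null(raw$categories)) abort_parse(sprintf("%s: missing 'categories' block", path))
  known <- registry_summary(registry)$code
  cat_kp <- list()
  for (cat in raw$categories) {
    kp_names <- unlist(cat$keypoints)
    unknown <- setdiff(kp_names, known)
    if (length(unknown) > 0) {
      abort_acumap(sprintf("%s: keypoint name(s) not in registry: %s",
                           path, paste(unknown, collapse = ", ")),
                   "acumap_mapping_error")
    }
    cat_kp[[as.character(cat$id)]] <- kp_names
  }
  rows <- list()
  for (ann in raw$annotations) {
    kp_names <- cat_kp[[as.character(ann$category_id)]]
    kp <- unlist(ann$keypoints)
    bbox <- unlist(ann$bbox %||% rep(NA_real_, 4))
    for (ci in seq_along(kp_names)) {
      v <- kp[3 * ci]
      if (is.na(v) || v <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = ann$image_id, code = kp_names[ci],
        x = kp[3 * ci - 2], y = kp[3 * ci - 1],
        bbox_x = bbox[1], bbox_y = bbox[2], bbox_w = bbox[3], bbox_h = bbox[4])
    }
  }
  if (length(rows) == 0) {
    return(data.frame(image_id = integer(0), code = character(0),
                      x = numeric(0), y = numeric(0), bbox_x = numeric(0),
                      bbox_y = numeric(0), bbox_w = numeric(0), bbox_h = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Read and write prediction tables
#'
#' CSV columns: `image_id`, `code`, `x`, `y`, `posture`, `visible`,
#' `confidence`; coordinates are written with 1-decimal fixed precision (the
#' COCO-results JSON written by [write_predictions_coco()] keeps full
#' precision).
#'
#' @param preds Prediction data.frame (see [map_acupoints()]); an `image_id`
#'   column is added as 1 when absent.
#' @param path File path.
#' @return The path (writers, invisibly) or a data.frame (reader).
#' @export
write_predictions_csv <- function(preds, path) {
  if (!"image_id" %in% names(preds)) preds$image_id <- 1L
  out <- data.frame(image_id = preds$image_id, code = preds$code,
                    x = sprintf("%.1f", preds$x), y = sprintf("%.1f", preds$y),
                    posture = preds$posture, visible = preds$visible,
                    confidence = preds$confidence)
  out$x[is.na(preds$x)] <- ""
  out$y[is.na(preds$y)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("prediction file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image_id", "code", "x", "y", "visible")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort_parse(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  df$visible <- as.logical(df$visible)
  if (!"confidence" %in% names(df)) df$confidence <- 1
  df
}

#' @rdname write_predictions_csv
#' @param registry An `acumap_registry` (fixes the keypoint ordering).
#' @param region Region of the predictions.
#' @export
write_predictions_coco <- function(preds, path, registry = load_registry(),
                                   region = "hand") {
  if (!"image_id" %in% names(preds)) preds$image_id <- 1L
  codes <- region_codes(registry, region)
  results <- list()
  for (img in unique(preds$image_id)) {
    rows <- preds[preds$image_id == img, , drop = FALSE]
    kp <- numeric(3 * length(codes))
    for (r in which(rows$visible)) {
      ci <- match(rows$code[r], codes)
      kp[(3 * (ci - 1) + 1):(3 * ci)] <- c(rows$x[r], rows$y[r], 2)
    }
    results[[length(results) + 1L]] <- list(
      image_id = img, category_id = 1L, keypoints = I(kp),
      score = mean(rows$confidence))
  }
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Evaluate prediction and ground-truth files
#'
#' File-level wrapper around [evaluate_predictions()]: reads a prediction CSV
#' and a COCO keypoint ground-truth JSON, optionally builds a calibration
#' from a reference length, and returns the full report.
#'
#' @param pred_file Prediction CSV path.
#' @param gt_file COCO ground-truth JSON path.
#' @param registry An `acumap_registry`.
#' @param ref_cm,ref_px Optional reference-object lengths for calibration.
#' @param oks_k OKS falloff constant.
#' @return An `acumap_eval_report`.
#' @export
evaluate_files <- function(pred_file, gt_file, registry = load_registry(),
                           ref_cm = NULL, ref_px = NULL, oks_k = 0.02) {
  preds <- read_predictions_csv(pred_file)
  gts <- read_coco_ground_truth(gt_file, registry)
  calib <- if (!is.null(ref_cm) && !is.null(ref_px)) {
    calibrate_from_reference(ref_cm, ref_px)
  }
  evaluate_predictions(preds, gts, calib = calib, oks_k = oks_k)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `acumap_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "acumap_eval_report"))
  out <- list(
    n_pairs = report$n_pairs,
    mean_distance_px = report$mean_distance$mean,
    ci95 = I(report$mean_distance$ci),
    ks_x = report$ks_x, ks_y = report$ks_y,
    counts = as.list(report$counts),
    precision_pct = report$precision, recall_pct = report$recall,
    ap_per_category = as.list(report$ap_per_category),
    map50 = report$map50, map5095 = report$map5095,
    oks_k = report$oks_k, oks_threshold = report$oks_threshold,
    mean_error_mm = if (!is.null(report$calibrated_errors_mm))
      mean(report$calibrated_errors_mm) else NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Package configuration
#'
#' A single JSON file of overridable settings. Unknown keys are rejected
#' (typo safety). Keys and defaults: `registry_path` (shipped table),
#' `hand_front_max_deg` 45, `hand_back_min_deg` 135, `face_yaw_threshold`
#' 0.2, `oks_k` 0.02, `oks_thresholds` 0.50:0.05:0.95, `default_ref_cm` /
#' `default_ref_px` (none), `log_level` `"warn"`.
#'
#' @param path Optional JSON config file overriding the defaults.
#' @return Named list of settings.
#' @export
acumap_config <- function(path = NULL) {
  cfg <- list(
    registry_path = NULL,
    hand_front_max_deg = 45,
    hand_back_min_deg = 135,
    face_yaw_threshold = 0.2,
    oks_k = 0.02,
    oks_thresholds = seq(0.5, 0.95, by = 0.05),
    default_ref_cm = NULL,
    default_ref_px = NULL,
    log_level = "warn")
  if (!is.null(path)) {
    if (!file.exists(path)) abort_parse(sprintf("config file not found: %s", path))
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      abort_validation(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(user)] <- user
  }
  if (cfg$hand_front_max_deg <= 0 || cfg$hand_front_max_deg >= cfg$hand_back_min_deg ||
      cfg$hand_back_min_deg > 180 || cfg$face_yaw_threshold <= 0 ||
      cfg$face_yaw_threshold >= 1 || cfg$oks_k <= 0) {
    abort_validation("config thresholds outside documented ranges")
  }
  cfg
}
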