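#' Pixel-to-physical calibration from a reference object
#'
#' A reference object of known physical length spanning a known pixel length
#' fixes the scene scale. The reported factor is truncated (not rounded)
#' toward zero at 4 decimals, matching the convention of quoting, e.g.,
#' 80 cm / 1488 px as 0.0537 cm per pixel; the untruncated ratio is kept in
#' `raw_cm_per_pixel`.
#'
#' @param length_cm Reference length in centimeters (> 0).
#' @param length_px The same length in pixels (> 0).
#' @return A `calibration_model` list: `cm_per_pixel` (truncated),
#'   `raw_cm_per_pixel`, `reference_length_cm`, `reference_length_px`.
#' @examples
#' calibrate_from_reference(80, 1488)$cm_per_pixel # 0.0537
#' @export
calibrate_from_reference <- function(length_cm, length_px) {
  if (!is.finite(length_cm) || length_cm <= 0 || !is.finite(length_px) || length_px <= 0) {
    abort_invalid_input("calibration lengths must be positive and finite")
  }
  raw <- length_cm / length_px
  structure(list(cm_per_pixel = trunc(raw * 1e4) / 1e4,
                 raw_cm_per_pixel = raw,
                 reference_length_cm = length_cm,
                 reference_length_px = length_px),
            class = "calibration_model")
}

#' Convert a pixel error to millimeters
#'
#' @param error_px Nonnegative pixel error(s).
#' @param calib A [calibrate_from_reference()] model.
#' @return `error_px * cm_per_pixel * 10`, in mm.
#' @examples
#' pixels_to_mm(10, calibrate_from_reference(80, 1488)) # 5.37
#' @export
pixels_to_mm <- function(error_px, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  if (any(!is.finite(error_px)) || any(error_px < 0)) {
    abort_invalid_input("pixel errors must be nonnegative and finite")
  }
  error_px * calib$cm_per_pixel * 10
}

#' Localization error between a prediction and its ground truth
#'
#' The Euclidean distance in image space between matching predicted and
#' annotated positions. Inputs are rows (lists/one-row data.frames) carrying
#' `code`, `x`, `y` and optionally `image_id`; codes (and image ids, when
#' both present) must agree.
#'
#' @param pred,gt Prediction and ground-truth records.
#' @return Distance in pixels.
#' @export
distance_error <- function(pred, gt) {
  if (!identical(as.character(pred$code), as.character(gt$code))) {
    abort_acumap(sprintf("cannot pair prediction '%s' with ground truth '%s'",
                         pred$code, gt$code), "acumap_pairing_error")
  }
  if (!is.null(pred$image_id) && !is.null(gt$image_id) &&
      !identical(pred$image_id, gt$image_id)) {
    abort_acumap("prediction and ground truth are from different images",
                 "acumap_pairing_error")
  }
  euclidean_distance(c(pred$x, pred$y), c(gt$x, gt$y))
}

#' Object keypoint similarity
#'
#' `OKS = exp(-d^2 / (2 s^2 k^2))`: a scale-normalized keypoint agreement
#' score in `(0, 1]`, strictly decreasing in the distance `d`. `s` is the
#' object scale in pixels (here the square root of the ground-truth bounding
#' box area) and `k` the per-keypoint falloff constant, 0.02 for all
#' acupoints.
#'
#' @param d Nonnegative pixel distance(s).
#' @param params List with positive `k` and `s`, see [oks_params()].
#' @return Similarity value(s) in `(0, 1]`.
#' @export
oks <- function(d, params) {
  if (any(!is.finite(d)) || any(d < 0)) abort_invalid_input("OKS distance must be >= 0")
  exp(-d^2 / (2 * params$s^2 * params$k^2))
}

#' @rdname oks
#' @param k Per-keypoint constant (> 0), default 0.02.
#' @param s Object scale in pixels (> 0).
#' @export
oks_params <- function(k = 0.02, s) {
  if (!is.finite(k) || k <= 0 || !is.finite(s) || s <= 0) {
    abort_invalid_input("OKS parameters k and s must be positive")
  }
  list(k = k, s = s)
}

#' Precision and recall from detection counts
#'
#' `precision = 100 TP / (TP + FP)`, `recall = 100 TP / (TP + FN)`, both in
#' percent. An undefined ratio (zero denominator) is reported as `NA`.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return Named numeric `c(precision, recall)` in percent.
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort_invalid_input("counts must be nonnegative")
  c(precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_)
}

#' Greedy OKS matching of predictions to ground truth
#'
#' Within one image and category: predictions are visited in descending
#' confidence; each matches the unmatched ground truth with the highest OKS,
#' provided that OKS reaches the threshold (ties broken by ground-truth
#' order). Unmatched predictions are false positives, unmatched ground truths
#' false negatives.
#'
#' @param preds Data.frame with `x`, `y` and optional `confidence` (default 1).
#' @param gts Data.frame with `x`, `y` and `s` (per-annotation OKS scale).
#' @param threshold OKS threshold in `(0, 1)`.
#' @param k OKS falloff constant.
#' @return List: `tp`, `fp`, `fn`, `matches` (data.frame `pred`, `gt`, `oks`
#'   of 1-based row indices).
#' @export
match_by_oks <- function(preds, gts, threshold = 0.5, k = 0.02) {
  np <- if (is.null(preds)) 0L else nrow(preds)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (np == 0) {
    return(list(tp = 0L, fp = 0L, fn = ng,
                matches = data.frame(pred = integer(0), gt = integer(0), oks = numeric(0))))
  }
  conf <- if ("confidence" %in% names(preds)) preds$confidence else rep(1, np)
  order_p <- order(-conf, seq_len(np))
  gt_used <- rep(FALSE, ng)
  matches <- list()
  for (pi in order_p) {
    if (ng == 0) break
    best_gt <- 0L; best_oks <- -Inf
    for (gi in seq_len(ng)) {
      if (gt_used[gi]) next
      d <- sqrt((preds$x[pi] - gts$x[gi])^2 + (preds$y[pi] - gts$y[gi])^2)
      o <- oks(d, oks_params(k = k, s = gts$s[gi]))
      if (o > best_oks) { best_oks <- o; best_gt <- gi }
    }
    if (best_gt > 0L && best_oks >= threshold) {
      gt_used[best_gt] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(pred = pi, gt = best_gt, oks = best_oks)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches)
             else data.frame(pred = integer(0), gt = integer(0), oks = numeric(0))
  tp <- nrow(matches)
  list(tp = tp, fp = np - tp, fn = ng - tp, matches = matches)
}

# Average precision for one category at one OKS threshold, 101-point
# interpolated over recall. detections: data.frame(image_id, x, y,
# confidence); gts: data.frame(image_id, x, y, s).
average_precision <- function(detections, gts, threshold, k = 0.02) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(NA_real_)
  if (is.null(detections) || nrow(detections) == 0) return(0)
  is_tp <- logical(0)
  confs <- numeric(0)
  for (img in unique(c(detections$image_id, gts$image_id))) {
    p <- detections[detections$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    if (nrow(p) == 0) next
    m <- match_by_oks(p, g, threshold = threshold, k = k)
    flags <- rep(FALSE, nrow(p))
    flags[m$matches$pred] <- TRUE
    is_tp <- c(is_tp, flags)
    confs <- c(confs, if ("confidence" %in% names(p)) p$confidence else rep(1, nrow(p)))
  }
  ord <- order(-confs)
  is_tp <- is_tp[ord]
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope, then 101-point interpolation
  for (i in rev(seq_along(precision))[-1]) {
    precision[i] <- max(precision[i], precision[i + 1])
  }
  grid <- seq(0, 1, by = 0.01)
  interp <- vapply(grid, function(r) {
    ok <- recall >= r
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1))
  mean(interp)
}

#' Mean average precision over categories
#'
#' @param ap_per_category Named numeric vector or list of per-category AP
#'   values in `[0, 1]` (NAs, from categories without ground truth, are
#'   dropped).
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(ap_per_category) {
  ap <- unlist(ap_per_category)
  ap <- ap[!is.na(ap)]
  if (length(ap) == 0) abort_invalid_input("mean_ap() needs at least one category")
  mean(ap)
}

#' Mean error with a 95% confidence interval
#'
#' Normal-approximation interval `mean +/- 1.96 sd / sqrt(n)`; degenerate
#' (equal to the mean) when `n = 1`.
#'
#' @param errors Nonempty numeric vector of pixel errors.
#' @return List: `mean`, `ci` (length-2), `sd`, `n`.
#' @export
summarize_errors <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0 || any(!is.finite(errors))) {
    abort_invalid_input("summarize_errors() needs a nonempty finite sample")
  }
  m <- mean(errors)
  n <- length(errors)
  s <- if (n > 1) stats::sd(errors) else 0
  half <- 1.96 * s / sqrt(n)
  list(mean = m, ci = c(m - half, m + half), sd = s, n = n)
}

# Two-sample KS statistic by direct ECDF sup-difference.
ks_statistic <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

# Asymptotic Kolmogorov tail: P(sup > t) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_pvalue <- function(t) {
  if (t < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov–Smirnov comparison per axis
#'
#' Compares predicted and ground-truth coordinate distributions along one
#' axis: statistic is the supremum of the absolute ECDF difference, the
#' p-value is the asymptotic two-sample Kolmogorov approximation (suited to
#' the large samples this is used for; no tie correction).
#'
#' @param pred_values,gt_values Nonempty numeric samples.
#' @return List with `statistic` in `[0, 1]` and `p_value`.
#' @export
ks_axis_test <- function(pred_values, gt_values) {
  if (length(pred_values) == 0 || length(gt_values) == 0) {
    abort_invalid_input("KS test needs two nonempty samples")
  }
  d <- ks_statistic(pred_values, gt_values)
  m <- length(pred_values); n <- length(gt_values)
  t <- sqrt(m * n / (m + n)) * d
  list(statistic = d, p_value = kolmogorov_pvalue(t))
}

#' Full evaluation of predictions against ground truth
#'
#' Pairs predictions and annotations by image and acupoint code, then
#' computes the complete report: per-code pixel error distributions, overall
#' mean error with 95% CI, per-axis KS comparisons of the coordinate
#' distributions, OKS-thresholded TP/FP/FN counts with precision/recall,
#' per-code average precision (each code is its own category) at OKS 0.5 and
#' averaged over thresholds 0.50:0.05:0.95, and millimeter-calibrated errors
#' when a calibration is supplied. The OKS scale `s` per annotation is
#' `sqrt(bbox area)`; annotations without a bbox fall back to the square root
#' of the image's ground-truth keypoint bounding-box area.
#'
#' @param preds Data.frame of predictions: `image_id`, `code`, `x`, `y`,
#'   optional `confidence`, `visible`.
#' @param gts Data.frame of ground truth: `image_id`, `code`, `x`, `y`,
#'   optional `bbox_w`, `bbox_h`.
#' @param calib Optional [calibrate_from_reference()] model.
#' @param oks_k OKS falloff constant.
#' @param oks_threshold Threshold for the headline TP/FP/FN counts.
#' @return An `acumap_eval_report` list.
#' @export
evaluate_predictions <- function(preds, gts, calib = NULL, oks_k = 0.02,
                                 oks_threshold = 0.5) {
  if (!is.null(preds) && nrow(preds) > 0 && "visible" %in% names(preds)) {
    preds <- preds[preds$visible & !is.na(preds$x), , drop = FALSE]
  }
  if (is.null(gts) || nrow(gts) == 0) abort_invalid_input("no ground-truth annotations")
  if (is.null(preds)) preds <- data.frame(image_id = character(0), code = character(0),
                                          x = numeric(0), y = numeric(0))
  if (!"confidence" %in% names(preds)) preds$confidence <- rep(1, nrow(preds))

  # per-annotation OKS scale
  if (all(c("bbox_w", "bbox_h") %in% names(gts)) && !anyNA(gts$bbox_w)) {
    gts$s <- sqrt(gts$bbox_w * gts$bbox_h)
  } else {
    gts$s <- NA_real_
    for (img in unique(gts$image_id)) {
      sel <- gts$image_id == img
      w <- diff(range(gts$x[sel])); h <- diff(range(gts$y[sel]))
      gts$s[sel] <- sqrt(max(w * h, 1))
    }
  }

  key_p <- paste(preds$image_id, preds$code)
  key_g <- paste(gts$image_id, gts$code)
  common <- intersect(key_p, key_g)
  pi <- match(common, key_p); gi <- match(common, key_g)
  errors <- sqrt((preds$x[pi] - gts$x[gi])^2 + (preds$y[pi] - gts$y[gi])^2)
  per_code <- split(errors, gts$code[gi])

  codes <- sort(unique(gts$code))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap50 <- sapply(codes, function(cd) {
    average_precision(preds[preds$code == cd, , drop = FALSE],
                      gts[gts$code == cd, , drop = FALSE],
                      threshold = 0.5, k = oks_k)
  })
  ap5095 <- sapply(codes, function(cd) {
    mean(vapply(thresholds, function(th) {
      average_precision(preds[preds$code == cd, , drop = FALSE],
                        gts[gts$code == cd, , drop = FALSE],
                        threshold = th, k = oks_k)
    }, numeric(1)))
  })

  tp <- 0L; fp <- 0L; fn <- 0L
  for (img in unique(gts$image_id)) {
    for (cd in codes) {
      m <- match_by_oks(preds[preds$image_id == img & preds$code == cd, , drop = FALSE],
                        gts[gts$image_id == img & gts$code == cd, , drop = FALSE],
                        threshold = oks_threshold, k = oks_k)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
  }
  pr <- precision_recall(tp, fp, fn)

  report <- list(
    n_pairs = length(common),
    per_point_errors = per_code,
    mean_distance = if (length(errors) > 0) summarize_errors(errors) else NULL,
    ks_x = if (length(common) > 0) ks_axis_test(preds$x[pi], gts$x[gi]) else NULL,
    ks_y = if (length(common) > 0) ks_axis_test(preds$y[pi], gts$y[gi]) else NULL,
    counts = c(TP = tp, FP = fp, FN = fn),
    precision = pr[["precision"]],
    recall = pr[["recall"]],
    ap_per_category = ap50,
    map50 = mean_ap(ap50),
    map5095 = mean_ap(ap5095),
    oks_k = oks_k,
    oks_threshold = oks_threshold,
    calibration = calib,
    calibrated_errors_mm = if (!is.null(calib) && length(errors) > 0)
      pixels_to_mm(errors, calib) else NULL
  )
  class(report) <- "acumap_eval_report"
  report
}

#' @export
print.acumap_eval_report <- function(x, ...) {
  cat("<acumap_eval_report>\n")
  cat(sprintf("  matched pairs: %d\n", x$n_pairs))
  if (!is.null(x$mean_distance)) {
    cat(sprintf("  mean distance: %.2f px (95%% CI %.2f-%.2f)\n",
                x$mean_distance$mean, x$mean_distance$ci[1], x$mean_distance$ci[2]))
  }
  if (!is.null(x$calibrated_errors_mm)) {
    cat(sprintf("  mean distance: %.2f mm (calibrated)\n", mean(x$calibrated_errors_mm)))
  }
  cat(sprintf("  TP/FP/FN @OKS %.2f: %d/%d/%d  precision %.1f%%  recall %.1f%%\n",
              x$oks_threshold, x$counts[["TP"]], x$counts[["FP"]], x$counts[["FN"]],
              x$precision, x$recall))
  cat(sprintf("  mAP@50: %.3f  mAP@50-95: %.3f\n", x$map50, x$map5095))
  if (!is.null(x$ks_x)) {
    cat(sprintf("  KS x: D=%.3f p=%.3f   KS y: D=%.3f p=%.3f\n",
                x$ks_x$statistic, x$ks_x$p_value, x$ks_y$statistic, x$ks_y$p_value))
  }
  invisible(x)
}
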