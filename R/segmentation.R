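#' Rectangular region of interest
#'
#' Pixel-index rectangle stored 0-based and half-open (`row_start <= r <
#' row_stop`), matching the convention used for serialised ROIs. Use
#' [roi_rows()]/[roi_cols()] for the corresponding 1-based R indices.
#'
#' @param row_start,row_stop,col_start,col_stop 0-based half-open bounds.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row_start, row_stop, col_start, col_stop) {
  v <- c(row_start, row_stop, col_start, col_stop)
  if (!all(vapply(v, is_count, logical(1))) || any(v < 0)) {
    stop_pv("ROI bounds must be non-negative integers")
  }
  if (row_start >= row_stop || col_start >= col_stop) {
    stop_pv("degenerate ROI: start indices must be strictly below stop indices")
  }
  structure(list(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
                 col_start = as.integer(col_start), col_stop = as.integer(col_stop)),
            class = "rect_roi")
}

#' @rdname rect_roi
#' @param roi A `rect_roi`.
#' @export
roi_rows <- function(roi) (roi$row_start + 1L):roi$row_stop

#' @rdname rect_roi
#' @export
roi_cols <- function(roi) (roi$col_start + 1L):roi$col_stop

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("ROI rows [%d, %d) x cols [%d, %d) (0-based, half-open)\n",
              x$row_start, x$row_stop, x$col_start, x$col_stop))
  invisible(x)
}

#' Baseline per-frame lung segmentation
#'
#' Classical stand-in for a learned lung segmenter: lungs are the large dark
#' regions of a thoracic frame. The threshold is relative to the frame's
#' robust intensity range (1st/99th percentiles), making the rule invariant
#' to global intensity scaling -- MRI intensities are non-quantitative.
#' Pixels below `dark_frac` of the robust range are candidates; connected
#' components smaller than `min_area` are discarded and at most
#' `max_components` largest components are kept. Bright in-lung vessels stay
#' above the threshold, so they are preserved as excluded holes.
#'
#' @param frame 2D numeric matrix of finite intensities.
#' @param dark_frac Relative threshold in (0, 1): a pixel is dark when below
#'   `q01 + dark_frac * (q99 - q01)`.
#' @param min_area Minimum component area in pixels.
#' @param max_components Number of largest components retained (two lungs).
#' @return Logical matrix of the same shape (`TRUE` = lung). A constant
#'   frame yields an empty mask.
#' @export
segment_lungs_baseline <- function(frame, dark_frac = 0.4, min_area = 200L,
                                   max_components = 2L) {
  if (!is.matrix(frame) || !all(is.finite(frame))) {
    stop_pv("`frame` must be a finite-valued matrix")
  }
  q <- quantile(frame, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) return(matrix(FALSE, nrow(frame), ncol(frame)))
  thr <- q[1] + dark_frac * (q[2] - q[1])
  cand <- frame < thr
  keep_components(cand, min_area = min_area, max_components = max_components)
}

# retain the largest connected components of a logical mask
keep_components <- function(mask, min_area = 0L, max_components = Inf) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) > max_components) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)[seq_len(max_components)]]
  }
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Rectangular ROI from the outer boundaries of a lung mask
#'
#' The tight bounding box of all true pixels, expanded by `margin` pixels on
#' each side and clipped to the image bounds. Constraining the subsequent
#' vessel segmentation to this box avoids false detections outside the
#' thorax.
#'
#' @param lung_mask Logical matrix; must contain at least one `TRUE` pixel.
#' @param margin Expansion in pixels (>= 0).
#' @return A [rect_roi()].
#' @export
lung_bounding_roi <- function(lung_mask, margin = 0L) {
  if (!is.matrix(lung_mask) || !is.logical(lung_mask)) {
    stop_pv("`lung_mask` must be a logical matrix")
  }
  if (!any(lung_mask)) stop_pv("no lung found in frame: empty lung mask")
  if (!is_count(margin) || margin < 0) stop_pv("`margin` must be a non-negative integer")
  idx <- which(lung_mask, arr.ind = TRUE)
  r0 <- max(min(idx[, 1]) - 1L - margin, 0L)
  r1 <- min(max(idx[, 1]) + margin, nrow(lung_mask))
  c0 <- max(min(idx[, 2]) - 1L - margin, 0L)
  c1 <- min(max(idx[, 2]) + margin, ncol(lung_mask))
  rect_roi(r0, r1, c0, c1)
}

#' Baseline per-frame vessel segmentation within an ROI
#'
#' Classical stand-in for a learned vessel segmenter: vessels are the bright
#' structures inside the lung ROI. Pixels at or above the `percentile`-th
#' percentile of the in-ROI intensities are candidates (ties at the
#' threshold are included, so the rule is deterministic); components smaller
#' than `min_size` pixels are removed. The mask is `FALSE` everywhere
#' outside the ROI.
#'
#' @param frame 2D numeric matrix.
#' @param roi A [rect_roi()] inside the frame.
#' @param percentile In-ROI intensity percentile for the threshold
#'   (default 97).
#' @param min_size Minimum component size in pixels (default 3).
#' @return Logical matrix of the same shape as `frame`.
#' @export
segment_vessels_baseline <- function(frame, roi, percentile = 97, min_size = 3L) {
  if (!is.matrix(frame)) stop_pv("`frame` must be a matrix")
  if (!inherits(roi, "rect_roi")) stop_pv("`roi` must be a rect_roi")
  if (roi$row_stop > nrow(frame) || roi$col_stop > ncol(frame)) {
    stop_pv("ROI exceeds the frame bounds")
  }
  if (!is_num1(percentile) || percentile <= 0 || percentile >= 100) {
    stop_pv("`percentile` must lie in (0, 100)")
  }
  sub <- frame[roi_rows(roi), roi_cols(roi), drop = FALSE]
  thr <- quantile(sub, percentile / 100, names = FALSE)
  cand <- sub >= thr
  if (all(cand)) cand[] <- FALSE  # constant ROI: no bright structure
  cand <- keep_components(cand, min_area = min_size)
  out <- matrix(FALSE, nrow(frame), ncol(frame))
  out[roi_rows(roi), roi_cols(roi)] <- cand
  out
}

#' Overlap metrics between a predicted and a reference mask
#'
#' Dice = `2|A&B| / (|A| + |B|)` (1 when both masks are empty), sensitivity
#' = TP/(TP+FN), specificity = TN/(TN+FP). Vacuously empty denominators
#' yield 1.
#'
#' @param pred,truth Logical matrices of identical shape.
#' @return A list of class `overlap_metrics` with `dice`, `sensitivity`,
#'   `specificity`.
#' @export
overlap_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_pv("`pred` and `truth` must have identical shapes")
  }
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  sens <- if (tp + fn == 0) 1 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 1 else tn / (tn + fp)
  structure(list(dice = dice, sensitivity = sens, specificity = spec),
            class = "overlap_metrics")
}

#' @export
print.overlap_metrics <- function(x, ...) {
  cat(sprintf("Dice %.4f, sensitivity %.4f, specificity %.4f\n",
              x$dice, x$sensitivity, x$specificity))
  invisible(x)
}

#' Two-stage segmentation of a whole image series
#'
#' Applies the lung -> ROI -> vessel scheme independently to every frame.
#' Either stage can be replaced by a plug-in segmenter (e.g. a learned
#' model): a function taking the 2D frame and returning a logical mask of
#' identical shape (the vessel segmenter additionally receives the frame's
#' [rect_roi()]).
#'
#' @param images An [image_series()] or a rows x cols x frames array.
#' @param lung_segmenter `function(frame) -> logical mask`; defaults to
#'   [segment_lungs_baseline()].
#' @param vessel_segmenter `function(frame, roi) -> logical mask`; defaults
#'   to [segment_vessels_baseline()].
#' @param margin ROI margin in pixels.
#' @return A list of class `segmentation_result` with logical arrays `lungs`
#'   and `vessels` (rows x cols x frames) and the per-frame `rois`.
#' @export
segment_series <- function(images, lung_segmenter = NULL,
                           vessel_segmenter = NULL, margin = 0L) {
  arr <- if (inherits(images, "image_series")) images$data else images
  if (!is.array(arr) || length(dim(arr)) != 3) {
    stop_pv("`images` must be an image_series or a 3D array")
  }
  if (is.null(lung_segmenter)) lung_segmenter <- segment_lungs_baseline
  if (is.null(vessel_segmenter)) vessel_segmenter <- segment_vessels_baseline
  nt <- dim(arr)[3]
  lungs <- array(FALSE, dim(arr)); vessels <- array(FALSE, dim(arr))
  rois <- vector("list", nt)
  for (ti in seq_len(nt)) {
    frame <- arr[, , ti]
    lmask <- lung_segmenter(frame)
    if (!identical(dim(lmask), dim(frame))) {
      stop_pv("lung segmenter returned a mask of different shape (frame ", ti, ")")
    }
    roi <- lung_bounding_roi(lmask, margin = margin)
    vmask <- vessel_segmenter(frame, roi)
    if (!identical(dim(vmask), dim(frame))) {
      stop_pv("vessel segmenter returned a mask of different shape (frame ", ti, ")")
    }
    lungs[, , ti] <- lmask; vessels[, , ti] <- vmask; rois[[ti]] <- roi
  }
  structure(list(lungs = lungs, vessels = vessels, rois = rois),
            class = "segmentation_result")
}

#' Per-frame overlap of a segmentation against reference masks
#'
#' @param masks Logical rows x cols x frames array of predictions.
#' @param truth Logical array of the same shape with the reference.
#' @return A data frame with one row per frame: `frame`, `dice`,
#'   `sensitivity`, `specificity`.
#' @export
overlap_by_frame <- function(masks, truth) {
  if (!identical(dim(masks), dim(truth))) stop_pv("shape mismatch")
  nt <- dim(masks)[3]
  out <- lapply(seq_len(nt), function(ti) {
    m <- overlap_metrics(masks[, , ti], truth[, , ti])
    data.frame(frame = ti, dice = m$dice, sensitivity = m$sensitivity,
               specificity = m$specificity)
  })
  do.call(rbind, out)
}
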