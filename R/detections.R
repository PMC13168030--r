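#' Intersection-over-union of axis-aligned bounding boxes
#'
#' @param a,b Numeric vectors `(x_min, y_min, x_max, y_max)` or matrices
#'   with those four columns (row-wise IoU).
#' @return Numeric vector of IoU values in \[0, 1\].
#' @export
bbox_iou <- function(a, b) {
  a <- .as_bbox(a); b <- .as_bbox(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else stop("a and b must have matching numbers of boxes", call. = FALSE)
  }
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- area_a + area_b - inter
  ifelse(un > 0, inter / un, 0)
}

.as_bbox <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 4L) stop("a bbox needs 4 coordinates", call. = FALSE)
    p <- matrix(p, nrow = 1L)
  }
  if (ncol(p) != 4L) stop("bboxes need 4 columns", call. = FALSE)
  if (any(p[, 1] >= p[, 3]) || any(p[, 2] >= p[, 4]))
    stop("malformed bbox: require x_min < x_max and y_min < y_max",
         call. = FALSE)
  storage.mode(p) <- "double"
  p
}

#' Confidence thresholding and non-maximum suppression of detections
#'
#' Drops detections below the confidence threshold, then removes redundant
#' bounding boxes by greedy non-maximum suppression *within each frame*:
#' detections are visited in descending confidence (ties broken by original
#' row order) and any remaining detection whose box overlaps an already
#' kept one with IoU above `iou_max` is suppressed.
#'
#' @param det Data frame of detections with columns `frame_index`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `kp_x`, `kp_y`, `confidence`.
#' @param conf_min Minimum confidence kept, in \[0, 1\].
#' @param iou_max Maximum allowed IoU between kept boxes, in \[0, 1\].
#' @return The surviving detections, ordered by frame then descending
#'   confidence.
#' @export
filter_detections <- function(det, conf_min = 0.5, iou_max = 0.5) {
  .check_det(det)
  if (conf_min < 0 || conf_min > 1 || iou_max < 0 || iou_max > 1)
    stop("conf_min and iou_max must lie in [0, 1]", call. = FALSE)
  det <- det[det$confidence >= conf_min, , drop = FALSE]
  if (nrow(det) == 0L) return(det)
  keep_parts <- lapply(split(seq_len(nrow(det)), det$frame_index), function(idx) {
    sub <- det[idx, , drop = FALSE]
    ord <- order(-sub$confidence, seq_len(nrow(sub)))
    boxes <- as.matrix(sub[ord, c("x_min", "y_min", "x_max", "y_max")])
    kept <- integer(0)
    for (i in seq_along(ord)) {
      if (length(kept) &&
          any(bbox_iou(boxes[i, , drop = FALSE],
                       boxes[kept, , drop = FALSE]) > iou_max)) next
      kept <- c(kept, i)
    }
    idx[ord[kept]]
  })
  out <- det[unlist(keep_parts, use.names = FALSE), , drop = FALSE]
  out <- out[order(out$frame_index, -out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.det_cols <- c("frame_index", "x_min", "y_min", "x_max", "y_max",
               "kp_x", "kp_y", "confidence")

.check_det <- function(det) {
  if (!is.data.frame(det))
    stop("detections must be a data frame", call. = FALSE)
  miss <- setdiff(.det_cols, names(det))
  if (length(miss))
    stop("detections table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(det) && (any(det$x_min >= det$x_max) || any(det$y_min >= det$y_max)))
    stop("malformed bbox: require x_min < x_max and y_min < y_max",
         call. = FALSE)
  invisible(det)
}
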