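#' Pinhole camera intrinsics
#'
#' Bundles the calibrated intrinsic parameters of the nadir camera: focal
#' lengths and principal point in pixels, plus the sensor size. Pixel
#' coordinates throughout the package are 0-based with the origin at the
#' top-left corner; `x` is the image column (cross-track direction) and `y`
#' the image row (platform travel direction).
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image size in pixels.
#' @return An object of class `"camera_intrinsics"`.
#' @examples
#' K <- camera_intrinsics(fx = 1000, fy = 1000, cx = 550, cy = 310,
#'                        width = 1100, height = 620)
#' back_project(650, 310, 1.15, K)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(is.numeric(fx), is.numeric(fy), is.numeric(cx), is.numeric(cy))
  if (!is.finite(fx) || fx <= 0 || !is.finite(fy) || fy <= 0)
    stop("focal lengths fx and fy must be positive and finite", call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop("image width and height must be positive integers", call. = FALSE)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point (cx, cy) must lie inside the image", call. = FALSE)
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %d x %d px, fx=%g fy=%g, c=(%g, %g)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Align an RGB frame index with its depth frame
#'
#' The RGB and depth streams may run at different frame rates; the depth
#' frame matched to RGB frame `t` is `floor(t * depth_rate / rgb_rate)`.
#' When the rates are equal this is the identity.
#'
#' @param rgb_index Integer vector of RGB frame indices (0-based, >= 0).
#' @param rgb_rate,depth_rate Frame rates in frames per second; positive.
#' @return Integer vector of depth frame indices.
#' @examples
#' align_depth_index(7, rgb_rate = 30, depth_rate = 15)  # 3
#' @export
align_depth_index <- function(rgb_index, rgb_rate, depth_rate) {
  if (!is.numeric(rgb_rate) || !is.numeric(depth_rate) ||
      rgb_rate <= 0 || depth_rate <= 0)
    stop("frame rates must be positive", call. = FALSE)
  if (any(rgb_index < 0)) stop("rgb_index must be >= 0", call. = FALSE)
  as.integer(floor(rgb_index * depth_rate / rgb_rate))
}

#' Depth frame container
#'
#' Holds one depth map in meters together with its validity mask. Raw depth
#' files carry integer millimeters with 0 marking pixels where stereo
#' matching failed; on construction those pixels (and NaNs) become invalid
#' and are stored as `NA`.
#'
#' @param values Numeric matrix of depth values in meters (rows = image
#'   rows, columns = image columns). Zero or non-finite entries are treated
#'   as invalid.
#' @param frame_index Integer index of the frame in the depth stream.
#' @return An object of class `"depth_frame"` with elements `values`
#'   (meters, `NA` where invalid), `valid` (logical matrix) and
#'   `frame_index`.
#' @export
depth_frame <- function(values, frame_index = 0L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  valid <- is.finite(values) & values > 0
  vals <- values
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid,
                 frame_index = as.integer(frame_index)),
            class = "depth_frame")
}

#' Robust depth at a pixel by neighbourhood median
#'
#' Extracts the depth at a pixel as the median of the *valid* depth values
#' in a square window centred on it. Invalid pixels (stereo dropouts,
#' stored as `NA`) never influence the result; the window is clipped at the
#' image borders rather than padded. If no valid pixel remains the reading
#' is missing (`NA`), to be absorbed by cross-frame aggregation.
#'
#' @param depth A [depth_frame()].
#' @param x,y Pixel coordinates (0-based; fractional coordinates are
#'   rounded to the nearest pixel). Vectors of equal length are accepted.
#' @param window Odd window side length in pixels (default 3).
#' @return Numeric vector of depths in meters, `NA` where no valid pixel
#'   was available.
#' @export
extract_depth <- function(depth, x, y, window = 3L) {
  stopifnot(inherits(depth, "depth_frame"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  nr <- nrow(depth$values); nc <- ncol(depth$values)
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(xi < 0L) || any(xi >= nc) || any(yi < 0L) || any(yi >= nr))
    stop("depth lookup center outside the image", call. = FALSE)
  h <- window %/% 2L
  out <- numeric(length(xi))
  for (k in seq_along(xi)) {
    rows <- max(0L, yi[k] - h):min(nr - 1L, yi[k] + h)
    cols <- max(0L, xi[k] - h):min(nc - 1L, xi[k] + h)
    vals <- depth$values[rows + 1L, cols + 1L]
    vals <- vals[!is.na(vals)]
    out[k] <- if (length(vals)) stats::median(vals) else NA_real_
  }
  out
}

#' Back-project a pixel with depth into camera coordinates
#'
#' Inverts the pinhole projection: a pixel `(x, y)` observed at depth `z`
#' maps to metric camera coordinates `X = (x - cx) z / fx`,
#' `Y = (y - cy) z / fy`, `Z = z`. `X` is cross-track, `Y` along-track
#' (platform travel), `Z` the camera-to-scene distance.
#'
#' @param x,y Pixel coordinates (0-based), numeric vectors.
#' @param z Depth in meters; must be positive and finite.
#' @param K A [camera_intrinsics()].
#' @return A data frame with columns `X`, `Y`, `Z` in meters.
#' @export
back_project <- function(x, y, z, K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length", call. = FALSE)
  if (any(!is.finite(z)) || any(z <= 0))
    stop("depth z must be positive and finite", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pixel coordinates must be finite", call. = FALSE)
  data.frame(X = (x - K$cx) * z / K$fx,
             Y = (y - K$cy) * z / K$fy,
             Z = z)
}

#' Project camera-frame points onto the image
#'
#' Forward pinhole model, the algebraic inverse of [back_project()]:
#' `x = X fx / Z + cx`, `y = Y fy / Z + cy`. Used by the synthetic
#' observation renderer.
#'
#' @param X,Y,Z Camera-frame coordinates in meters; `Z > 0`.
#' @param K A [camera_intrinsics()].
#' @return A data frame with pixel columns `x`, `y` and the depth `z = Z`.
#' @export
project_points <- function(X, Y, Z, K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  n <- length(X)
  if (length(Y) != n || length(Z) != n)
    stop("X, Y, Z must have equal length", call. = FALSE)
  if (any(!is.finite(Z)) || any(Z <= 0))
    stop("Z must be positive and finite", call. = FALSE)
  data.frame(x = X * K$fx / Z + K$cx,
             y = Y * K$fy / Z + K$cy,
             z = Z)
}

#' 3D Euclidean plant spacing
#'
#' The spacing between two plants is the three-dimensional Euclidean
#' distance between their reference keypoints,
#' `sqrt((Xa-Xb)^2 + (Ya-Yb)^2 + (Za-Zb)^2)`.
#'
#' @param a,b Numeric vectors of length 3 `(X, Y, Z)` in meters, or
#'   matrices / data frames with three columns for row-wise distances.
#' @return Numeric vector of distances in meters.
#' @examples
#' spacing_3d(c(0, 0, 1.15), c(0.15, 0, 1.15))  # 0.15
#' @export
spacing_3d <- function(a, b) {
  a <- .as_xyz(a); b <- .as_xyz(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else stop("a and b must have matching numbers of points", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("coordinates must be finite", call. = FALSE)
  sqrt(rowSums((a - b)^2))
}

.as_xyz <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point must have 3 coordinates", call. = FALSE)
    p <- matrix(p, nrow = 1L)
  }
  if (ncol(p) != 3L) stop("points must have 3 columns (X, Y, Z)", call. = FALSE)
  storage.mode(p) <- "double"
  p
}
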