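#' Measurement pipeline settings
#'
#' Collects the tunable thresholds of the measurement chain. The matching
#' gate defaults to half the target spacing when left `NULL`.
#'
#' @param target_spacing Target within-row spacing, meters (> 0).
#' @param conf_min Detection confidence threshold.
#' @param iou_max Non-maximum-suppression IoU threshold.
#' @param window Odd depth median window side, pixels.
#' @param depth_anchor Where depth is sampled: at the `"keypoint"` pixel
#'   (default; the back-projected point *is* the keypoint, so sampling
#'   there avoids parallax) or at the `"bbox_center"`.
#' @param gate Tracker matching radius, meters; `NULL` = `target_spacing/2`.
#' @param max_age Frames a track survives unmatched.
#' @param row_gap Cross-track gap separating rows, meters.
#' @param mode `"track"` (cross-frame tracking, default) or `"per_frame"`
#'   (spacings among detections of each frame alone, for single images).
#' @param aggregate Track position statistic, `"median"` or `"mean"`.
#' @inheritParams qualified_stats
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(target_spacing, conf_min = 0.5, iou_max = 0.5,
                            window = 3L,
                            depth_anchor = c("keypoint", "bbox_center"),
                            gate = NULL, max_age = 5L, row_gap = 0.3,
                            mode = c("track", "per_frame"),
                            aggregate = c("median", "mean"),
                            sigma_formula = c("corrected", "as_printed"),
                            cv_normalize_by_mean = FALSE) {
  if (missing(target_spacing) || !is.numeric(target_spacing) ||
      target_spacing <= 0)
    stop("target_spacing must be a positive number", call. = FALSE)
  depth_anchor <- match.arg(depth_anchor)
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  sigma_formula <- match.arg(sigma_formula)
  if (is.null(gate)) gate <- target_spacing / 2
  if (gate <= 0 || row_gap <= 0)
    stop("gate and row_gap must be > 0", call. = FALSE)
  structure(list(target_spacing = target_spacing, conf_min = conf_min,
                 iou_max = iou_max, window = as.integer(window),
                 depth_anchor = depth_anchor, gate = gate,
                 max_age = as.integer(max_age), row_gap = row_gap,
                 mode = mode, aggregate = aggregate,
                 sigma_formula = sigma_formula,
                 cv_normalize_by_mean = cv_normalize_by_mean),
            class = "pipeline_config")
}

#' Localize filtered detections in camera 3D coordinates
#'
#' For each detection, samples a robust depth ([extract_depth()]) at the
#' configured anchor pixel from the temporally aligned depth frame and
#' back-projects the *keypoint* pixel to camera coordinates. Detections
#' whose depth reading is missing keep `NA` coordinates (the tracker
#' skips them; cross-frame aggregation absorbs the loss).
#'
#' @param det Filtered detection data frame.
#' @param depth_dir Directory of `depth_<index>.pgm` frames.
#' @param K A [camera_intrinsics()].
#' @param rgb_rate,depth_rate Stream rates for frame alignment.
#' @param window,depth_anchor See [pipeline_config()].
#' @return `det` with added columns `X`, `Y`, `Z` (camera meters).
#' @export
localize_detections <- function(det, depth_dir, K, rgb_rate, depth_rate,
                                window = 3L,
                                depth_anchor = c("keypoint", "bbox_center")) {
  depth_anchor <- match.arg(depth_anchor)
  det$X <- det$Y <- det$Z <- NA_real_
  if (nrow(det) == 0L) return(det)
  det <- det[order(det$frame_index), , drop = FALSE]
  ax <- if (depth_anchor == "keypoint") det$kp_x else (det$x_min + det$x_max) / 2
  ay <- if (depth_anchor == "keypoint") det$kp_y else (det$y_min + det$y_max) / 2
  didx <- align_depth_index(det$frame_index, rgb_rate, depth_rate)
  cache_idx <- -1L
  cache <- NULL
  z <- rep(NA_real_, nrow(det))
  for (k in seq_len(nrow(det))) {
    if (didx[k] != cache_idx) {
      path <- file.path(depth_dir, sprintf("depth_%06d.pgm", didx[k]))
      if (!file.exists(path))
        stop("missing depth frame: ", path, call. = FALSE)
      cache <- read_depth_pgm(path, frame_index = didx[k])
      cache_idx <- didx[k]
    }
    z[k] <- extract_depth(cache, ax[k], ay[k], window = window)
  }
  ok <- !is.na(z)
  if (any(ok)) {
    p <- back_project(det$kp_x[ok], det$kp_y[ok], z[ok], K)
    det$X[ok] <- p$X; det$Y[ok] <- p$Y; det$Z[ok] <- p$Z
  }
  det
}

#' Run the full spacing-measurement pipeline on a run directory
#'
#' Executes the measurement chain on an acquired (or simulated) run:
#' detection filtering, depth extraction and back-projection, cross-frame
#' tracking with ego-motion compensation, world aggregation, row
#' assignment, within-row spacing computation and sowing-quality
#' evaluation (pooled and per row).
#'
#' @param run_dir Directory holding `detections.csv`, `depth/`,
#'   `motion.csv`, `intrinsics.cfg` (see [simulate_run()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `tracks.csv`, `spacings.csv` and `report.json`.
#' @param verbose Emit one summary line per stage?
#' @return An object of class `"stand_measurement"`: list with
#'   `positions` (tracked, row-assigned plant positions), `spacings`,
#'   `report` (pooled `"sowing_quality"`), `reports_per_row`, `tracks`,
#'   `config` and `acquisition`.
#' @export
run_pipeline <- function(run_dir, config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  acq <- read_intrinsics(file.path(run_dir, "intrinsics.cfg"))
  motion <- read_motion(file.path(run_dir, "motion.csv"))
  det <- read_detections(file.path(run_dir, "detections.csv"))
  say("detections: read %d over %d frames", nrow(det),
      length(unique(det$frame_index)))
  filt <- filter_detections(det, config$conf_min, config$iou_max)
  say("filter: kept %d of %d (conf >= %g, NMS IoU > %g)", nrow(filt),
      nrow(det), config$conf_min, config$iou_max)
  loc <- localize_detections(filt, file.path(run_dir, "depth"),
                             acq$intrinsics, acq$rgb_rate, acq$depth_rate,
                             window = config$window,
                             depth_anchor = config$depth_anchor)
  say("depth: %d of %d detections with valid depth", sum(!is.na(loc$Z)),
      nrow(loc))

  if (config$mode == "per_frame") {
    obs <- loc[!is.na(loc$Z), , drop = FALSE]
    obs$track_id <- seq_len(nrow(obs))
    parts <- lapply(split(obs, obs$frame_index), function(g) {
      g <- assign_rows(g, config$row_gap)
      row_spacings(g)
    })
    spac <- do.call(rbind, parts)
    if (!is.null(spac)) rownames(spac) <- NULL
    positions <- obs
    tracks <- NULL
  } else {
    tracks <- track_plants(loc[, c("frame_index", "X", "Y", "Z")], motion,
                           gate = config$gate, max_age = config$max_age,
                           aggregate = config$aggregate)
    say("tracking: %d tracks formed", nrow(tracks$positions))
    positions <- assign_rows(tracks$positions, config$row_gap)
    say("rows: %d", length(unique(positions$row_id)))
    spac <- row_spacings(positions)
  }
  if (is.null(spac) || nrow(spac) == 0L)
    stop("pipeline produced no spacing interval", call. = FALSE)
  say("spacings: %d intervals in %d row(s)", nrow(spac),
      length(unique(spac$row_id)))
  report <- evaluate_sowing(spac$spacing_m, config$target_spacing,
                            sigma_formula = config$sigma_formula,
                            cv_normalize_by_mean = config$cv_normalize_by_mean)
  per_row <- lapply(split(spac, spac$row_id), function(g)
    tryCatch(evaluate_sowing(g$spacing_m, config$target_spacing,
                             sigma_formula = config$sigma_formula,
                             cv_normalize_by_mean =
                               config$cv_normalize_by_mean),
             error = function(e) NULL))
  per_row <- per_row[!vapply(per_row, is.null, logical(1))]
  say("report: QFI %.2f%% MUL %.2f%% MI %.2f%% over N' = %d intervals",
      report$qfi, report$mul, report$mi, report$counts$Np)

  res <- structure(list(positions = positions, spacings = spac,
                        report = report, reports_per_row = per_row,
                        tracks = tracks, config = config,
                        acquisition = acq),
                   class = "stand_measurement")
  if (!is.null(out_dir)) write_measurement(res, out_dir)
  res
}

#' Write the pipeline artifacts of a measurement
#'
#' Writes `tracks.csv` (`track_id,row_id,order_in_row,X_m,Y_m,Z_m,
#' n_valid_obs`), `spacings.csv` (`row_id,order,spacing_m`) and
#' `report.json` into `out_dir`.
#'
#' @param x A `"stand_measurement"` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @export
write_measurement <- function(x, out_dir) {
  stopifnot(inherits(x, "stand_measurement"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pos <- x$positions
  tr <- data.frame(track_id = pos$track_id, row_id = pos$row_id,
                   order_in_row = pos$order_in_row,
                   X_m = pos$X, Y_m = pos$Y, Z_m = pos$Z,
                   n_valid_obs = if ("n_valid_obs" %in% names(pos))
                     pos$n_valid_obs else 1L)
  utils::write.csv(.num_fmt(tr), file.path(out_dir, "tracks.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(.num_fmt(x$spacings), file.path(out_dir, "spacings.csv"),
                   row.names = FALSE, quote = FALSE)
  write_report(x$report, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.stand_measurement <- function(x, ...) {
  cat(sprintf("stand_measurement: %d plants, %d row(s), %d spacing intervals\n",
              nrow(x$positions), length(unique(x$positions$row_id)),
              nrow(x$spacings)))
  print(x$report)
  invisible(x)
}

#' Evaluate sowing quality from a spacing CSV
#'
#' Reads a `row_id,order,spacing_m` series (e.g. `spacings.csv` from
#' [run_pipeline()], or manually measured spacings) and evaluates the
#' quality indices pooled and per row.
#'
#' @param path Spacing CSV path.
#' @param target_spacing Target spacing, meters.
#' @param ... Passed to [evaluate_sowing()].
#' @return List with `pooled` (a `"sowing_quality"`) and `per_row`.
#' @export
evaluate_spacings_file <- function(path, target_spacing, ...) {
  spac <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row_id", "spacing_m") %in% names(spac)))
    stop(path, " needs columns row_id and spacing_m", call. = FALSE)
  pooled <- evaluate_sowing(spac$spacing_m, target_spacing, ...)
  per_row <- lapply(split(spac, spac$row_id), function(g)
    tryCatch(evaluate_sowing(g$spacing_m, target_spacing, ...),
             error = function(e) NULL))
  list(pooled = pooled, per_row = per_row[!vapply(per_row, is.null,
                                                  logical(1))])
}
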