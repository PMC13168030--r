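# Synthetic field + acquisition simulator. Emulates a planter pass: nominal
# drop points at the target spacing with miss and multiple events, observed
# by a moving nadir stereo camera that emits keypoint detections and 16-bit
# depth maps. All generative distributions are this package's own; outputs
# are labelled synthetic.

#' Stand (planted row) simulation settings
#'
#' Defines the generative model of the plant stand: `n_positions` nominal
#' drop points per row at the target spacing; each point is empty with
#' probability `p_miss` (a skip, lengthening the neighbouring gap),
#' otherwise holds one plant displaced along-track by
#' `Normal(0, spacing_sd^2)`, plus with probability `p_multiple` an extra
#' plant offset by `Normal(0, multiple_offset_sd^2)` (a double drop,
#' creating a short gap). Plant keypoint heights are
#' `Normal(plant_height_mean, plant_height_sd^2)`, floored at 1 cm.
#'
#' @param target_spacing Target within-row spacing, meters.
#' @param n_positions Nominal drop points per row (>= 2).
#' @param p_miss,p_multiple Event probabilities in \[0, 1\].
#' @param spacing_sd Along-track placement jitter SD, meters.
#' @param multiple_offset_sd Offset SD of the extra plant in a double
#'   drop, meters.
#' @param n_rows Number of parallel rows.
#' @param row_spacing Cross-track distance between rows, meters.
#' @param cross_track_sd Cross-track placement jitter SD, meters.
#' @param plant_height_mean,plant_height_sd Keypoint height above ground,
#'   meters.
#' @param seed Integer seed driving the stand's private RNG stream.
#' @return An object of class `"stand_config"`.
#' @export
stand_config <- function(target_spacing = 0.20, n_positions = 101L,
                         p_miss = 0.1, p_multiple = 0.05,
                         spacing_sd = 0.01, multiple_offset_sd = 0.03,
                         n_rows = 1L, row_spacing = 0.6,
                         cross_track_sd = 0.01,
                         plant_height_mean = 0.30, plant_height_sd = 0.02,
                         seed = 1L) {
  if (target_spacing <= 0) stop("target_spacing must be > 0", call. = FALSE)
  if (n_positions < 2L) stop("n_positions must be >= 2", call. = FALSE)
  for (p in c(p_miss, p_multiple))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (spacing_sd < 0 || multiple_offset_sd < 0 || cross_track_sd < 0 ||
      plant_height_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(target_spacing = target_spacing,
                 n_positions = as.integer(n_positions),
                 p_miss = p_miss, p_multiple = p_multiple,
                 spacing_sd = spacing_sd,
                 multiple_offset_sd = multiple_offset_sd,
                 n_rows = as.integer(n_rows), row_spacing = row_spacing,
                 cross_track_sd = cross_track_sd,
                 plant_height_mean = plant_height_mean,
                 plant_height_sd = plant_height_sd,
                 seed = as.integer(seed)),
            class = "stand_config")
}

#' Camera acquisition simulation settings
#'
#' Defines the moving nadir camera: intrinsics, mount height, travel speed
#' and stream rates, plus the observation noise — Gaussian keypoint pixel
#' jitter, Gaussian depth noise, independent per-pixel depth dropout, and
#' the detector confidence range. Optional sinusoidal micro-topography
#' modulates the ground depth along-track.
#'
#' @param intrinsics A [camera_intrinsics()]; the default is a desk-scale
#'   160x120 camera (fx = fy = 150 px) whose footprint at 1.15 m matches a
#'   nadir row camera.
#' @param camera_height Mount height above ground, meters.
#' @param speed Platform speed, m/s (default 0.556, i.e. 2 km/h).
#' @param rgb_rate,depth_rate Stream frame rates, frames/s.
#' @param pixel_jitter_sd Keypoint localization jitter SD, pixels.
#' @param depth_noise_sd Depth measurement noise SD, meters (default
#'   0.012, ~1% of the mount height).
#' @param p_invalid_pixel Probability that a depth pixel is invalid.
#' @param detection_conf_range Range of the uniform detector confidence.
#' @param plant_radius Half-size of the rendered plant core (bbox and
#'   depth footprint), meters.
#' @param terrain_amplitude,terrain_wavelength Sinusoidal ground
#'   micro-topography (meters); amplitude 0 disables it.
#' @param seed Integer seed driving the rendering RNG stream (independent
#'   of the stand stream, so acquisition noise never changes the stand).
#' @return An object of class `"acquisition_config"`.
#' @export
acquisition_config <- function(intrinsics = camera_intrinsics(150, 150, 80,
                                                              60, 160, 120),
                               camera_height = 1.15, speed = 0.556,
                               rgb_rate = 30, depth_rate = 30,
                               pixel_jitter_sd = 1.0,
                               depth_noise_sd = 0.012,
                               p_invalid_pixel = 0.02,
                               detection_conf_range = c(0.6, 0.99),
                               plant_radius = 0.03,
                               terrain_amplitude = 0,
                               terrain_wavelength = 5,
                               seed = 1L) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (camera_height <= 0) stop("camera_height must be > 0", call. = FALSE)
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (rgb_rate <= 0 || depth_rate <= 0)
    stop("frame rates must be > 0", call. = FALSE)
  if (p_invalid_pixel < 0 || p_invalid_pixel > 1)
    stop("p_invalid_pixel must lie in [0, 1]", call. = FALSE)
  if (length(detection_conf_range) != 2L ||
      detection_conf_range[1] > detection_conf_range[2])
    stop("detection_conf_range must be an increasing pair", call. = FALSE)
  structure(list(intrinsics = intrinsics, camera_height = camera_height,
                 speed = speed, rgb_rate = rgb_rate, depth_rate = depth_rate,
                 pixel_jitter_sd = pixel_jitter_sd,
                 depth_noise_sd = depth_noise_sd,
                 p_invalid_pixel = p_invalid_pixel,
                 detection_conf_range = detection_conf_range,
                 plant_radius = plant_radius,
                 terrain_amplitude = terrain_amplitude,
                 terrain_wavelength = terrain_wavelength,
                 seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Simulate a planted stand with ground truth
#'
#' Draws the plant stand defined by a [stand_config()] and computes its
#' ground truth: true plant positions, the ordered true spacing series per
#' row (3D distances between keypoints, including height differences) and
#' the oracle sowing-quality report obtained by running
#' [evaluate_sowing()] on the true spacings. Reproducible from the config
#' seed; the stand RNG stream is independent of the rendering stream.
#'
#' @param cfg A [stand_config()].
#' @return An object of class `"plant_stand"`: list with `plants` (data
#'   frame `plant_id`, `row`, `X`, `Y`, `height`), `spacings` (data frame
#'   `row_id`, `order`, `spacing_m`), `oracle` (pooled
#'   `"sowing_quality"`), `oracle_per_row` (list) and `config`.
#' @export
simulate_stand <- function(cfg) {
  stopifnot(inherits(cfg, "stand_config"))
  plants <- .with_seed(cfg$seed, {
    parts <- vector("list", cfg$n_rows)
    for (r in seq_len(cfg$n_rows)) {
      n <- cfg$n_positions
      nominal <- (seq_len(n) - 1L) * cfg$target_spacing
      present <- stats::runif(n) >= cfg$p_miss
      y <- nominal[present] + stats::rnorm(sum(present), 0, cfg$spacing_sd)
      x <- (r - 1L) * cfg$row_spacing +
        stats::rnorm(sum(present), 0, cfg$cross_track_sd)
      h <- pmax(0.01, stats::rnorm(sum(present), cfg$plant_height_mean,
                                   cfg$plant_height_sd))
      extra <- stats::runif(sum(present)) < cfg$p_multiple
      ne <- sum(extra)
      if (ne) {
        ye <- y[extra] + stats::rnorm(ne, 0, cfg$multiple_offset_sd)
        xe <- (r - 1L) * cfg$row_spacing +
          stats::rnorm(ne, 0, cfg$cross_track_sd)
        he <- pmax(0.01, stats::rnorm(ne, cfg$plant_height_mean,
                                      cfg$plant_height_sd))
      } else ye <- xe <- he <- numeric(0)
      parts[[r]] <- data.frame(row = r, X = c(x, xe), Y = c(y, ye),
                               height = c(h, he))
    }
    out <- do.call(rbind, parts)
    out <- out[order(out$row, out$Y), , drop = FALSE]
    out <- cbind(plant_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
  spacings <- .true_spacings(plants)
  if (nrow(spacings) == 0L)
    stop("simulated stand has no spacing interval; increase n_positions ",
         "or lower p_miss", call. = FALSE)
  oracle <- evaluate_sowing(spacings$spacing_m, cfg$target_spacing)
  per_row <- lapply(split(spacings, spacings$row_id), function(g)
    evaluate_sowing(g$spacing_m, cfg$target_spacing))
  structure(list(plants = plants, spacings = spacings, oracle = oracle,
                 oracle_per_row = per_row, config = cfg),
            class = "plant_stand")
}

.true_spacings <- function(plants) {
  parts <- lapply(split(plants, plants$row), function(g) {
    g <- g[order(g$Y, g$plant_id), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    p <- as.matrix(data.frame(X = g$X, Y = g$Y, Z = g$height))
    data.frame(row_id = g$row[1L], order = seq_len(nrow(g) - 1L),
               spacing_m = spacing_3d(p[-nrow(p), , drop = FALSE],
                                      p[-1L, , drop = FALSE]))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(data.frame(row_id = integer(0), order = integer(0),
                      spacing_m = numeric(0)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @export
print.plant_stand <- function(x, ...) {
  cat(sprintf("plant_stand: %d plants in %d row(s), target %g m, seed %d\n",
              nrow(x$plants), x$config$n_rows, x$config$target_spacing,
              x$config$seed))
  cat(sprintf("  oracle: QFI %.2f%%  MUL %.2f%%  MI %.2f%%\n",
              x$oracle$qfi, x$oracle$mul, x$oracle$mi))
  invisible(x)
}

#' Render synthetic observations of a stand
#'
#' Simulates the moving-camera acquisition of a [simulate_stand()] result:
#' for each RGB frame, plants whose rendered bounding box lies fully
#' inside the image produce a detection (jittered keypoint, confidence
#' drawn from the configured range); for each depth frame, a 16-bit
#' millimeter PGM is written containing ground depth everywhere, plant
#' depth (`camera_height - height`) over each plant's core footprint,
#' Gaussian depth noise, and independently invalidated pixels. A per-frame
#' motion table and the intrinsics config are written alongside.
#'
#' @param stand A `"plant_stand"` from [simulate_stand()].
#' @param acq An [acquisition_config()].
#' @param dir Output run directory (created if needed). Layout:
#'   `detections.csv`, `depth/depth_<index>.pgm`, `motion.csv`,
#'   `intrinsics.cfg`.
#' @return Invisibly, a manifest list with the file paths, `n_frames` and
#'   `n_detections`.
#' @export
render_observations <- function(stand, acq, dir) {
  stopifnot(inherits(stand, "plant_stand"),
            inherits(acq, "acquisition_config"))
  K <- acq$intrinsics
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)

  plants <- stand$plants
  pz <- acq$camera_height - plants$height   # camera-to-keypoint depth
  if (any(pz <= 0))
    stop("camera_height must exceed every plant height", call. = FALSE)
  # widest along-track half-extent of the view at plant depth, plus slack
  half_view <- max(K$cy, K$height - K$cy) / K$fy * acq$camera_height + 0.1
  step <- acq$speed / acq$rgb_rate
  n_frames <- as.integer(ceiling((max(plants$Y) + half_view) / step)) + 1L
  r_px_x <- acq$plant_radius * K$fx / pz
  r_px_y <- acq$plant_radius * K$fy / pz

  det <- .with_seed(acq$seed, {
    rows <- vector("list", n_frames)
    for (t in seq_len(n_frames) - 1L) {
      disp <- acq$speed * t / acq$rgb_rate
      yc <- plants$Y - disp
      vis <- which(abs(yc) < half_view)
      if (!length(vis)) next
      pr <- project_points(plants$X[vis], yc[vis], pz[vis], K)
      ok <- pr$x - r_px_x[vis] >= 0 & pr$x + r_px_x[vis] <= K$width - 1 &
        pr$y - r_px_y[vis] >= 0 & pr$y + r_px_y[vis] <= K$height - 1
      if (!any(ok)) next
      v <- vis[ok]; pr <- pr[ok, , drop = FALSE]
      kx <- pr$x + stats::rnorm(length(v), 0, acq$pixel_jitter_sd)
      ky <- pr$y + stats::rnorm(length(v), 0, acq$pixel_jitter_sd)
      kx <- pmin(pmax(kx, pr$x - r_px_x[v]), pr$x + r_px_x[v])
      ky <- pmin(pmax(ky, pr$y - r_px_y[v]), pr$y + r_px_y[v])
      rows[[t + 1L]] <- data.frame(
        frame_index = t, timestamp_s = t / acq$rgb_rate,
        x_min = pr$x - r_px_x[v], y_min = pr$y - r_px_y[v],
        x_max = pr$x + r_px_x[v], y_max = pr$y + r_px_y[v],
        kp_x = kx, kp_y = ky,
        confidence = stats::runif(length(v), acq$detection_conf_range[1],
                                  acq$detection_conf_range[2]))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      stop("no plant ever fully visible; check camera footprint",
           call. = FALSE)
    out <- do.call(rbind, rows)

    # depth stream at its own rate and timestamps
    n_depth <- align_depth_index(n_frames - 1L, acq$rgb_rate,
                                 acq$depth_rate) + 1L
    ord <- order(pz, decreasing = TRUE)   # near plants drawn last
    row_y <- (seq_len(K$height) - 1L - K$cy) / K$fy * acq$camera_height
    for (j in seq_len(n_depth) - 1L) {
      disp <- acq$speed * j / acq$depth_rate
      ground <- acq$camera_height -
        (if (acq$terrain_amplitude > 0)
          acq$terrain_amplitude *
            sin(2 * pi * (disp + row_y) / acq$terrain_wavelength)
         else 0)
      img <- matrix(ground, nrow = K$height, ncol = K$width)
      yc <- plants$Y - disp
      for (i in ord[abs(yc[ord]) < half_view]) {
        pr <- project_points(plants$X[i], yc[i], pz[i], K)
        r_lo <- max(0, round(pr$y - r_px_y[i]))
        r_hi <- min(K$height - 1, round(pr$y + r_px_y[i]))
        c_lo <- max(0, round(pr$x - r_px_x[i]))
        c_hi <- min(K$width - 1, round(pr$x + r_px_x[i]))
        if (r_lo > r_hi || c_lo > c_hi) next
        img[(r_lo:r_hi) + 1L, (c_lo:c_hi) + 1L] <- pz[i]
      }
      if (acq$depth_noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, acq$depth_noise_sd)
      if (acq$p_invalid_pixel > 0)
        img[stats::runif(length(img)) < acq$p_invalid_pixel] <- 0
      write_depth_pgm(img, file.path(dir, "depth",
                                     sprintf("depth_%06d.pgm", j)))
    }
    out
  })

  write_detections(det, file.path(dir, "detections.csv"))
  motion <- platform_motion(speed = acq$speed, rgb_rate = acq$rgb_rate)
  write_motion(motion, file.path(dir, "motion.csv"),
               frames = seq_len(n_frames) - 1L)
  write_intrinsics(K, acq$rgb_rate, acq$depth_rate, acq$camera_height,
                   file.path(dir, "intrinsics.cfg"))
  invisible(list(dir = dir,
                 detections = file.path(dir, "detections.csv"),
                 depth_dir = file.path(dir, "depth"),
                 motion = file.path(dir, "motion.csv"),
                 intrinsics = file.path(dir, "intrinsics.cfg"),
                 n_frames = n_frames, n_detections = nrow(det)))
}

#' Generate a complete synthetic run with ground truth on disk
#'
#' Convenience wrapper: simulates the stand, renders the observations into
#' `dir` and stores the ground truth (`truth.json`: plant positions, true
#' spacings, oracle report, both configs, all labelled synthetic).
#'
#' @param stand_cfg A [stand_config()].
#' @param acq_cfg An [acquisition_config()].
#' @param dir Output run directory.
#' @return Invisibly, list with `stand` (the `"plant_stand"`), `manifest`
#'   (see [render_observations()]) and `dir`.
#' @export
simulate_run <- function(stand_cfg, acq_cfg, dir) {
  stand <- simulate_stand(stand_cfg)
  manifest <- render_observations(stand, acq_cfg, dir)
  truth <- list(
    generator = "synthetic",
    note = paste("All generative distributions are this package's own;",
                 "positions, spacings and the oracle report are simulation",
                 "ground truth, not field data."),
    stand_config = unclass(stand_cfg),
    acquisition = list(camera_height = acq_cfg$camera_height,
                       speed = acq_cfg$speed, rgb_rate = acq_cfg$rgb_rate,
                       depth_rate = acq_cfg$depth_rate,
                       seed = acq_cfg$seed),
    plants = stand$plants,
    true_spacings = stand$spacings,
    oracle = list(qfi_pct = stand$oracle$qfi, mul_pct = stand$oracle$mul,
                  mi_pct = stand$oracle$mi, s_bar = stand$oracle$s_bar,
                  sigma = stand$oracle$sigma, cv_pct = stand$oracle$cv,
                  bins = as.list(stand$oracle$bins),
                  counts = list(n0 = stand$oracle$counts$n0,
                                n1 = stand$oracle$counts$n1,
                                n2 = stand$oracle$counts$n2,
                                N = stand$oracle$counts$Np)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(stand = stand, manifest = manifest, dir = dir))
}
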