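#' Platform motion model
#'
#' Describes the along-track displacement of the moving platform, either as
#' a constant travel speed sampled at the RGB frame rate or as an explicit
#' per-frame displacement table.
#'
#' @param speed Constant platform speed in m/s (constant-speed mode).
#' @param rgb_rate RGB frame rate in frames/s (needed in constant-speed
#'   mode to convert frame index to time).
#' @param table Data frame with columns `frame_index` and `displacement_m`
#'   (per-frame mode); displacement must be non-decreasing in frame index.
#' @return An object of class `"platform_motion"`.
#' @seealso [displacement_at()]
#' @export
platform_motion <- function(speed = NULL, rgb_rate = NULL, table = NULL) {
  if (!is.null(table)) {
    if (!is.data.frame(table) ||
        !all(c("frame_index", "displacement_m") %in% names(table)))
      stop("motion table needs columns frame_index and displacement_m",
           call. = FALSE)
    table <- table[order(table$frame_index), , drop = FALSE]
    if (is.unsorted(table$displacement_m))
      stop("displacement must be non-decreasing over frame index",
           call. = FALSE)
    return(structure(list(mode = "per_frame_table", table = table),
                     class = "platform_motion"))
  }
  if (is.null(speed) || is.null(rgb_rate) || speed < 0 || rgb_rate <= 0)
    stop("constant-speed motion needs speed >= 0 and rgb_rate > 0",
         call. = FALSE)
  structure(list(mode = "constant_speed", speed = as.numeric(speed),
                 rgb_rate = as.numeric(rgb_rate)),
            class = "platform_motion")
}

#' Along-track platform displacement at given frames
#'
#' @param motion A [platform_motion()].
#' @param frame_index Integer vector of RGB frame indices.
#' @return Numeric vector of displacements in meters.
#' @export
displacement_at <- function(motion, frame_index) {
  stopifnot(inherits(motion, "platform_motion"))
  if (motion$mode == "constant_speed")
    return(motion$speed * frame_index / motion$rgb_rate)
  idx <- match(frame_index, motion$table$frame_index)
  if (anyNA(idx))
    stop("motion table has no entry for frame(s) ",
         paste(utils::head(frame_index[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  motion$table$displacement_m[idx]
}

#' Transform camera-frame observations into the world frame
#'
#' Compensates platform ego-motion: the along-track coordinate of each
#' camera-frame observation is increased by the platform displacement at
#' its frame, so that a static plant maps to the same world point from
#' every frame in which it is seen.
#'
#' @param obs Data frame with columns `frame_index`, `X`, `Y`, `Z`
#'   (camera-frame meters).
#' @param motion A [platform_motion()].
#' @return `obs` with `Y` replaced by the world along-track coordinate.
#' @export
to_world <- function(obs, motion) {
  stopifnot(is.data.frame(obs),
            all(c("frame_index", "X", "Y", "Z") %in% names(obs)))
  obs$Y <- obs$Y + displacement_at(motion, obs$frame_index)
  obs
}

#' Aggregate world-frame track observations into one position per track
#'
#' Fuses the repeated world-frame observations of each track into a single
#' plant position by a coordinate-wise robust statistic (median by
#' default; a mean is available). Tracks without any valid observation are
#' dropped with a warning.
#'
#' @param obs Data frame with columns `track_id`, `X`, `Y`, `Z` in world
#'   meters; rows with a missing coordinate are ignored.
#' @param stat `"median"` (default, robust to occasional identity
#'   switches) or `"mean"`.
#' @return Data frame `track_id`, `X`, `Y`, `Z`, `n_valid_obs`, one row per
#'   reported track, ordered by `track_id`.
#' @export
aggregate_tracks <- function(obs, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(obs),
            all(c("track_id", "X", "Y", "Z") %in% names(obs)))
  ok <- stats::complete.cases(obs[, c("X", "Y", "Z")])
  if (!all(ok)) obs <- obs[ok, , drop = FALSE]
  if (nrow(obs) == 0L)
    return(data.frame(track_id = integer(0), X = numeric(0), Y = numeric(0),
                      Z = numeric(0), n_valid_obs = integer(0)))
  fun <- if (stat == "median") stats::median else mean
  parts <- lapply(split(obs, obs$track_id), function(g)
    data.frame(track_id = g$track_id[1L],
               X = fun(g$X), Y = fun(g$Y), Z = fun(g$Z),
               n_valid_obs = nrow(g)))
  out <- do.call(rbind, parts)
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motion-gated cross-frame plant tracking
#'
#' Associates per-frame 3D plant observations across frames so that each
#' physical plant keeps one identity for the whole pass. Prediction uses
#' ego-motion compensation only: after [to_world()], a static plant is
#' stationary, so a live track's predicted position is the running
#' coordinate-wise aggregate of its world-frame observations. Per frame,
#' detections are matched one-to-one to live tracks greedily by ascending
#' Euclidean distance (ties by ascending track id, then detection order),
#' accepting matches within `gate`. Unmatched detections open new tracks;
#' tracks unmatched for more than `max_age` frames are closed.
#' Observations with a missing depth reading carry `NA` coordinates and
#' are skipped (track ages still advance).
#'
#' @param obs Data frame of camera-frame observations with columns
#'   `frame_index`, `X`, `Y`, `Z`; `NA` coordinates mark missing-depth
#'   detections.
#' @param motion A [platform_motion()].
#' @param gate Matching radius in meters (> 0); a sensible default is half
#'   the target plant spacing.
#' @param max_age Frames a track may remain unmatched before being closed.
#' @param aggregate Statistic fusing observations into a track position,
#'   `"median"` or `"mean"`.
#' @return An object of class `"plant_tracks"`: a list with
#'   `observations` (world-frame per-observation table with `track_id`) and
#'   `positions` (per-track aggregated positions, see
#'   [aggregate_tracks()]).
#' @export
track_plants <- function(obs, motion, gate, max_age = 5L,
                         aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(obs))
  if (!all(c("frame_index", "X", "Y", "Z") %in% names(obs)))
    stop("obs needs columns frame_index, X, Y, Z", call. = FALSE)
  if (!is.numeric(gate) || gate <= 0) stop("gate must be > 0", call. = FALSE)
  max_age <- as.integer(max_age)

  w <- to_world(obs, motion)
  w <- w[stats::complete.cases(w[, c("X", "Y", "Z")]), , drop = FALSE]
  empty <- data.frame(track_id = integer(0), frame_index = integer(0),
                      X = numeric(0), Y = numeric(0), Z = numeric(0))
  if (nrow(w) == 0L)
    return(structure(list(observations = empty,
                          positions = aggregate_tracks(empty, aggregate),
                          gate = gate, max_age = max_age,
                          aggregate = aggregate),
                     class = "plant_tracks"))
  w <- w[order(w$frame_index), , drop = FALSE]

  agg1 <- if (aggregate == "median") stats::median else mean
  tracks <- list()   # per track: list(id, last, xs, ys, zs, frames)
  next_id <- 1L
  live <- integer(0) # indices into `tracks`

  frames <- split(seq_len(nrow(w)), w$frame_index)
  frame_ids <- as.integer(names(frames))
  for (fi in seq_along(frames)) {
    f <- frame_ids[fi]
    live <- live[vapply(tracks[live], function(t) f - t$last <= max_age,
                        logical(1))]
    rows <- frames[[fi]]
    det <- w[rows, , drop = FALSE]
    matched_det <- rep(FALSE, nrow(det))
    if (length(live)) {
      pred <- t(vapply(tracks[live], function(t)
        c(agg1(t$xs), agg1(t$ys), agg1(t$zs)), numeric(3)))
      d2 <- outer(seq_len(nrow(det)), seq_along(live),
                  Vectorize(function(i, j)
                    sqrt((det$X[i] - pred[j, 1])^2 +
                         (det$Y[i] - pred[j, 2])^2 +
                         (det$Z[i] - pred[j, 3])^2)))
      cand <- which(d2 <= gate, arr.ind = TRUE)
      if (nrow(cand)) {
        ids <- vapply(tracks[live], function(t) t$id, integer(1))
        ord <- order(d2[cand], ids[cand[, 2]], cand[, 1])
        used_track <- rep(FALSE, length(live))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (matched_det[i] || used_track[j]) next
          matched_det[i] <- TRUE; used_track[j] <- TRUE
          ti <- live[j]
          tracks[[ti]]$xs <- c(tracks[[ti]]$xs, det$X[i])
          tracks[[ti]]$ys <- c(tracks[[ti]]$ys, det$Y[i])
          tracks[[ti]]$zs <- c(tracks[[ti]]$zs, det$Z[i])
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
          tracks[[ti]]$last <- f
        }
      }
    }
    for (i in which(!matched_det)) {
      tracks[[length(tracks) + 1L]] <- list(id = next_id, last = f,
                                            xs = det$X[i], ys = det$Y[i],
                                            zs = det$Z[i], frames = f)
      live <- c(live, length(tracks))
      next_id <- next_id + 1L
    }
  }

  obs_out <- do.call(rbind, lapply(tracks, function(t)
    data.frame(track_id = t$id, frame_index = t$frames,
               X = t$xs, Y = t$ys, Z = t$zs)))
  obs_out <- obs_out[order(obs_out$track_id, obs_out$frame_index), ,
                     drop = FALSE]
  rownames(obs_out) <- NULL
  structure(list(observations = obs_out,
                 positions = aggregate_tracks(obs_out, aggregate),
                 gate = gate, max_age = max_age, aggregate = aggregate),
            class = "plant_tracks")
}

#' @export
print.plant_tracks <- function(x, ...) {
  cat(sprintf("plant_tracks: %d tracks from %d observations (gate %.3g m, max_age %d, %s)\n",
              nrow(x$positions), nrow(x$observations), x$gate, x$max_age,
              x$aggregate))
  invisible(x)
}
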