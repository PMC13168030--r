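const_motion <- function(speed = 0.6, rate = 30) {
  platform_motion(speed = speed, rgb_rate = rate)
}

# Camera-frame observations of static world plants seen from a platform
# moving at `speed`: the camera Y coordinate shrinks as the platform
# advances.
obs_of <- function(world, frames, speed, rate = 30) {
  do.call(rbind, lapply(frames, function(f)
    data.frame(frame_index = f, X = world[, 1],
               Y = world[, 2] - speed * f / rate, Z = world[, 3])))
}

test_that("a single plant seen in consecutive frames yields one track", {
  world <- matrix(c(0, 1.0, 0.85), 1)
  tr <- track_plants(obs_of(world, 0:2, 0.6), const_motion(0.6),
                     gate = 0.1)
  expect_equal(nrow(tr$positions), 1)
  expect_equal(nrow(tr$observations), 3)
  expect_equal(tr$positions$n_valid_obs, 3)
  expect_equal(unlist(tr$positions[, c("X", "Y", "Z")]),
               c(X = 0, Y = 1.0, Z = 0.85), tolerance = 1e-12)
})

test_that("well-separated plants keep distinct identities", {
  world <- rbind(c(0, 1.0, 0.85), c(0, 1.5, 0.85))
  tr <- track_plants(obs_of(world, 0:4, 0.6), const_motion(0.6),
                     gate = 0.1)
  expect_equal(nrow(tr$positions), 2)
  expect_true(all(tr$positions$n_valid_obs == 5))
  expect_equal(sort(tr$positions$Y), c(1.0, 1.5), tolerance = 1e-12)
})

test_that("a detection beyond the gate opens a new track", {
  obs <- rbind(data.frame(frame_index = 0, X = 0, Y = 1.0, Z = 0.85),
               data.frame(frame_index = 1, X = 0, Y = 1.0 + 0.2, Z = 0.85))
  tr <- track_plants(obs, platform_motion(speed = 0, rgb_rate = 30),
                     gate = 0.1)
  expect_equal(nrow(tr$positions), 2)
})

test_that("ego-motion compensation is an exact additive shift", {
  obs <- data.frame(frame_index = 0, X = 0, Y = 0.2, Z = 1.15)
  m <- platform_motion(table = data.frame(frame_index = 0,
                                          displacement_m = 3.0))
  w <- to_world(obs, m)
  expect_identical(w$Y, 3.2)
})

test_that("track aggregation is the coordinate-wise median", {
  obs <- data.frame(track_id = 1, X = c(0, 0, 0),
                    Y = c(3.18, 3.20, 3.29), Z = 0.85)
  expect_equal(aggregate_tracks(obs)$Y, 3.20)
  expect_equal(aggregate_tracks(obs, stat = "mean")$Y, mean(c(3.18, 3.2, 3.29)))
})

test_that("a static plant's world position is invariant to platform speed", {
  K <- test_K()
  world <- rbind(c(0.02, 0.50, 0.85), c(-0.03, 0.70, 0.82))
  ref <- NULL
  for (speed in c(0.2, 0.556, 1.1)) {
    frames <- 0:60
    obs <- do.call(rbind, lapply(frames, function(f) {
      yc <- world[, 2] - speed * f / 30
      vis <- abs(yc * K$fy / world[, 3]) < 55   # inside the frame
      if (!any(vis)) return(NULL)
      px <- project_points(world[vis, 1], yc[vis], world[vis, 3], K)
      p <- back_project(px$x, px$y, px$z, K)
      data.frame(frame_index = f, X = p$X, Y = p$Y, Z = p$Z)
    }))
    tr <- track_plants(obs, const_motion(speed), gate = 0.1)
    pos <- as.matrix(tr$positions[order(tr$positions$Y), c("X", "Y", "Z")])
    expect_equal(nrow(pos), 2)
    if (is.null(ref)) ref <- pos
    else expect_lt(max(abs(pos - ref)), 1e-9)
    expect_lt(max(abs(pos - world[order(world[, 2]), ])), 1e-9)
  }
})

test_that("missing-depth observations are skipped but tracks persist", {
  obs <- data.frame(frame_index = 0:4, X = 0, Y = 1.0, Z = 0.85)
  obs$X[2:4] <- NA; obs$Y[2:4] <- NA; obs$Z[2:4] <- NA
  tr <- track_plants(obs, platform_motion(speed = 0, rgb_rate = 30),
                     gate = 0.1, max_age = 5)
  expect_equal(nrow(tr$positions), 1)
  expect_equal(tr$positions$n_valid_obs, 2)
})

test_that("tracks unmatched beyond max_age are closed", {
  obs <- data.frame(frame_index = c(0, 10), X = 0, Y = 1.0, Z = 0.85)
  tr <- track_plants(obs, platform_motion(speed = 0, rgb_rate = 30),
                     gate = 0.1, max_age = 3)
  expect_equal(nrow(tr$positions), 2)  # gap of 10 frames splits the track
  tr2 <- track_plants(obs, platform_motion(speed = 0, rgb_rate = 30),
                      gate = 0.1, max_age = 15)
  expect_equal(nrow(tr2$positions), 1)
})

test_that("association is invariant to input row order", {
  set.seed(5)
  world <- cbind(0, seq(0, 2, by = 0.2), 0.85)
  obs <- obs_of(world, 0:30, 0.5)
  obs <- obs[abs(obs$Y) < 0.4, ]
  tr1 <- track_plants(obs, const_motion(0.5), gate = 0.1)
  shuf <- obs[sample(nrow(obs)), ]
  tr2 <- track_plants(shuf, const_motion(0.5), gate = 0.1)
  # track numbering may differ; the reconstructed stand may not
  by_y <- function(tr) {
    p <- tr$positions[order(tr$positions$Y), c("X", "Y", "Z", "n_valid_obs")]
    rownames(p) <- NULL
    p
  }
  expect_equal(by_y(tr1), by_y(tr2))
  expect_equal(row_spacings(assign_rows(tr1$positions, 0.3))$spacing_m,
               row_spacings(assign_rows(tr2$positions, 0.3))$spacing_m)
})
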