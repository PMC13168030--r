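test_that("the deterministic limit places every plant at its nominal point", {
  stand <- simulate_stand(noiseless_stand(25))
  expect_equal(nrow(stand$plants), 25)
  expect_equal(stand$spacings$spacing_m, rep(0.2, 24))
  expect_equal(stand$oracle$qfi, 100)
})

test_that("stand generation is reproducible and independent of rendering", {
  cfg <- stand_config(n_positions = 40, seed = 99)
  s1 <- simulate_stand(cfg)
  s2 <- simulate_stand(cfg)
  expect_identical(s1$plants, s2$plants)
  s3 <- simulate_stand(stand_config(n_positions = 40, seed = 100))
  expect_false(identical(s1$plants, s3$plants))
  # drawing rendering noise between the two stand draws must not matter
  s4 <- local({
    a <- simulate_stand(cfg)
    invisible(rnorm(1000))
    b <- simulate_stand(cfg)
    list(a = a, b = b)
  })
  expect_identical(s4$a$plants, s4$b$plants)
})

test_that("the stored oracle report closes over the true spacings", {
  for (seed in c(2, 7, 21)) {
    stand <- simulate_stand(stand_config(n_positions = 60, seed = seed))
    redo <- evaluate_sowing(stand$spacings$spacing_m,
                            stand$config$target_spacing)
    expect_identical(unclass(stand$oracle), unclass(redo))
  }
})

test_that("oracle miss index matches a direct Monte-Carlo simulation", {
  stand <- simulate_stand(stand_config(n_positions = 3000, p_miss = 0.1,
                                       p_multiple = 0, spacing_sd = 0,
                                       cross_track_sd = 0,
                                       plant_height_sd = 0, seed = 5))
  set.seed(6)
  trials <- replicate(400, {
    sp <- direct_stand_spacings(1000, 0.2, 0.1, 0, 0, 0, 0, 0.3, 0)
    brute_mi(sp, 0.2)
  })
  se <- sd(trials) * sqrt(1000 / 3000) / 1  # scale SE to the larger stand
  expect_lt(abs(stand$oracle$mi - mean(trials)), 3 * se)
})

test_that("identical seeds give byte-identical rendered runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sc <- stand_config(n_positions = 6, seed = 3)
  ac <- acquisition_config(seed = 4)
  simulate_run(sc, ac, d1)
  simulate_run(sc, ac, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("noiseless rendering back-projects to the true plant positions", {
  d <- withr::local_tempdir()
  run <- simulate_run(noiseless_stand(8), noiseless_acq(), d)
  acq <- read_intrinsics(file.path(d, "intrinsics.cfg"))
  det <- read_detections(file.path(d, "detections.csv"))
  loc <- localize_detections(det, file.path(d, "depth"), acq$intrinsics,
                             acq$rgb_rate, acq$depth_rate)
  expect_true(all(!is.na(loc$Z)))
  w <- to_world(loc, read_motion(file.path(d, "motion.csv")))
  plants <- run$stand$plants
  err <- vapply(seq_len(nrow(w)), function(i)
    min(spacing_3d(cbind(plants$X, plants$Y, 1.15 - plants$height),
                   c(w$X[i], w$Y[i], w$Z[i]))), numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("total depth dropout yields missing readings for every detection", {
  d <- withr::local_tempdir()
  simulate_run(noiseless_stand(4),
               acquisition_config(pixel_jitter_sd = 0, depth_noise_sd = 0,
                                  p_invalid_pixel = 1, seed = 2), d)
  acq <- read_intrinsics(file.path(d, "intrinsics.cfg"))
  det <- read_detections(file.path(d, "detections.csv"))
  loc <- localize_detections(det, file.path(d, "depth"), acq$intrinsics,
                             acq$rgb_rate, acq$depth_rate)
  expect_true(all(is.na(loc$Z)))
})

test_that("a plant projects where the motion model predicts", {
  # plant at along-track 3.2 m, platform at 2.78 m: camera-frame Y = 0.42 m
  K <- test_K()
  z <- 1.15 - 0.30
  px <- project_points(0, 3.2 - 2.78, z, K)
  expect_equal(px$y, K$cy + 0.42 * K$fy / z)
})

test_that("spacing error grows with depth noise", {
  errs <- vapply(c(0, 0.01, 0.04), function(sd) {
    d <- withr::local_tempdir()
    simulate_run(noiseless_stand(12, seed = 8),
                 acquisition_config(pixel_jitter_sd = 0, depth_noise_sd = sd,
                                    p_invalid_pixel = 0, seed = 9), d)
    m <- run_pipeline(d, pipeline_config(target_spacing = 0.2),
                      verbose = FALSE)
    median(abs(m$spacings$spacing_m - 0.2))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
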