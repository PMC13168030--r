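# Shared fixtures and independent oracles used across test files.

# Default test camera: small nadir sensor, generous footprint.
test_K <- function() camera_intrinsics(150, 150, 80, 60, 160, 120)

# One-detection row builder.
det_row <- function(frame, x_min, y_min, x_max, y_max, kp_x, kp_y, conf,
                    t = frame / 30) {
  data.frame(frame_index = frame, timestamp_s = t, x_min = x_min,
             y_min = y_min, x_max = x_max, y_max = y_max,
             kp_x = kp_x, kp_y = kp_y, confidence = conf)
}

# Brute-force per-element interval classifier (independent of bin_ratios).
brute_bins <- function(ratios) {
  out <- integer(5)
  for (r in ratios) {
    b <- if (r <= 0.5) 1L
    else if (r <= 1.5) 2L
    else if (r <= 2.5) 3L
    else if (r <= 3.5) 4L
    else 5L
    out[b] <- out[b] + 1L
  }
  names(out) <- c("n1p", "n2p", "n3p", "n4p", "n5p")
  out
}

# Brute-force miss index from a spacing vector, written from the interval
# definitions directly (independent of the quality module).
brute_mi <- function(spacings, target) {
  s <- round(spacings / target, 6)
  b <- brute_bins(s)
  n0 <- b[3] + 2 * b[4] + 3 * b[5]
  Np <- b[2] + 2 * b[3] + 3 * b[4] + 4 * b[5]
  unname(100 * n0 / Np)
}

# Direct generative simulation of one stand draw (mirrors the documented
# generative model but shares no code with simulate_stand); returns the
# spacing vector of a single row.
direct_stand_spacings <- function(n, target, p_miss, p_multiple, spacing_sd,
                                  multiple_offset_sd, cross_track_sd,
                                  h_mean, h_sd) {
  nominal <- (seq_len(n) - 1) * target
  keep <- runif(n) >= p_miss
  y <- nominal[keep] + rnorm(sum(keep), 0, spacing_sd)
  x <- rnorm(sum(keep), 0, cross_track_sd)
  h <- pmax(0.01, rnorm(sum(keep), h_mean, h_sd))
  extra <- runif(sum(keep)) < p_multiple
  if (any(extra)) {
    y <- c(y, y[extra] + rnorm(sum(extra), 0, multiple_offset_sd))
    x <- c(x, rnorm(sum(extra), 0, cross_track_sd))
    h <- c(h, pmax(0.01, rnorm(sum(extra), h_mean, h_sd)))
  }
  o <- order(y)
  y <- y[o]; x <- x[o]; h <- h[o]
  if (length(y) < 2) return(numeric(0))
  sqrt(diff(x)^2 + diff(y)^2 + diff(h)^2)
}

# Noiseless configs for end-to-end recovery checks.
noiseless_stand <- function(n, target = 0.2, seed = 1) {
  stand_config(target_spacing = target, n_positions = n, p_miss = 0,
               p_multiple = 0, spacing_sd = 0, cross_track_sd = 0,
               plant_height_sd = 0, seed = seed)
}
noiseless_acq <- function(seed = 1) {
  acquisition_config(pixel_jitter_sd = 0, depth_noise_sd = 0,
                     p_invalid_pixel = 0, seed = seed)
}
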