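center <- c(1000, 1000)

make_step <- function(x0, y0, dx, dy, frame_t = 20, dt = 30) {
  data.frame(track_id = 1L, frame_t = frame_t, x0_um = x0, y0_um = y0,
             x1_um = x0 + dx, y1_um = y0 + dy, dt_s = dt)
}

test_that("step metrics compute angle, directed displacement, and speed", {
  # step pointing exactly at the center: angle 0, bias contribution 90
  rec <- step_metrics(make_step(500, 1000, 12.5, 0), center)
  expect_equal(rec$theta_deg, 0)
  expect_equal(90 - rec$theta_deg, 90)
  expect_equal(rec$directed_um, 12.5)

  # perpendicular step: angle 90, directed 0
  rec <- step_metrics(make_step(500, 1000, 0, 12.5), center)
  expect_equal(rec$theta_deg, 90)
  expect_equal(rec$directed_um, 0, tolerance = 1e-12)

  # v = (10, 0), u = (1, 0), dt = 30 s: speed and directed speed 20 um/min
  rec <- step_metrics(make_step(500, 1000, 10, 0), center)
  expect_equal(rec$speed_um_min, 20)
  expect_equal(rec$directed_speed_um_min, 20)
  # independent dot-product cross-check of the directed component
  v <- c(10, 0)
  u <- (center - c(500, 1000)) / sqrt(sum((center - c(500, 1000))^2))
  expect_equal(rec$directed_um, sum(v * u))

  # straight away from the center: angle 180, directed negative
  rec <- step_metrics(make_step(500, 1000, -12.5, 0), center)
  expect_equal(rec$theta_deg, 180)
  expect_equal(rec$directed_um, -12.5)
})

test_that("short steps and center-origin steps are excluded from angles", {
  rec <- step_metrics(make_step(500, 1000, 8, 0), center)
  expect_true(is.na(rec$theta_deg))      # below the 10 um minimum move
  expect_false(is.na(rec$directed_um))   # directed displacement still defined

  rec <- step_metrics(make_step(1000, 1000, 12, 0), center)
  expect_true(rec$center_flag)
  expect_true(is.na(rec$theta_deg))
  expect_true(is.na(rec$directed_um))
})

test_that("directed displacement never exceeds distance", {
  set.seed(41)
  steps <- data.frame(
    track_id = 1L, frame_t = 20L,
    x0_um = runif(500, 0, 2000), y0_um = runif(500, 0, 2000),
    dt_s = 30
  )
  steps$x1_um <- steps$x0_um + rnorm(500, 0, 10)
  steps$y1_um <- steps$y0_um + rnorm(500, 0, 10)
  rec <- step_metrics(steps, center)
  ok <- !rec$center_flag
  expect_true(all(abs(rec$directed_um[ok]) <= rec$distance_um[ok] + 1e-9))
  s <- well_summary(rec, r_min = 0, r_max = Inf)
  expect_lte(s$directed_speed, s$stim_speed)
})

test_that("angular bias spans [-90, 90] and hits the bounds exactly", {
  # all steps exactly toward the center: bias 90
  inward <- radial_steps(100, c(300, 1500), 12.5, center)
  s_in <- well_summary(step_metrics(inward, center))
  expect_equal(s_in$angular_bias, 90)

  # all steps exactly away: bias -90
  outward <- radial_steps(100, c(300, 1500), 12.5, center, outward = TRUE)
  s_out <- well_summary(step_metrics(outward, center))
  expect_equal(s_out$angular_bias, -90)

  # uniform random directions: bias near 0 (10,000 steps, fixed seed)
  set.seed(42)
  n <- 10000
  r <- runif(n, 300, 1500)
  phi <- runif(n, 0, 2 * pi)
  ang <- runif(n, 0, 2 * pi)
  steps <- data.frame(
    track_id = seq_len(n), frame_t = 20L,
    x0_um = center[1] + r * cos(phi), y0_um = center[2] + r * sin(phi),
    dt_s = 30
  )
  steps$x1_um <- steps$x0_um + 12.5 * cos(ang)
  steps$y1_um <- steps$y0_um + 12.5 * sin(ang)
  s_rand <- well_summary(step_metrics(steps, center))
  expect_lt(abs(s_rand$angular_bias), 2)
})

test_that("angular bias is invariant under rotation about the center", {
  set.seed(43)
  n <- 400
  steps <- radial_steps(n, c(300, 1500), 15, center, seed = 44)
  # perturb directions so the bias is non-trivial
  ang <- atan2(steps$y1_um - steps$y0_um, steps$x1_um - steps$x0_um) +
    rnorm(n, 0, 0.8)
  steps$x1_um <- steps$x0_um + 15 * cos(ang)
  steps$y1_um <- steps$y0_um + 15 * sin(ang)
  b0 <- well_summary(step_metrics(steps, center))$angular_bias

  th <- 1.1  # arbitrary rotation
  rot <- function(x, y) {
    list(x = center[1] + cos(th) * (x - center[1]) - sin(th) * (y - center[2]),
         y = center[2] + sin(th) * (x - center[1]) + cos(th) * (y - center[2]))
  }
  p0 <- rot(steps$x0_um, steps$y0_um)
  p1 <- rot(steps$x1_um, steps$y1_um)
  rsteps <- steps
  rsteps$x0_um <- p0$x; rsteps$y0_um <- p0$y
  rsteps$x1_um <- p1$x; rsteps$y1_um <- p1$y
  b1 <- well_summary(step_metrics(rsteps, center))$angular_bias
  expect_equal(b1, b0, tolerance = 1e-9)
})

test_that("radial bounds and epochs gate the per-well statistics", {
  # steps at 200 and 1,700 um are outside the 250-1,625 annulus
  s200 <- make_step(center[1] - 200, center[2], 12.5, 0)
  s1700 <- make_step(center[1] - 1700, center[2], 12.5, 0)
  s500 <- make_step(center[1] - 500, center[2], 12.5, 0)
  rec <- step_metrics(rbind(s200, s1700, s500), center)
  s <- well_summary(rec)
  expect_equal(s$n_stim, 1L)
  expect_equal(s$n_angle, 1L)

  # epoch assignment: both-pre, spanning, both-post (uncaging frame 17)
  steps <- rbind(make_step(500, 800, 10, 0, frame_t = 15),
                 make_step(500, 800, 10, 0, frame_t = 16),
                 make_step(500, 800, 10, 0, frame_t = 17))
  rec <- step_metrics(steps, center, n_pre_frames = 17)
  expect_equal(rec$epoch, c("pre", "spanning", "post"))

  # zero qualifying steps give NA, not 0
  empty <- well_summary(rec[rec$epoch == "spanning", , drop = FALSE])
  expect_true(is.na(empty$basal_speed))
  expect_true(is.na(empty$stim_speed))
  expect_true(is.na(empty$angular_bias))
})

test_that("time course tracks the stimulus-induced speed change", {
  acq <- acquisition_params()
  center_um <- acq$gradient_center * acq$pixel_size
  p <- cell_sim_params(n_cells = 250, basal_speed = 8, stimulated_speed = 20,
                       nonmover_fraction = 0, position_noise_px = 0)
  tr <- simulate_trajectories(p, acq, seed = 45)
  rec <- step_metrics(truth_steps(tr$positions), center_um)
  tc <- time_course(rec)

  # histogram rows sum to 1 wherever a frame has qualifying angles
  sums <- rowSums(tc$angle_hist)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))

  # recovered per-epoch speed means match the generator within 3 SE
  pre <- tc$by_frame$frame_t + 1 < acq$n_pre_frames
  post <- tc$by_frame$frame_t >= acq$n_pre_frames
  pre_steps <- rec$speed_um_min[rec$epoch == "pre" &
                                  rec$origin_r_um >= 250 &
                                  rec$origin_r_um <= 1625]
  se_pre <- sd(pre_steps) / sqrt(length(pre_steps))
  expect_lt(abs(mean(tc$by_frame$mean_speed[pre], na.rm = TRUE) - 8),
            3 * se_pre + 0.05)
  post_steps <- rec$speed_um_min[rec$epoch == "post" &
                                   rec$origin_r_um >= 250 &
                                   rec$origin_r_um <= 1625]
  se_post <- sd(post_steps) / sqrt(length(post_steps))
  expect_lt(abs(mean(tc$by_frame$mean_speed[post], na.rm = TRUE) - 20),
            3 * se_post + 0.1)
  # and the jump happens at the uncaging frame
  expect_gt(min(tc$by_frame$mean_speed[post], na.rm = TRUE),
            max(tc$by_frame$mean_speed[pre], na.rm = TRUE))
})
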