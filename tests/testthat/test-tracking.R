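test_that("mutual nearest-neighbor matching accepts only unambiguous pairs", {
  # two distant cells each moving a little: both linked
  t0 <- data.frame(x_um = c(0, 500), y_um = c(0, 0))
  t1 <- data.frame(x_um = c(5, 505), y_um = c(0, 0))
  lk <- match_frames(t0, t1)
  expect_equal(lk$i, 1:2)
  expect_equal(lk$j, 1:2)

  # A's forward NN is B, but B's backward NN is C: A gets no link
  t0 <- data.frame(x_um = c(0, 3), y_um = c(0, 0))   # A, C
  t1 <- data.frame(x_um = 2, y_um = 0)               # B
  lk <- match_frames(t0, t1)
  expect_false(1 %in% lk$i)
  expect_equal(lk, data.frame(i = 2L, j = 1L, dist_um = 1))

  # exact distance tie: ambiguous, no link
  t0 <- data.frame(x_um = 0, y_um = 0)
  t1 <- data.frame(x_um = c(-4, 4), y_um = c(0, 0))
  expect_equal(nrow(match_frames(t0, t1)), 0L)
})

test_that("matching equals the brute-force mutual-NN oracle on random instances", {
  set.seed(31)
  for (trial in 1:1000) {
    n <- sample(1:20, 1)
    m <- sample(1:20, 1)
    p_t <- data.frame(x_um = runif(n, 0, 200), y_um = runif(n, 0, 200))
    p_t1 <- data.frame(x_um = runif(m, 0, 200), y_um = runif(m, 0, 200))
    got <- match_frames(p_t, p_t1)
    exp <- bf_mutual_nn(data.frame(x = p_t$x_um, y = p_t$y_um),
                        data.frame(x = p_t1$x_um, y = p_t1$y_um))
    expect_equal(got[c("i", "j")], exp,
                 ignore_attr = TRUE)
    # one-to-one partial matching
    expect_false(anyDuplicated(got$i) > 0)
    expect_false(anyDuplicated(got$j) > 0)
  }
})

test_that("matching is symmetric under frame-role reversal", {
  set.seed(32)
  for (trial in 1:50) {
    p_t <- data.frame(x_um = runif(12, 0, 100), y_um = runif(12, 0, 100))
    p_t1 <- data.frame(x_um = runif(15, 0, 100), y_um = runif(15, 0, 100))
    ab <- match_frames(p_t, p_t1)
    ba <- match_frames(p_t1, p_t)
    expect_equal(ab[order(ab$i), c("i", "j")],
                 setNames(ba[order(ba$j), c("j", "i")], c("i", "j")),
                 ignore_attr = TRUE)
  }
})

test_that("crowding filter requires crowding in both frames", {
  # isolated pair: kept
  t0 <- data.frame(x_um = c(0, 500), y_um = c(0, 0))
  t1 <- data.frame(x_um = c(5, 505), y_um = c(0, 0))
  lk <- match_frames(t0, t1)
  expect_equal(nrow(crowding_filter(lk, t0, t1)), 2L)

  # 30 um apart in both frames: both steps excluded
  t0 <- data.frame(x_um = c(0, 30), y_um = c(0, 0))
  t1 <- data.frame(x_um = c(2, 32), y_um = c(0, 0))
  lk <- match_frames(t0, t1)
  expect_equal(nrow(lk), 2L)
  expect_equal(nrow(crowding_filter(lk, t0, t1)), 0L)

  # crowded in frame t only: kept (the condition is a conjunction)
  t0 <- data.frame(x_um = c(0, 30), y_um = c(0, 0))
  t1 <- data.frame(x_um = c(0, 100), y_um = c(2, 0))
  lk <- match_frames(t0, t1)
  expect_equal(nrow(crowding_filter(lk, t0, t1)), nrow(lk))

  # full truth table of the conjunction on a single moving cell plus a
  # neighbor placed near/far in each frame
  for (near_t in c(TRUE, FALSE)) for (near_t1 in c(TRUE, FALSE)) {
    t0 <- data.frame(x_um = c(0, if (near_t) 20 else 300), y_um = c(0, 0))
    t1 <- data.frame(x_um = c(4, if (near_t1) 24 else 304), y_um = c(0, 0))
    lk <- match_frames(t0, t1)
    kept <- crowding_filter(lk[lk$i == 1, ], t0, t1)
    expect_equal(nrow(kept), as.integer(!(near_t && near_t1)))
  }
})

test_that("trajectories are maximal chains split at missing links", {
  # one isolated cell over 50 frames: a single trajectory
  det <- data.frame(frame = 0:49, x_px = (0:49) * 2, y_px = 0)
  traj <- link_movie(det, pixel_size = 2.5, d_thresh = Inf)
  expect_equal(length(unique(traj$track_id)), 1L)
  expect_equal(sum(traj$track_id == traj$track_id[1]), 50L)

  # removing the link at frame 24->25 splits it into two trajectories
  links <- lapply(setNames(0:48, 0:48), function(f) {
    if (f == 24) data.frame(i = integer(0), j = integer(0))
    else data.frame(i = 1L, j = 1L)
  })
  split2 <- build_trajectories(det, links)
  expect_equal(length(unique(split2$track_id)), 2L)
  expect_equal(as.vector(table(split2$track_id)), c(25L, 25L))

  # duplicate participation is a hard error
  bad <- list("0" = data.frame(i = c(1L, 1L), j = c(1L, 2L)))
  det2 <- data.frame(frame = c(0L, 1L, 1L), x_px = c(0, 1, 2), y_px = 0)
  expect_error(build_trajectories(det2, bad), "one-to-one")
})

test_that("nonmover filter uses strict more-than-two-pixels displacement", {
  # stationary cell with 0.5 px jitter: removed
  set.seed(33)
  jitter <- data.frame(track_id = 1L, frame = 0:29,
                       x_px = 10 + rnorm(30, 0, 0.3),
                       y_px = 10 + rnorm(30, 0, 0.3))
  expect_equal(nrow(filter_nonmoving(jitter)), 0L)

  # steady mover: kept
  mover <- data.frame(track_id = 1L, frame = 0:9, x_px = (0:9) * 4,
                      y_px = 0)
  expect_equal(nrow(filter_nonmoving(mover)), 10L)

  # wanders to exactly 2.0 px and back: removed (strict "more than")
  edge <- data.frame(track_id = 1L, frame = 0:2, x_px = c(0, 2, 0),
                     y_px = 0)
  expect_equal(nrow(filter_nonmoving(edge)), 0L)
})

test_that("links connect detections of the same ground-truth cell", {
  acq <- test_acq()
  p <- cell_sim_params(n_cells = 25, nonmover_fraction = 0,
                       position_noise_px = 0.3)
  tr <- simulate_trajectories(p, acq, seed = 34)
  obs <- observed_positions(tr, seed = 35)
  det <- data.frame(frame = obs$frame,
                    x_px = obs$x_um / acq$pixel_size,
                    y_px = obs$y_um / acq$pixel_size,
                    cell = obs$cell_id)
  correct <- 0L
  total <- 0L
  for (f in 0:(acq$n_frames - 2L)) {
    a <- det[det$frame == f, ]
    b <- det[det$frame == f + 1L, ]
    lk <- match_frames(a, b, acq$pixel_size)
    lk <- crowding_filter(lk, a, b, 40, acq$pixel_size)
    total <- total + nrow(lk)
    correct <- correct + sum(a$cell[lk$i] == b$cell[lk$j])
  }
  expect_gt(total, 400)
  expect_gte(correct / total, 0.99)
})
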