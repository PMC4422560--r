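#' Sample from a von Mises distribution
#'
#' Best–Fisher (1979) rejection sampler.  For `kappa` below 1e-8 the
#' distribution is taken as uniform on the circle; for `kappa` at or above
#' the degenerate cap (1e6, or `Inf`) all draws equal `mu` exactly.
#'
#' @param n number of draws.
#' @param mu mean direction, radians (scalar or length-n).
#' @param kappa concentration, >= 0.
#' @return angles in `(-pi, pi]`.
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(length(kappa) == 1, !is.na(kappa), kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa >= 1e6) return(wrap_angle(rep_len(mu, n)))
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi) + rep_len(mu, n)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0) {
      out[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      got <- got + k
    }
  }
  wrap_angle(out + rep_len(mu, n))
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# reflect positions into [lo, hi] (billiard boundary)
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate ground-truth cell trajectories
#'
#' Generates one position per cell per frame under a biased persistent
#' random walk.  During pre-stimulus frames, headings are
#' persistent-random (no directional bias) and step lengths are gamma with
#' mean `basal_speed * dt`; for steps landing on or after the uncaging
#' frame, step-length mean switches to `stimulated_speed * dt` and target
#' headings are von Mises around the direction from the current position
#' toward the gradient center, with concentration `bias_kappa`.  The
#' realized heading interpolates the previous heading with the drawn target
#' heading using weight `persistence` (except in the degenerate
#' `bias_kappa = Inf` limit, where post-stimulus steps point exactly at the
#' center).  A `nonmover_fraction` of cells never moves.  Cells reflect off
#' the image boundary, so all positions stay in bounds.
#'
#' @param params [cell_sim_params()].
#' @param acq [acquisition_params()].
#' @param seed integer RNG seed.
#' @param population population label attached to the trajectories
#'   (conventionally `"experimental"` or `"control"`).
#' @return an object of class `ground_truth`: a list with `positions`
#'   (data frame `cell_id, frame, x_um, y_um`; frame is 0-based),
#'   `nonmover` (logical per cell), `params`, `acq`, `population`, `seed`.
#' @examples
#' tr <- simulate_trajectories(cell_sim_params(n_cells = 5),
#'                             acquisition_params(), seed = 1)
#' head(tr$positions)
#' @export
simulate_trajectories <- function(params, acq, seed,
                                  population = "experimental") {
  stopifnot(inherits(params, "cell_sim_params"),
            inherits(acq, "acquisition_params"))
  set.seed(as.integer(seed))
  n <- params$n_cells
  nf <- acq$n_frames
  dt_min <- acq$frame_interval / 60  # minutes
  width <- (acq$image_shape[2] - 1) * acq$pixel_size
  height <- (acq$image_shape[1] - 1) * acq$pixel_size
  center <- gradient_center_um(acq)

  x <- matrix(NA_real_, n, nf)
  y <- matrix(NA_real_, n, nf)
  if (n > 0) {
    x[, 1] <- runif(n, 0, width)
    y[, 1] <- runif(n, 0, height)
  }
  nonmover <- runif(n) < params$nonmover_fraction
  if (params$basal_speed == 0 && params$stimulated_speed == 0) {
    nonmover[] <- TRUE
  }
  moving <- !nonmover
  heading <- runif(n, -pi, pi)
  p <- params$persistence
  exact_bias <- params$bias_kappa >= 1e6

  for (f in seq_len(nf - 1L)) {
    # step from frame f-1 to frame f in 0-based terms; stimulated once the
    # landing frame is at or past the uncaging frame
    stim <- f >= acq$n_pre_frames
    speed <- if (stim) params$stimulated_speed else params$basal_speed
    mean_len <- speed * dt_min
    if (mean_len > 0 && any(moving)) {
      idx <- which(moving)
      m <- length(idx)
      if (stim && params$bias_kappa > 0) {
        mu <- atan2(center[2] - y[idx, f], center[1] - x[idx, f])
        drawn <- rvonmises(m, 0, params$bias_kappa) + mu
      } else {
        drawn <- runif(m, -pi, pi)
      }
      if (stim && exact_bias) {
        h <- wrap_angle(drawn)
      } else {
        h <- atan2(p * sin(heading[idx]) + (1 - p) * sin(drawn),
                   p * cos(heading[idx]) + (1 - p) * cos(drawn))
      }
      len <- rgamma(m, shape = params$step_shape,
                    rate = params$step_shape / mean_len)
      x[idx, f + 1L] <- reflect_into(x[idx, f] + len * cos(h), 0, width)
      y[idx, f + 1L] <- reflect_into(y[idx, f] + len * sin(h), 0, height)
      heading[idx] <- h
    }
    still <- which(!moving | mean_len == 0)
    if (length(still)) {
      x[still, f + 1L] <- x[still, f]
      y[still, f + 1L] <- y[still, f]
    }
  }

  positions <- data.frame(
    cell_id = rep(seq_len(n), nf),
    frame = rep(0:(nf - 1L), each = n),
    x_um = as.vector(x),
    y_um = as.vector(y)
  )
  positions <- positions[order(positions$cell_id, positions$frame), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  structure(
    list(positions = positions, nonmover = nonmover, params = params,
         acq = acq, population = population, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Observed positions with centroid localization noise
#'
#' Adds independent Gaussian localization noise
#' (`position_noise_px * pixel_size` um per coordinate) to the true
#' positions, emulating centroid measurement error without rendering and
#' re-segmenting images.
#'
#' @param truth a `ground_truth` object.
#' @param seed integer RNG seed for the noise draws.
#' @return the positions data frame with noisy `x_um`, `y_um`.
#' @export
observed_positions <- function(truth, seed) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed))
  pos <- truth$positions
  s <- truth$params$position_noise_px * truth$acq$pixel_size
  if (s > 0) {
    pos$x_um <- pos$x_um + rnorm(nrow(pos), 0, s)
    pos$y_um <- pos$y_um + rnorm(nrow(pos), 0, s)
  }
  pos
}

#' Steps between consecutive frames of simulated trajectories
#'
#' Converts a position table (one row per cell per frame) into the step
#' table consumed by [step_metrics()], bypassing the imaging and tracking
#' stages.  Used to test the statistics layer against ground truth and to
#' build synthetic plates quickly.
#'
#' @param positions data frame with `cell_id, frame, x_um, y_um` (e.g. from
#'   [observed_positions()] or `truth$positions`).
#' @param frame_interval s between frames.
#' @return data frame `track_id, frame_t, x0_um, y0_um, x1_um, y1_um, dt_s`.
#' @export
truth_steps <- function(positions, frame_interval = 30) {
  pos <- positions[order(positions$cell_id, positions$frame), , drop = FALSE]
  same <- pos$cell_id[-1] == pos$cell_id[-nrow(pos)] &
    pos$frame[-1] == pos$frame[-nrow(pos)] + 1L
  i0 <- which(c(same, FALSE))
  data.frame(
    track_id = pos$cell_id[i0],
    frame_t = pos$frame[i0],
    x0_um = pos$x_um[i0], y0_um = pos$y_um[i0],
    x1_um = pos$x_um[i0 + 1L], y1_um = pos$y_um[i0 + 1L],
    dt_s = rep(frame_interval, length(i0))
  )
}

#' Write ground truth positions as CSV
#' @param truth a `ground_truth` object.
#' @param path output CSV path.
#' @param well well label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, well = "A01") {
  pos <- truth$positions
  pos$population <- truth$population
  pos$well <- well
  utils::write.csv(pos, path, row.names = FALSE)
  invisible(path)
}
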