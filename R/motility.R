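#' Per-step movement metrics
#'
#' For each step, computes the movement vector from the prior-frame
#' centroid to the latter-frame centroid, its length (distance moved), the
#' movement angle relative to the optimal direction unit vector (from the
#' prior-frame centroid toward the gradient center; 0 deg = straight at
#' the center, 180 deg = straight away), the directed displacement (dot
#' product of the movement vector with the optimal direction unit vector),
#' and the radial distance of the step origin from the gradient center.
#'
#' Angles are reported only for steps of at least `min_angle_move_um`
#' (default 10 um = 4 px), so that localization noise on near-stationary
#' cells does not contaminate the angle statistics.  A step originating
#' exactly at the gradient center has no defined optimal direction; its
#' angle and directed displacement are `NA` and it is flagged.
#'
#' Epochs: a step is `"pre"` when both its frames precede the uncaging
#' frame, `"post"` when both follow it, and the single step spanning the
#' uncaging event is `"spanning"` (excluded from both epochs'
#' statistics).
#'
#' @param steps data frame from [trajectory_steps()] or [truth_steps()]
#'   (columns `frame_t, x0_um, y0_um, x1_um, y1_um, dt_s`).
#' @param center gradient center `(x, y)` in um.
#' @param n_pre_frames number of pre-stimulus frames (uncaging happens
#'   between frames `n_pre_frames - 1` and `n_pre_frames`, 0-based).
#' @param min_angle_move_um minimum distance moved for angle measurement,
#'   um.
#' @return an object of class `step_records`: the input with added columns
#'   `distance_um`, `speed_um_min`, `theta_deg`, `directed_um`,
#'   `directed_speed_um_min`, `origin_r_um`, `epoch`, `center_flag`.
#' @export
step_metrics <- function(steps, center, n_pre_frames = 17,
                         min_angle_move_um = 10) {
  stopifnot(all(c("frame_t", "x0_um", "y0_um", "x1_um", "y1_um", "dt_s")
                %in% names(steps)),
            length(center) == 2, all(steps$dt_s > 0))
  vx <- steps$x1_um - steps$x0_um
  vy <- steps$y1_um - steps$y0_um
  distance <- sqrt(vx^2 + vy^2)
  ox <- center[1] - steps$x0_um
  oy <- center[2] - steps$y0_um
  origin_r <- sqrt(ox^2 + oy^2)
  at_center <- origin_r == 0
  ux <- ifelse(at_center, NA_real_, ox / origin_r)
  uy <- ifelse(at_center, NA_real_, oy / origin_r)
  directed <- vx * ux + vy * uy
  cross <- vx * uy - vy * ux
  theta <- atan2(abs(cross), directed) * 180 / pi
  theta[distance < min_angle_move_um | at_center] <- NA_real_
  epoch <- ifelse(steps$frame_t + 1L < n_pre_frames, "pre",
                  ifelse(steps$frame_t >= n_pre_frames, "post", "spanning"))
  out <- steps
  out$distance_um <- distance
  out$speed_um_min <- 60 * distance / steps$dt_s
  out$theta_deg <- theta
  out$directed_um <- directed
  out$directed_speed_um_min <- 60 * directed / steps$dt_s
  out$origin_r_um <- origin_r
  out$epoch <- epoch
  out$center_flag <- at_center
  class(out) <- c("step_records", class(out))
  out
}

#' Per-well motility summary
#'
#' Aggregates step records into the four per-well statistics:
#'
#' * **basal speed**: mean of `distance / dt` over all pre-stimulus steps
#'   (um/min; the pre-stimulus field is spatially homogeneous, so no
#'   radial bounds apply);
#' * **stimulated speed**: the same over post-stimulus steps whose origin
#'   lies between `r_min` and `r_max` from the gradient center (the
#'   annulus in which the gradient is well formed);
#' * **directed speed**: mean of `directed displacement / dt` over the
#'   same post-stimulus steps;
#' * **angular bias**: 90 minus the mean movement angle over the
#'   post-stimulus steps in the annulus that also moved at least
#'   `min_angle_move_um`.  0 = random directions, 90 = all steps straight
#'   at the center, negative = net movement away.
#'
#' Statistics with zero qualifying steps are `NA`, never 0.
#'
#' @param records a `step_records` data frame from [step_metrics()].
#' @param r_min,r_max radial inclusion bounds for in-gradient statistics,
#'   um.
#' @param population,well labels copied into the summary row.
#' @return one-row data frame of class `well_motility_summary`:
#'   `basal_speed`, `stim_speed`, `directed_speed`, `angular_bias`,
#'   `n_basal`, `n_stim`, `n_angle`, `population`, `well`.
#' @export
well_summary <- function(records, r_min = 250, r_max = 1625,
                         population = NA_character_, well = NA_character_) {
  stopifnot(inherits(records, "step_records") ||
              all(c("epoch", "speed_um_min", "origin_r_um") %in%
                    names(records)))
  pre <- records$epoch == "pre"
  post <- records$epoch == "post" &
    records$origin_r_um >= r_min & records$origin_r_um <= r_max
  ang <- post & !is.na(records$theta_deg)
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  out <- data.frame(
    basal_speed = mean_or_na(records$speed_um_min[pre]),
    stim_speed = mean_or_na(records$speed_um_min[post]),
    directed_speed = mean_or_na(
      records$directed_speed_um_min[post & !records$center_flag]),
    angular_bias = 90 - mean_or_na(records$theta_deg[ang]),
    n_basal = sum(pre),
    n_stim = sum(post),
    n_angle = sum(ang),
    population = population,
    well = well,
    stringsAsFactors = FALSE
  )
  class(out) <- c("well_motility_summary", class(out))
  out
}

#' Per-frame time course of motility statistics
#'
#' Mean speed and directed speed per step-origin frame, plus a per-frame
#' histogram of movement angles (rows normalized to sum to 1 when a frame
#' has at least one qualifying angle).  The radial inclusion annulus is
#' applied at every frame so pre- and post-stimulus values are computed
#' over the same region.
#'
#' @param records a `step_records` data frame.
#' @param n_bins number of angle histogram bins over `[0, 180]` deg.
#' @param r_min,r_max radial inclusion bounds, um.
#' @return list with `by_frame` (data frame `frame_t, mean_speed,
#'   mean_directed_speed, n`) and `angle_hist` (matrix, one row per frame,
#'   one column per bin).
#' @export
time_course <- function(records, n_bins = 12, r_min = 250, r_max = 1625) {
  sel <- records$origin_r_um >= r_min & records$origin_r_um <= r_max
  rec <- records[sel, , drop = FALSE]
  frames <- sort(unique(records$frame_t))
  by_frame <- data.frame(
    frame_t = frames,
    mean_speed = NA_real_,
    mean_directed_speed = NA_real_,
    n = 0L
  )
  breaks <- seq(0, 180, length.out = n_bins + 1)
  hist_mat <- matrix(0, length(frames), n_bins,
                     dimnames = list(frames, NULL))
  for (k in seq_along(frames)) {
    rf <- rec[rec$frame_t == frames[k], , drop = FALSE]
    by_frame$n[k] <- nrow(rf)
    if (nrow(rf) > 0) {
      by_frame$mean_speed[k] <- mean(rf$speed_um_min)
      by_frame$mean_directed_speed[k] <-
        mean(rf$directed_speed_um_min[!rf$center_flag])
    }
    th <- rf$theta_deg[!is.na(rf$theta_deg)]
    if (length(th) > 0) {
      counts <- tabulate(findInterval(th, breaks, rightmost.closed = TRUE),
                         nbins = n_bins)
      hist_mat[k, ] <- counts / sum(counts)
    }
  }
  list(by_frame = by_frame, angle_hist = hist_mat)
}
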