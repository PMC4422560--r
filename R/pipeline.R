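#' Analyze one well's movie end to end
#'
#' Runs the full imaging-to-statistics pipeline on a frame stack: per-frame
#' blockwise-percentile background subtraction, threshold + watershed
#' segmentation, area filtering, mutual nearest-neighbor tracking with the
#' crowding filter, nonmover removal, and per-well motility statistics.
#'
#' @param frames list of intensity matrices or a `frame_stack` from
#'   [render_movie()].
#' @param acq [acquisition_params()] describing the acquisition.
#' @param threshold segmentation threshold (intensity above local
#'   background).
#' @param block_px,percentile background-estimation parameters.
#' @param min_area,max_area area filter bounds, px.
#' @param d_thresh crowding threshold, um.
#' @param max_disp_px nonmover threshold, px.
#' @param r_min,r_max radial inclusion bounds for in-gradient statistics,
#'   um.
#' @param population,well labels for the summary row.
#' @return list with `summary` (a [well_summary()] row), `records` (step
#'   records), `trajectories` (tracked detections), `detections`.
#' @export
analyze_movie <- function(frames, acq, threshold,
                          block_px = 32, percentile = 80,
                          min_area = 5, max_area = 75,
                          d_thresh = 40, max_disp_px = 2,
                          r_min = 250, r_max = 1625,
                          population = NA_character_,
                          well = NA_character_) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  det <- detect_movie(frames, threshold, block_px = block_px,
                      percentile = percentile, min_area = min_area,
                      max_area = max_area)
  traj <- link_movie(det, pixel_size = acq$pixel_size, d_thresh = d_thresh)
  traj <- filter_nonmoving(traj, max_disp_px = max_disp_px)
  steps <- trajectory_steps(traj, pixel_size = acq$pixel_size,
                            frame_interval = acq$frame_interval)
  records <- step_metrics(steps, gradient_center_um(acq),
                          n_pre_frames = acq$n_pre_frames)
  list(
    summary = well_summary(records, r_min = r_min, r_max = r_max,
                           population = population, well = well),
    records = records,
    trajectories = traj,
    detections = det
  )
}
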