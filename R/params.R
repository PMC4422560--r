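#' Cell motion parameters for the trajectory simulator
#'
#' Parameters of the biased persistent random walk used to generate
#' ground-truth trajectories.  Before the stimulus, cells take steps of mean
#' length `basal_speed * dt` in persistent-random directions; after the
#' stimulus, step length mean switches to `stimulated_speed * dt` and
#' headings are drawn from a von Mises distribution concentrated (with
#' parameter `bias_kappa`) around the direction toward the gradient center.
#' A `nonmover_fraction` of cells stays pinned at its initial position
#' (plus localization noise), emulating the dead/undifferentiated cells the
#' nonmover filter is designed to remove.
#'
#' Defaults emulate neutrophil-like cells that roughly double their speed on
#' stimulation and acquire a clear directional bias.
#'
#' @param n_cells number of cells per well.
#' @param basal_speed pre-stimulus mean speed, um/min.
#' @param stimulated_speed post-stimulus mean speed, um/min.
#' @param persistence step-to-step direction correlation in `[0, 1)`.
#' @param bias_kappa von Mises concentration of post-stimulus headings
#'   around the direction to the gradient center; 0 = unbiased; `Inf`
#'   (or any value >= the internal cap of 1e6) points every post-stimulus
#'   step exactly at the center.
#' @param nonmover_fraction fraction of cells that never move, in `[0, 1]`.
#' @param position_noise_px centroid localization noise, pixels (s.d. per
#'   coordinate).
#' @param step_shape gamma shape of the step-length distribution (mean is
#'   always speed * dt); shape 2 gives realistically dispersed step lengths.
#' @return an object of class `cell_sim_params`.
#' @seealso [simulate_trajectories()], [acquisition_params()]
#' @export
cell_sim_params <- function(n_cells = 200,
                            basal_speed = 10,
                            stimulated_speed = 20,
                            persistence = 0.5,
                            bias_kappa = 2,
                            nonmover_fraction = 0.05,
                            position_noise_px = 0.3,
                            step_shape = 2) {
  stopifnot(
    is.numeric(n_cells), length(n_cells) == 1, n_cells >= 0,
    is.finite(basal_speed), basal_speed >= 0,
    is.finite(stimulated_speed), stimulated_speed >= 0,
    is.finite(persistence), persistence >= 0, persistence < 1,
    !is.na(bias_kappa), bias_kappa >= 0,
    is.finite(nonmover_fraction),
    nonmover_fraction >= 0, nonmover_fraction <= 1,
    is.finite(position_noise_px), position_noise_px >= 0,
    is.finite(step_shape), step_shape > 0
  )
  structure(
    list(
      n_cells = as.integer(n_cells),
      basal_speed = basal_speed,
      stimulated_speed = stimulated_speed,
      persistence = persistence,
      bias_kappa = bias_kappa,
      nonmover_fraction = nonmover_fraction,
      position_noise_px = position_noise_px,
      step_shape = step_shape
    ),
    class = "cell_sim_params"
  )
}

#' Acquisition geometry and timing
#'
#' Frame geometry and schedule of the time-lapse acquisition: 1,024 x 1,280
#' pixel frames at 2.5 um/px, one frame every 30 s, 17 frames before the
#' initial uncaging pulse and 33 after (50 total).  The gradient center
#' defaults to the image center.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param n_pre_frames frames acquired before gradient generation.
#' @param n_post_frames frames acquired after gradient generation.
#' @param gradient_center `(x, y)` pixel coordinates (0-based) of the
#'   gradient center, default the image center `((cols-1)/2, (rows-1)/2)`.
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(image_shape = c(1024L, 1280L),
                               pixel_size = 2.5,
                               frame_interval = 30,
                               n_pre_frames = 17L,
                               n_post_frames = 33L,
                               gradient_center = NULL) {
  stopifnot(
    length(image_shape) == 2, all(image_shape >= 1),
    pixel_size > 0, frame_interval > 0,
    n_pre_frames >= 0, n_post_frames >= 0,
    n_pre_frames + n_post_frames >= 2
  )
  if (is.null(gradient_center)) {
    gradient_center <- c((image_shape[2] - 1) / 2, (image_shape[1] - 1) / 2)
  }
  stopifnot(length(gradient_center) == 2)
  structure(
    list(
      image_shape = as.integer(image_shape),
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      n_pre_frames = as.integer(n_pre_frames),
      n_post_frames = as.integer(n_post_frames),
      n_frames = as.integer(n_pre_frames + n_post_frames),
      gradient_center = as.numeric(gradient_center)
    ),
    class = "acquisition_params"
  )
}

#' Gradient center in microns
#' @param acq an [acquisition_params()] object.
#' @return `(x, y)` in um.
#' @keywords internal
gradient_center_um <- function(acq) {
  acq$gradient_center * acq$pixel_size
}

#' Synthetic screening-plate specification
#'
#' Describes a plate in which every well holds two co-plated populations: an
#' experimental population carrying its condition's true effects and a
#' control population with the shared base parameters.  Both populations in
#' a well share one multiplicative well-to-well speed factor (lognormal with
#' log-s.d. `well_effect_sd`), the structure the in-well-control
#' normalization is designed to remove.
#'
#' Condition effects are relative: an effect of -0.5 on stimulated speed
#' multiplies the experimental population's stimulated speed by 0.5, so the
#' recovered phenotype score should be about -0.5.
#'
#' @param conditions data frame with columns `condition` and any of
#'   `basal_effect`, `stim_effect`, `bias_effect` (missing columns are
#'   treated as zero effect).
#' @param n_replicates wells per condition.
#' @param well_effect_sd s.d. of the log multiplicative well effect.
#' @param cell_params base [cell_sim_params()] shared by the control
#'   population in every well.
#' @param acq [acquisition_params()].
#' @return an object of class `plate_sim_spec`.
#' @seealso [make_plate()]
#' @export
plate_sim_spec <- function(conditions,
                           n_replicates = 3,
                           well_effect_sd = 0.15,
                           cell_params = cell_sim_params(),
                           acq = acquisition_params()) {
  stopifnot(is.data.frame(conditions), "condition" %in% names(conditions))
  for (col in c("basal_effect", "stim_effect", "bias_effect")) {
    if (is.null(conditions[[col]])) conditions[[col]] <- 0
    stopifnot(all(is.finite(conditions[[col]])))
  }
  n_wells <- nrow(conditions) * n_replicates
  if (n_wells > 96) {
    stop("plate has ", n_wells, " wells; at most 96 supported")
  }
  stopifnot(well_effect_sd >= 0, inherits(cell_params, "cell_sim_params"),
            inherits(acq, "acquisition_params"))
  structure(
    list(
      conditions = conditions,
      n_replicates = as.integer(n_replicates),
      n_wells = as.integer(n_wells),
      well_effect_sd = well_effect_sd,
      cell_params = cell_params,
      acq = acq
    ),
    class = "plate_sim_spec"
  )
}

#' Read a plate specification from a YAML file
#'
#' The YAML schema mirrors [plate_sim_spec()]: top-level keys
#' `n_replicates`, `well_effect_sd`, optional `cell_params` (a mapping of
#' [cell_sim_params()] arguments), optional `acquisition` (a mapping of
#' [acquisition_params()] arguments), and `conditions`, a sequence of
#' mappings each with `condition` and optional `basal_effect`,
#' `stim_effect`, `bias_effect`.
#'
#' @param path YAML file path.
#' @return a `plate_sim_spec`.
#' @export
read_plate_spec <- function(path) {
  y <- yaml::read_yaml(path)
  conds <- do.call(rbind, lapply(y$conditions, function(cond) {
    data.frame(
      condition = cond$condition,
      basal_effect = cond$basal_effect %||% 0,
      stim_effect = cond$stim_effect %||% 0,
      bias_effect = cond$bias_effect %||% 0
    )
  }))
  cp <- do.call(cell_sim_params, y$cell_params %||% list())
  acq <- do.call(acquisition_params, y$acquisition %||% list())
  plate_sim_spec(
    conditions = conds,
    n_replicates = y$n_replicates %||% 3,
    well_effect_sd = y$well_effect_sd %||% 0.15,
    cell_params = cp,
    acq = acq
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
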