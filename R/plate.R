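# derive a per-well RNG substream seed from the plate seed and well index
well_seed <- function(seed, well, salt = 0L) {
  (as.double(seed) * 48271 + well * 104729 + salt * 7919) %% 2147483647
}

#' Simulate a whole screening plate
#'
#' Generates per-well motility summaries for a plate in which every well
#' carries an experimental population (with its condition's true effects)
#' and an in-well control population.  Both populations share one
#' multiplicative well-to-well speed factor (lognormal, log-s.d.
#' `well_effect_sd`), applied to basal and stimulated speed; the
#' experimental population's parameters are additionally scaled by
#' `(1 + effect)` for each phenotype with a declared condition effect.
#' Trajectories are simulated directly and summarized through
#' [step_metrics()] and [well_summary()] (centroid localization noise
#' included), bypassing the rendering/segmentation stages, so a 96-well
#' plate simulates in seconds.
#'
#' @param spec a [plate_sim_spec()].
#' @param seed integer seed; per-well substreams are derived from it, so
#'   the plate is reproducible as a whole.
#' @return data frame with two rows per well (experimental + control) and
#'   columns `well`, `condition`, `replicate`, `population`,
#'   `basal_speed`, `stim_speed`, `directed_speed`, `angular_bias`,
#'   `n_basal`, `n_stim`, `n_angle`.  The attribute `"truth"` holds the
#'   per-well data frame of true effects and well factors.
#' @export
make_plate <- function(spec, seed) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  acq <- spec$acq
  base <- spec$cell_params
  center <- gradient_center_um(acq)
  layout <- data.frame(
    well = seq_len(spec$n_wells),
    condition = rep(spec$conditions$condition, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), nrow(spec$conditions)),
    basal_effect = rep(spec$conditions$basal_effect,
                       each = spec$n_replicates),
    stim_effect = rep(spec$conditions$stim_effect,
                      each = spec$n_replicates),
    bias_effect = rep(spec$conditions$bias_effect,
                      each = spec$n_replicates)
  )
  rows <- vector("list", 2L * spec$n_wells)
  well_factor <- numeric(spec$n_wells)
  for (w in seq_len(spec$n_wells)) {
    set.seed(well_seed(seed, w, 0L))
    well_factor[w] <- exp(rnorm(1, 0, spec$well_effect_sd))
    pops <- list(
      experimental = cell_sim_params(
        n_cells = base$n_cells,
        basal_speed = base$basal_speed * well_factor[w] *
          (1 + layout$basal_effect[w]),
        stimulated_speed = base$stimulated_speed * well_factor[w] *
          (1 + layout$stim_effect[w]),
        persistence = base$persistence,
        bias_kappa = base$bias_kappa * (1 + layout$bias_effect[w]),
        nonmover_fraction = base$nonmover_fraction,
        position_noise_px = base$position_noise_px,
        step_shape = base$step_shape
      ),
      control = cell_sim_params(
        n_cells = base$n_cells,
        basal_speed = base$basal_speed * well_factor[w],
        stimulated_speed = base$stimulated_speed * well_factor[w],
        persistence = base$persistence,
        bias_kappa = base$bias_kappa,
        nonmover_fraction = base$nonmover_fraction,
        position_noise_px = base$position_noise_px,
        step_shape = base$step_shape
      )
    )
    for (p in seq_along(pops)) {
      pop <- names(pops)[p]
      truth <- simulate_trajectories(pops[[p]], acq,
                                     seed = well_seed(seed, w, p),
                                     population = pop)
      obs <- observed_positions(truth, seed = well_seed(seed, w, p + 2L))
      # nonmover filter on observed positions (> 2 px from initial location)
      max_disp <- tapply(seq_len(nrow(obs)), obs$cell_id, function(ix) {
        max(sqrt((obs$x_um[ix] - obs$x_um[ix[1]])^2 +
                   (obs$y_um[ix] - obs$y_um[ix[1]])^2))
      })
      movers <- as.integer(names(max_disp))[max_disp > 2 * acq$pixel_size]
      obs <- obs[obs$cell_id %in% movers, , drop = FALSE]
      rec <- step_metrics(truth_steps(obs, acq$frame_interval), center,
                          n_pre_frames = acq$n_pre_frames)
      smry <- well_summary(rec, population = pop, well = w)
      smry$condition <- layout$condition[w]
      smry$replicate <- layout$replicate[w]
      rows[[(w - 1L) * 2L + p]] <- smry
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  layout$well_factor <- well_factor
  attr(out, "truth") <- layout
  out
}
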