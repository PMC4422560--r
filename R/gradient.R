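#' An uncaging pulse
#'
#' One UV exposure that converts a fraction of the locally remaining caged
#' attractant into its active form.  The out-of-focus illumination profile
#' is modeled as a radial Gaussian of width `profile_sigma` centered on the
#' gradient center.
#'
#' @param time pulse time, s.
#' @param dose_fraction fraction of the locally remaining caged molecule
#'   converted, in `[0, 1]`.
#' @param profile_sigma spatial s.d. of the illumination profile, um
#'   (`Inf` = spatially uniform).
#' @return an object of class `uncaging_pulse`.
#' @export
uncaging_pulse <- function(time, dose_fraction, profile_sigma = 500) {
  stopifnot(is.finite(time), time >= 0,
            is.finite(dose_fraction), dose_fraction >= 0, dose_fraction <= 1,
            profile_sigma > 0)
  structure(list(time = time, dose_fraction = dose_fraction,
                 profile_sigma = profile_sigma),
            class = "uncaging_pulse")
}

#' An initial-plus-recharging pulse schedule
#'
#' An initial pulse at t = 0 followed by periodic small recharging pulses.
#' The default recharge-to-initial dose ratio 0.008 corresponds to the
#' exposure-time ratio 20 ms / 2.5 s, and the default interval to one
#' recharge every three 30-s frames.
#'
#' @param t_end schedule horizon, s (recharges at `interval, 2*interval,
#'   ... <= t_end`).
#' @param initial_dose dose fraction of the initial pulse.
#' @param recharge_ratio recharge-to-initial dose ratio.
#' @param recharge_interval s between recharges.
#' @param profile_sigma illumination width, um (shared by all pulses).
#' @return a list of [uncaging_pulse()] objects, class `pulse_schedule`.
#' @export
pulse_schedule <- function(t_end,
                           initial_dose = 0.3,
                           recharge_ratio = 0.008,
                           recharge_interval = 90,
                           profile_sigma = 500) {
  stopifnot(t_end >= 0, recharge_interval > 0, recharge_ratio >= 0)
  times <- 0
  if (recharge_ratio > 0) {
    times <- c(times, seq(recharge_interval, t_end, by = recharge_interval))
  }
  doses <- c(initial_dose, rep(initial_dose * recharge_ratio,
                               length(times) - 1))
  pulses <- Map(uncaging_pulse, time = times, dose_fraction = doses,
                profile_sigma = profile_sigma)
  stopifnot(all(diff(times) > 0))
  structure(pulses, class = "pulse_schedule")
}

#' Radial concentration field
#'
#' State of the uncaged attractant pool and the remaining caged reservoir
#' on a cell-centered radial grid (`r[i] = (i - 1/2) * dr`).  The
#' constructor returns the pre-uncaging state: no free attractant, a
#' uniform caged reservoir.  [evolve()] appends one column per output time
#' to the concentration matrices `C` (uncaged) and `K` (caged).
#'
#' @param r_max outer radius of the simulation domain, um.
#' @param dr radial grid spacing, um.
#' @param reservoir initial caged concentration (arbitrary units).
#' @param D diffusion coefficient of the uncaged attractant, um^2/s.
#' @return an object of class `concentration_field` with elements `r`,
#'   `dr`, `times`, `C` (length(r) x length(times)), `K`, `D`.
#' @export
concentration_field <- function(r_max = 3000, dr = 5, reservoir = 1,
                                D = 300) {
  stopifnot(r_max > dr, dr > 0, reservoir >= 0, D > 0)
  n <- floor(r_max / dr)
  r <- (seq_len(n) - 0.5) * dr
  structure(
    list(r = r, dr = dr, times = 0,
         C = matrix(0, n, 1),
         K = matrix(reservoir, n, 1),
         reservoir0 = rep(reservoir, n),
         D = D),
    class = "concentration_field"
  )
}

#' Apply an uncaging pulse to a concentration field
#'
#' Converts caged reservoir to free attractant at the field's latest stored
#' time.  The amount released at radius r is
#' `kappa(r) * dose_fraction * exp(-r^2 / (2 * profile_sigma^2))`, and is
#' moved from the caged reservoir to the uncaged pool.  With
#' `deplete = FALSE` the release is computed from the *initial* reservoir
#' and the reservoir is left untouched, which makes fields from multiple
#' pulses superpose linearly (useful for testing).
#'
#' @param field a `concentration_field`.
#' @param pulse an [uncaging_pulse()].
#' @param deplete deplete the caged reservoir (default) or not.
#' @return the updated `concentration_field`.
#' @export
apply_pulse <- function(field, pulse, deplete = TRUE) {
  stopifnot(inherits(field, "concentration_field"),
            inherits(pulse, "uncaging_pulse"))
  j <- ncol(field$C)
  g <- exp(-field$r^2 / (2 * pulse$profile_sigma^2))
  src <- if (deplete) field$K[, j] else field$reservoir0
  released <- src * pulse$dose_fraction * g
  field$C[, j] <- field$C[, j] + released
  if (deplete) field$K[, j] <- field$K[, j] - released
  field
}

# Crank-Nicolson propagator for radial diffusion on the cell-centered grid.
# Conservative form: flux between cells i and i+1 crosses the face at
# radius i*dr, so the r-weighted total mass is preserved exactly (up to
# floating point) and the scheme is 2nd order in dr and dt.
radial_propagator <- function(n, dr, D, dt) {
  r <- (seq_len(n) - 0.5) * dr
  rface <- seq_len(n - 1) * dr  # interior faces
  A <- matrix(0, n, n)
  coef <- D / dr^2
  for (i in seq_len(n - 1)) {
    f <- coef * rface[i]
    A[i, i] <- A[i, i] - f / r[i]
    A[i, i + 1] <- A[i, i + 1] + f / r[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - f / r[i + 1]
    A[i + 1, i] <- A[i + 1, i] + f / r[i + 1]
  }
  eye <- diag(n)
  solve(eye - (dt / 2) * A, eye + (dt / 2) * A)
}

#' Evolve a concentration field under a pulse schedule
#'
#' Simulates 2-D free diffusion of the uncaged attractant (and, with its
#' own coefficient, of the caged reservoir) in a thin gel layer, radially
#' symmetric about the gradient center, punctuated by the uncaging pulses
#' of `schedule`.  Diffusion uses a mass-conservative Crank-Nicolson
#' finite-difference scheme with zero-flux boundaries, so the total uncaged
#' mass is constant between pulses and non-decreasing overall.
#'
#' @param schedule a [pulse_schedule()] or list of [uncaging_pulse()].
#' @param D diffusion coefficient of the uncaged attractant, um^2/s
#'   (default 300, a small-molecule-in-gel order of magnitude).
#' @param times output times, s (must be multiples of `dt`, as must pulse
#'   times).
#' @param r_max,dr radial domain, um.
#' @param dt internal time step, s.
#' @param D_caged diffusion coefficient of the caged reservoir (default
#'   equal to `D`).
#' @param reservoir initial caged concentration.
#' @param deplete passed to [apply_pulse()].
#' @param field optional pre-built starting [concentration_field()] (its
#'   `r_max`, `dr`, `reservoir` override the arguments).
#' @return a `concentration_field` with one column of `C`/`K` per output
#'   time.
#' @examples
#' fld <- evolve(pulse_schedule(300), times = seq(0, 300, 30))
#' steepness(fld, r = 300)
#' @export
evolve <- function(schedule, D = 300, times, r_max = 3000, dr = 5, dt = 1,
                   D_caged = D, reservoir = 1, deplete = TRUE,
                   field = NULL) {
  stopifnot(D > 0, D_caged > 0, length(times) >= 1, all(times >= 0))
  if (is.null(field)) {
    field <- concentration_field(r_max = r_max, dr = dr,
                                 reservoir = reservoir, D = D)
  }
  times <- sort(unique(times))
  n <- length(field$r)
  on_grid <- function(t) {
    k <- round(t / dt)
    if (any(abs(t - k * dt) > 1e-9 * max(1, dt))) {
      stop("times and pulse times must lie on the internal dt grid")
    }
    k
  }
  out_steps <- on_grid(times)
  pulse_times <- vapply(schedule, function(p) p$time, numeric(1))
  stopifnot(all(diff(pulse_times) > 0))
  pulse_steps <- on_grid(pulse_times)
  n_steps <- max(c(out_steps, pulse_steps))

  P <- radial_propagator(n, field$dr, D, dt)
  Pk <- if (D_caged == D) P else radial_propagator(n, field$dr, D_caged, dt)

  cvec <- field$C[, ncol(field$C)]
  kvec <- field$K[, ncol(field$K)]
  Cout <- matrix(NA_real_, n, length(times))
  Kout <- matrix(NA_real_, n, length(times))
  record <- function(step) {
    j <- match(step, out_steps)
    if (!is.na(j)) {
      Cout[, j] <<- cvec
      Kout[, j] <<- kvec
    }
  }
  for (step in 0:n_steps) {
    hit <- which(pulse_steps == step)
    for (h in hit) {
      g <- exp(-field$r^2 / (2 * schedule[[h]]$profile_sigma^2))
      src <- if (deplete) kvec else field$reservoir0
      released <- src * schedule[[h]]$dose_fraction * g
      cvec <- cvec + released
      if (deplete) kvec <- kvec - released
    }
    record(step)
    if (step < n_steps) {
      cvec <- as.vector(P %*% cvec)
      kvec <- as.vector(Pk %*% kvec)
    }
  }
  field$times <- times
  field$C <- Cout
  field$K <- Kout
  field$D <- D
  field
}

#' Total uncaged mass over time
#'
#' Mass of the free attractant pool, `2 * pi * sum(r * c(r) * dr)`, one
#' value per stored time.
#'
#' @param field a `concentration_field`.
#' @return numeric vector, one value per column of `field$C`.
#' @export
field_mass <- function(field) {
  stopifnot(inherits(field, "concentration_field"))
  as.vector(2 * pi * field$dr * crossprod(field$r, field$C))
}

#' Gradient steepness across a cell-length probe
#'
#' Percent concentration change over a probe of length `L` starting at
#' radius `r`: `100 * (c(r) - c(r + L)) / c(r)` at each stored time.
#' Positive values mean concentration decreases outward (an inward-pointing
#' gradient); the value is bounded above by 100.  The temporal coefficient
#' of variation (s.d. / |mean|) is computed over the times in `window`.
#'
#' @param field a `concentration_field` with stored time course.
#' @param r reference radius, um.
#' @param L probe length, um (default 30, about one neutrophil length).
#' @param window `c(t0, t1)` s; times used for the temporal CV (default all
#'   stored times after the first pulse-bearing time, i.e. `times > 0`).
#' @return an object of class `steepness_report`: list with `profile`
#'   (data frame `time_s, pct`), `cv`, `r`, `L`, `window`.
#' @export
steepness <- function(field, r, L = 30, window = NULL) {
  stopifnot(inherits(field, "concentration_field"),
            r >= min(field$r), r + L <= max(field$r))
  c_r <- apply(field$C, 2, function(col) approx(field$r, col, xout = r)$y)
  c_rL <- apply(field$C, 2, function(col) approx(field$r, col, xout = r + L)$y)
  pct <- ifelse(c_r > 0, 100 * (c_r - c_rL) / c_r, NA_real_)
  if (anyNA(pct)) {
    warning("steepness undefined at times where c(r) = 0")
  }
  if (is.null(window)) window <- c(min(field$times[field$times > 0],
                                       Inf), max(field$times))
  sel <- field$times >= window[1] & field$times <= window[2] & !is.na(pct)
  cv <- if (sum(sel) >= 2 && abs(mean(pct[sel])) > 0) {
    sd(pct[sel]) / abs(mean(pct[sel]))
  } else {
    NA_real_
  }
  structure(
    list(profile = data.frame(time_s = field$times, pct = pct),
         cv = cv, r = r, L = L, window = window),
    class = "steepness_report"
  )
}

#' Search recharge dose ratios that hold the gradient steady
#'
#' Deterministic grid search: for each candidate recharge-to-initial dose
#' ratio, simulates the full pulse schedule and scores the temporal
#' coefficient of variation of gradient steepness at the reference radius
#' over the target window.  Returns the ratio minimizing the CV, together
#' with the full CV table and the no-recharge baseline.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param interval recharge interval, s.
#' @param sigma illumination profile width, um.
#' @param dose_ratios candidate recharge-to-initial dose ratios (include 0
#'   to allow "no recharging" to win).
#' @param t_end simulation horizon, s.
#' @param window temporal window for the CV, s (default `c(interval,
#'   t_end)`).
#' @param ref_r reference radius for steepness, um.
#' @param L probe length, um.
#' @param initial_dose dose fraction of the initial pulse.
#' @param r_max,dr,dt simulation grid (see [evolve()]).
#' @return list with `best_ratio`, `results` (data frame `ratio, cv`), and
#'   `no_recharge_cv`.
#' @export
design_recharge <- function(D = 300, interval = 90, sigma = 500,
                            dose_ratios = c(0, 0.002, 0.005, 0.008,
                                            0.012, 0.02, 0.03),
                            t_end = 1500, window = NULL, ref_r = 300,
                            L = 30, initial_dose = 0.3,
                            r_max = 3000, dr = 10, dt = 2) {
  stopifnot(length(dose_ratios) >= 1, all(dose_ratios >= 0))
  if (is.null(window)) window <- c(interval, t_end)
  times <- seq(0, t_end, by = interval / 3)
  cvs <- vapply(dose_ratios, function(ratio) {
    sched <- pulse_schedule(t_end, initial_dose = initial_dose,
                            recharge_ratio = ratio,
                            recharge_interval = interval,
                            profile_sigma = sigma)
    fld <- evolve(sched, D = D, times = times, r_max = r_max, dr = dr,
                  dt = dt)
    steepness(fld, r = ref_r, L = L, window = window)$cv
  }, numeric(1))
  no_recharge_cv <- if (0 %in% dose_ratios) {
    cvs[match(0, dose_ratios)]
  } else {
    sched0 <- pulse_schedule(t_end, initial_dose = initial_dose,
                             recharge_ratio = 0,
                             recharge_interval = interval,
                             profile_sigma = sigma)
    fld0 <- evolve(sched0, D = D, times = times, r_max = r_max, dr = dr,
                   dt = dt)
    steepness(fld0, r = ref_r, L = L, window = window)$cv
  }
  list(best_ratio = dose_ratios[which.min(cvs)],
       results = data.frame(ratio = dose_ratios, cv = cvs),
       no_recharge_cv = no_recharge_cv)
}

#' Write a concentration time course as long-format CSV
#' @param field a `concentration_field`.
#' @param path output CSV path (columns `time_s, r_um, conc`).
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  long <- data.frame(
    time_s = rep(field$times, each = length(field$r)),
    r_um = rep(field$r, length(field$times)),
    conc = as.vector(field$C)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
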