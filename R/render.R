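#' Optics settings for movie rendering
#'
#' Nuclei are rendered as isotropic Gaussian bright spots on a smooth
#' non-uniform background with shot-like noise (Gaussian with s.d.
#' proportional to the square root of the local expected intensity).  With
#' the default spot width and amplitude, segmenting at the default
#' threshold yields object areas well inside the (5, 75] px acceptance
#' window of [filter_by_area()].
#'
#' @param spot_sigma_px Gaussian s.d. of the rendered nucleus, px.
#' @param spot_intensity peak intensity added by one nucleus.
#' @param background_level mean background intensity.
#' @param background_tilt relative background slope across the full image,
#'   `(x, y)`; models uneven illumination.
#' @param noise_scale multiplier on the sqrt-intensity noise s.d.; 0
#'   disables noise.
#' @return an object of class `optics_params`.
#' @export
optics_params <- function(spot_sigma_px = 2,
                          spot_intensity = 400,
                          background_level = 100,
                          background_tilt = c(0.2, 0.1),
                          noise_scale = 1) {
  stopifnot(spot_sigma_px > 0, spot_intensity >= 0, background_level >= 0,
            length(background_tilt) == 2, noise_scale >= 0)
  # expected supra-threshold area at half the peak height, used for the
  # area-filter sanity warning in render_movie()
  structure(
    list(spot_sigma_px = spot_sigma_px,
         spot_intensity = spot_intensity,
         background_level = background_level,
         background_tilt = as.numeric(background_tilt),
         noise_scale = noise_scale),
    class = "optics_params"
  )
}

#' Render a synthetic nuclei movie from ground-truth trajectories
#'
#' Produces one intensity matrix per frame for the channel corresponding to
#' the trajectory set's population label.  Each nucleus is an isotropic
#' Gaussian spot of width `spot_sigma_px`; the background is a tilted plane
#' plus shot-like noise.  Multi-population wells are rendered by calling
#' this once per `ground_truth` object (one channel each).
#'
#' @param truth a `ground_truth` object from [simulate_trajectories()].
#' @param optics an [optics_params()] object.
#' @param seed integer RNG seed for the noise.
#' @param max_area_px upper area filter used for the oversize-spot warning
#'   (see [filter_by_area()]).
#' @return a list of class `frame_stack`: `frames` (list of matrices,
#'   rows x cols), `channel`, `acq`, `optics`.
#' @export
render_movie <- function(truth, optics = optics_params(), seed = 1,
                         max_area_px = 75) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(optics, "optics_params"))
  set.seed(as.integer(seed))
  acq <- truth$acq
  nr <- acq$image_shape[1]
  nc <- acq$image_shape[2]
  # area enclosed by the half-maximum contour; crude guide for the filter
  expected_area <- pi * 2 * log(2) * optics$spot_sigma_px^2
  if (expected_area > max_area_px) {
    warning("expected spot area ", round(expected_area, 1),
            " px exceeds the upper area filter (", max_area_px, " px)")
  }
  tiltx <- optics$background_tilt[1]
  tilty <- optics$background_tilt[2]
  colfrac <- (seq_len(nc) - 1) / max(1, nc - 1)
  rowfrac <- (seq_len(nr) - 1) / max(1, nr - 1)
  bg <- optics$background_level *
    (1 + outer(rowfrac * tilty, colfrac * tiltx, `+`))
  halfw <- ceiling(4 * optics$spot_sigma_px)
  pos <- truth$positions
  frames <- vector("list", acq$n_frames)
  for (f in seq_len(acq$n_frames)) {
    img <- bg
    pf <- pos[pos$frame == f - 1L & !is.na(pos$x_um), , drop = FALSE]
    if (nrow(pf) > 0) {
      cx <- pf$x_um / acq$pixel_size  # 0-based px
      cy <- pf$y_um / acq$pixel_size
      for (i in seq_len(nrow(pf))) {
        c0 <- max(1L, floor(cx[i]) + 1L - halfw)
        c1 <- min(nc, floor(cx[i]) + 1L + halfw)
        r0 <- max(1L, floor(cy[i]) + 1L - halfw)
        r1 <- min(nr, floor(cy[i]) + 1L + halfw)
        if (c0 > c1 || r0 > r1) next
        dx2 <- ((c0:c1) - 1 - cx[i])^2
        dy2 <- ((r0:r1) - 1 - cy[i])^2
        spot <- optics$spot_intensity *
          exp(-outer(dy2, dx2, `+`) / (2 * optics$spot_sigma_px^2))
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + spot
      }
    }
    if (optics$noise_scale > 0) {
      img <- img + rnorm(length(img), 0, optics$noise_scale * sqrt(img))
      img[img < 0] <- 0
    }
    frames[[f]] <- img
  }
  structure(
    list(frames = frames, channel = truth$population, acq = acq,
         optics = optics),
    class = "frame_stack"
  )
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit samples after division by `scale`
#' (choose `scale` above the maximum expected intensity).
#'
#' @param stack a `frame_stack` from [render_movie()], or a plain list of
#'   matrices.
#' @param path TIFF file path.
#' @param scale intensity corresponding to the top of the 16-bit range.
#' @return `write_movie_tiff`: `path`, invisibly.  `read_movie_tiff`: a
#'   list of intensity matrices on the original scale.
#' @export
write_movie_tiff <- function(stack, path, scale = 4096) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  pages <- lapply(frames, function(m) pmin(m / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * scale)
}
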