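#' Segment nuclei in a background-subtracted frame
#'
#' Thresholds the frame at a single manually chosen intensity (the same
#' threshold is meant to be used for all wells and time points of an
#' experiment), then splits touching nuclei by running the watershed
#' algorithm on the inverted Euclidean distance transform of the
#' supra-threshold mask.  For each resulting object the (unweighted)
#' centroid of its member pixels and its pixel area are recorded.
#'
#' Coordinates are 0-based with `x` along columns and `y` along rows;
#' centroids are sub-pixel.
#'
#' @param img background-subtracted intensity matrix.
#' @param threshold intensity threshold (> 0); pixels strictly above it
#'   form the mask.
#' @param tolerance,ext watershed parameters (minimum object-separating
#'   peak height and peak neighborhood radius, px); the defaults merge
#'   peaks closer than about 2 px.
#' @return data frame with one row per object: `object` (label), `x_px`,
#'   `y_px`, `area_px`.
#' @seealso [filter_by_area()], [estimate_background()]
#' @export
segment_frame <- function(img, threshold, tolerance = 1, ext = 1) {
  stopifnot(is.matrix(img), is.finite(threshold), threshold > 0)
  mask <- img > threshold
  empty <- data.frame(object = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0))
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(img), ncol(img)))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                               ext = ext))
  pix <- which(lab > 0, arr.ind = TRUE)
  id <- lab[pix]
  area <- as.integer(tabulate(id))
  keep <- area > 0
  # centroid = unweighted mean of member pixel coordinates, 0-based
  sx <- rowsum(as.numeric(pix[, 2] - 1), id)
  sy <- rowsum(as.numeric(pix[, 1] - 1), id)
  labels <- as.integer(rownames(sx))
  data.frame(
    object = labels,
    x_px = as.vector(sx) / area[labels],
    y_px = as.vector(sy) / area[labels],
    area_px = area[labels]
  )
}

#' Filter detected objects by area
#'
#' Retains objects with area strictly greater than `min_area` and at most
#' `max_area` pixels; objects of 5 px or fewer (~31 um^2 at 2.5 um/px) and
#' objects above 75 px (~470 um^2) are excluded as debris and clumps.
#'
#' @param objects data frame with an `area_px` column (e.g. from
#'   [segment_frame()]).
#' @param min_area exclusive lower bound, px.
#' @param max_area inclusive upper bound, px.
#' @return the filtered data frame.
#' @export
filter_by_area <- function(objects, min_area = 5, max_area = 75) {
  stopifnot("area_px" %in% names(objects))
  objects[objects$area_px > min_area & objects$area_px <= max_area, ,
          drop = FALSE]
}

#' Otsu threshold helper
#'
#' Convenience automatic threshold for synthetic data; the assay itself
#' uses a single manually selected threshold per experiment.
#'
#' @param img intensity matrix.
#' @param levels histogram resolution.
#' @return a single threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, levels = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                      levels = levels)
  rng[1] + th * diff(rng)
}

#' Detect nuclei in every frame of a movie
#'
#' Runs background estimation, subtraction, segmentation, and area
#' filtering on each frame of a stack and returns the combined detection
#' table used by the tracking stage.
#'
#' @param frames list of intensity matrices, or a `frame_stack` from
#'   [render_movie()].
#' @param threshold segmentation threshold (applied after background
#'   subtraction).
#' @param block_px,percentile background-estimation parameters.
#' @param min_area,max_area area filter bounds, px.
#' @return data frame `frame` (0-based), `x_px`, `y_px`, `area_px`.
#' @export
detect_movie <- function(frames, threshold, block_px = 32, percentile = 80,
                         min_area = 5, max_area = 75) {
  if (inherits(frames, "frame_stack")) frames <- frames$frames
  out <- lapply(seq_along(frames), function(f) {
    bg <- estimate_background(frames[[f]], block_px = block_px,
                              percentile = percentile)
    obj <- segment_frame(subtract_background(frames[[f]], bg), threshold)
    obj <- filter_by_area(obj, min_area = min_area, max_area = max_area)
    if (nrow(obj) > 0) obj$frame <- f - 1L
    obj
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out)) {
    return(data.frame(object = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0),
                      frame = integer(0)))
  }
  rownames(out) <- NULL
  out
}
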