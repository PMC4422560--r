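#' Mutual nearest-neighbor matching between consecutive frames
#'
#' A link from detection `a` in frame t to detection `b` in frame t+1 is
#' accepted if and only if `b` is `a`'s nearest neighbor in frame t+1 *and*
#' `a` is `b`'s nearest neighbor in frame t.  A detection with two
#' equidistant nearest neighbors is treated as ambiguous and gets no link.
#' Distances are computed in microns.
#'
#' @param objs_t,objs_t1 data frames of detections in frames t and t+1,
#'   with columns `x_px`, `y_px` (or `x_um`, `y_um`, which take
#'   precedence).
#' @param pixel_size um per pixel (used when only pixel coordinates are
#'   present).
#' @return data frame with one row per accepted link: `i` (row in
#'   `objs_t`), `j` (row in `objs_t1`), `dist_um`.
#' @export
match_frames <- function(objs_t, objs_t1, pixel_size = 2.5) {
  p_t <- det_um(objs_t, pixel_size)
  p_t1 <- det_um(objs_t1, pixel_size)
  empty <- data.frame(i = integer(0), j = integer(0), dist_um = numeric(0))
  n <- nrow(p_t)
  m <- nrow(p_t1)
  if (n == 0 || m == 0) return(empty)
  D <- outer(p_t$x, p_t1$x, `-`)^2 + outer(p_t$y, p_t1$y, `-`)^2
  rmin <- apply(D, 1, min)
  cmin <- apply(D, 2, min)
  fwd <- max.col(-D, ties.method = "first")        # nearest in t+1 per row
  fwd_amb <- rowSums(D == rmin) > 1L
  bwd <- max.col(-t(D), ties.method = "first")     # nearest in t per col
  bwd_amb <- colSums(D == matrix(cmin, n, m, byrow = TRUE)) > 1L
  i <- seq_len(n)
  ok <- !fwd_amb & !bwd_amb[fwd] & bwd[fwd] == i
  data.frame(i = i[ok], j = fwd[ok], dist_um = sqrt(rmin[ok]))
}

det_um <- function(objs, pixel_size) {
  if (!is.null(objs$x_um)) {
    data.frame(x = objs$x_um, y = objs$y_um)
  } else {
    data.frame(x = objs$x_px * pixel_size, y = objs$y_px * pixel_size)
  }
}

# nearest same-frame neighbor distance (um) for each detection; Inf for a
# lone detection
same_frame_nn <- function(objs, pixel_size) {
  p <- det_um(objs, pixel_size)
  n <- nrow(p)
  if (n <= 1) return(rep(Inf, n))
  D <- outer(p$x, p$x, `-`)^2 + outer(p$y, p$y, `-`)^2
  diag(D) <- Inf
  sqrt(apply(D, 1, min))
}

#' Remove crowded steps from a set of links
#'
#' A link is excluded when the linked cell's nearest same-frame neighbor
#' is within `d_thresh` in the prior frame *and* in the latter frame
#' (default 40 um = 16 px).  Crowding in only one of the two frames keeps
#' the step.  This guards against the occasional identity swaps that
#' mutual nearest-neighbor matching can make in dense fields.
#'
#' @param links data frame from [match_frames()].
#' @param objs_t,objs_t1 the detection tables the links refer to.
#' @param d_thresh crowding distance threshold, um.
#' @param pixel_size um per pixel.
#' @return `links` with crowded rows removed.
#' @export
crowding_filter <- function(links, objs_t, objs_t1, d_thresh = 40,
                            pixel_size = 2.5) {
  if (nrow(links) == 0) return(links)
  nn_t <- same_frame_nn(objs_t, pixel_size)
  nn_t1 <- same_frame_nn(objs_t1, pixel_size)
  crowded <- nn_t[links$i] <= d_thresh & nn_t1[links$j] <= d_thresh
  links[!crowded, , drop = FALSE]
}

#' Assemble trajectories from frame-to-frame links
#'
#' Chains accepted links into maximal trajectories: a missing or rejected
#' link terminates the current trajectory and the next detection of that
#' cell starts a new one.  Every detection belongs to exactly one
#' trajectory (possibly of length 1).
#'
#' @param detections data frame with columns `frame` (0-based), `x_px`,
#'   `y_px` (one well and channel at a time).
#' @param links list of link data frames, one per consecutive frame pair,
#'   named by the prior frame (as produced by [link_movie()] internally);
#'   each element has columns `i`, `j` indexing the detections of frames
#'   `t` and `t+1` *within* their frame subsets (ordered as in
#'   `detections`).
#' @return `detections` with an added `track_id` column.
#' @export
build_trajectories <- function(detections, links) {
  stopifnot(is.data.frame(detections), "frame" %in% names(detections))
  frames <- sort(unique(detections$frame))
  idx_by_frame <- lapply(frames, function(f) which(detections$frame == f))
  names(idx_by_frame) <- frames
  track_id <- rep(NA_integer_, nrow(detections))
  next_id <- 1L
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- idx_by_frame[[fi]]
    new <- which(is.na(track_id[rows]))
    if (length(new)) {
      track_id[rows[new]] <- seq.int(next_id, next_id + length(new) - 1L)
      next_id <- next_id + length(new)
    }
    lk <- links[[as.character(f)]]
    if (is.null(lk) || nrow(lk) == 0) next
    if (anyDuplicated(lk$i) || anyDuplicated(lk$j)) {
      stop("links are not a one-to-one matching at frame ", f)
    }
    if (fi == length(frames)) next
    rows1 <- idx_by_frame[[fi + 1L]]
    # a link only continues a trajectory across consecutive frames
    if (frames[fi + 1L] != f + 1L) next
    track_id[rows1[lk$j]] <- track_id[rows[lk$i]]
  }
  detections$track_id <- track_id
  detections
}

#' Link all frames of a detection table into trajectories
#'
#' Runs [match_frames()] and [crowding_filter()] on every consecutive
#' frame pair and assembles trajectories with [build_trajectories()].
#'
#' @param detections data frame from [detect_movie()] (columns `frame`,
#'   `x_px`, `y_px`).
#' @param pixel_size um per pixel.
#' @param d_thresh crowding threshold, um; `Inf` disables the crowding
#'   filter.
#' @param max_link optional maximum link displacement, um (`Inf`, the
#'   default, imposes none: the mutual nearest-neighbor rule is the only
#'   constraint).
#' @return `detections` with an added `track_id` column.
#' @export
link_movie <- function(detections, pixel_size = 2.5, d_thresh = 40,
                       max_link = Inf) {
  frames <- sort(unique(detections$frame))
  links <- list()
  for (f in frames) {
    if (!((f + 1L) %in% frames)) next
    objs_t <- detections[detections$frame == f, , drop = FALSE]
    objs_t1 <- detections[detections$frame == f + 1L, , drop = FALSE]
    lk <- match_frames(objs_t, objs_t1, pixel_size)
    if (is.finite(max_link)) {
      lk <- lk[lk$dist_um <= max_link, , drop = FALSE]
    }
    if (is.finite(d_thresh)) {
      lk <- crowding_filter(lk, objs_t, objs_t1, d_thresh, pixel_size)
    }
    links[[as.character(f)]] <- lk
  }
  build_trajectories(detections, links)
}

#' Remove nonmoving cells
#'
#' Drops every trajectory whose cell never moves more than `max_disp_px`
#' pixels from its initial location (strictly more is required to be
#' kept).  Such cells are typically dead or incompletely differentiated
#' and would otherwise contribute pure localization noise.
#'
#' @param traj data frame with `track_id`, `x_px`, `y_px`, `frame` columns
#'   (from [build_trajectories()] / [link_movie()]).
#' @param max_disp_px displacement threshold, px.
#' @return `traj` with nonmoving trajectories removed.
#' @export
filter_nonmoving <- function(traj, max_disp_px = 2) {
  stopifnot(all(c("track_id", "x_px", "y_px", "frame") %in% names(traj)))
  if (nrow(traj) == 0) return(traj)
  traj <- traj[order(traj$track_id, traj$frame), , drop = FALSE]
  keep_ids <- unlist(lapply(split(traj, traj$track_id), function(d) {
    disp <- sqrt((d$x_px - d$x_px[1])^2 + (d$y_px - d$y_px[1])^2)
    if (max(disp) > max_disp_px) d$track_id[1] else NULL
  }))
  out <- traj[traj$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Steps along tracked trajectories
#'
#' Converts a tracked detection table into per-step records (consecutive
#' frames within one trajectory) in microns, ready for [step_metrics()].
#'
#' @param traj data frame with `track_id`, `frame`, `x_px`, `y_px`.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames (scalar, or a vector of frame
#'   timestamps in s indexed by `frame + 1`).
#' @return data frame `track_id, frame_t, x0_um, y0_um, x1_um, y1_um,
#'   dt_s`.
#' @export
trajectory_steps <- function(traj, pixel_size = 2.5, frame_interval = 30) {
  traj <- traj[order(traj$track_id, traj$frame), , drop = FALSE]
  n <- nrow(traj)
  if (n < 2) {
    return(data.frame(track_id = integer(0), frame_t = integer(0),
                      x0_um = numeric(0), y0_um = numeric(0),
                      x1_um = numeric(0), y1_um = numeric(0),
                      dt_s = numeric(0)))
  }
  same <- traj$track_id[-1] == traj$track_id[-n] &
    traj$frame[-1] == traj$frame[-n] + 1L
  i0 <- which(c(same, FALSE))
  dt <- if (length(frame_interval) > 1) {
    frame_interval[traj$frame[i0] + 2L] - frame_interval[traj$frame[i0] + 1L]
  } else {
    rep(frame_interval, length(i0))
  }
  data.frame(
    track_id = traj$track_id[i0],
    frame_t = traj$frame[i0],
    x0_um = traj$x_px[i0] * pixel_size,
    y0_um = traj$y_px[i0] * pixel_size,
    x1_um = traj$x_px[i0 + 1L] * pixel_size,
    y1_um = traj$y_px[i0 + 1L] * pixel_size,
    dt_s = dt
  )
}
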