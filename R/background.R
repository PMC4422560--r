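#' Blockwise-percentile background estimation
#'
#' Estimates a smooth local background for one frame by computing the 80th
#' percentile pixel intensity in blocks of 32 x 32 px (80 x 80 um at
#' 2.5 um/px) and bilinearly interpolating between block centers.  The
#' percentile is robust to bright nuclei as long as they cover well under
#' 20% of a block.  Pixels beyond the outermost block centers take the
#' clamped (nearest-center) interpolant, so every interpolated value lies
#' within the range of the block values.
#'
#' @param img intensity matrix (rows x cols).
#' @param block_px block edge length, px.  Image dimensions need not be
#'   multiples of `block_px`; trailing partial blocks use their remaining
#'   pixels.
#' @param percentile percentile in `[0, 100]`.
#' @return an object of class `background_field`: list with `background`
#'   (full-resolution matrix), `block_values` (block grid),
#'   `row_centers`, `col_centers` (block-center coordinates, 1-based px),
#'   `block_px`, `percentile`.
#' @export
estimate_background <- function(img, block_px = 32, percentile = 80) {
  stopifnot(is.matrix(img), min(dim(img)) >= block_px, block_px >= 1,
            percentile >= 0, percentile <= 100)
  nr <- nrow(img)
  nc <- ncol(img)
  row_breaks <- seq(1L, nr + 1L, by = block_px)
  if (tail(row_breaks, 1) <= nr) row_breaks <- c(row_breaks, nr + 1L)
  col_breaks <- seq(1L, nc + 1L, by = block_px)
  if (tail(col_breaks, 1) <= nc) col_breaks <- c(col_breaks, nc + 1L)
  nbr <- length(row_breaks) - 1L
  nbc <- length(col_breaks) - 1L
  B <- matrix(NA_real_, nbr, nbc)
  row_centers <- numeric(nbr)
  col_centers <- numeric(nbc)
  for (i in seq_len(nbr)) {
    rows <- row_breaks[i]:(row_breaks[i + 1L] - 1L)
    row_centers[i] <- mean(rows)
    for (j in seq_len(nbc)) {
      cols <- col_breaks[j]:(col_breaks[j + 1L] - 1L)
      if (i == 1L) col_centers[j] <- mean(cols)
      B[i, j] <- quantile(img[rows, cols], percentile / 100, names = FALSE)
    }
  }
  Wr <- interp_weights(nr, row_centers)
  Wc <- interp_weights(nc, col_centers)
  background <- Wr %*% B %*% t(Wc)
  structure(
    list(background = background, block_values = B,
         row_centers = row_centers, col_centers = col_centers,
         block_px = block_px, percentile = percentile),
    class = "background_field"
  )
}

# n x length(centers) sparse-pattern weight matrix for 1-D linear
# interpolation anchored at `centers`, clamped beyond the outer centers
interp_weights <- function(n, centers) {
  nb <- length(centers)
  W <- matrix(0, n, nb)
  x <- seq_len(n)
  if (nb == 1L) {
    W[, 1] <- 1
    return(W)
  }
  idx <- findInterval(x, centers)
  lo <- idx == 0L
  hi <- idx >= nb
  mid <- !lo & !hi
  W[cbind(which(lo), 1L)] <- 1
  W[cbind(which(hi), nb)] <- 1
  if (any(mid)) {
    i <- idx[mid]
    t <- (x[mid] - centers[i]) / (centers[i + 1L] - centers[i])
    W[cbind(which(mid), i)] <- 1 - t
    W[cbind(which(mid), i + 1L)] <- t
  }
  W
}

#' Subtract an estimated background from a frame
#'
#' Elementwise `max(img - background, 0)`; negative residuals are clamped
#' to zero so that downstream thresholding stays one-sided.
#'
#' @param img intensity matrix.
#' @param bg a [estimate_background()] result, or a matrix of the same
#'   dimensions.
#' @return the background-subtracted matrix.
#' @export
subtract_background <- function(img, bg) {
  bgm <- if (inherits(bg, "background_field")) bg$background else bg
  stopifnot(is.matrix(img), all(dim(img) == dim(bgm)))
  pmax(img - bgm, 0)
}
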