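# Independent brute-force oracles and small fixture builders used across
# the test files.

# Small acquisition geometry so rendered movies stay fast in tests.
test_acq <- function(nr = 256, nc = 320, n_pre = 8, n_post = 17) {
  acquisition_params(image_shape = c(nr, nc), n_pre_frames = n_pre,
                     n_post_frames = n_post)
}

# Blockwise-percentile background, computed independently: per-block
# percentile via the explicit type-7 order-statistic formula on sorted
# pixels, then two passes of stats::approx (rule = 2 clamps at the outer
# centers) instead of the package's weight-matrix bilinear product.
bf_background <- function(img, block_px, percentile) {
  nr <- nrow(img)
  nc <- ncol(img)
  row_starts <- seq(1, nr, by = block_px)
  col_starts <- seq(1, nc, by = block_px)
  pctl <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p / 100 + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  B <- matrix(NA_real_, length(row_starts), length(col_starts))
  rcent <- numeric(length(row_starts))
  ccent <- numeric(length(col_starts))
  for (i in seq_along(row_starts)) {
    rows <- row_starts[i]:min(nr, row_starts[i] + block_px - 1)
    rcent[i] <- mean(rows)
    for (j in seq_along(col_starts)) {
      cols <- col_starts[j]:min(nc, col_starts[j] + block_px - 1)
      if (i == 1) ccent[j] <- mean(cols)
      B[i, j] <- pctl(as.vector(img[rows, cols]), percentile)
    }
  }
  along_rows <- sapply(seq_len(ncol(B)), function(j) {
    if (nrow(B) == 1) rep(B[1, j], nr)
    else approx(rcent, B[, j], xout = seq_len(nr), rule = 2)$y
  })
  t(sapply(seq_len(nr), function(r) {
    if (ncol(B) == 1) rep(along_rows[r, 1], nc)
    else approx(ccent, along_rows[r, ], xout = seq_len(nc), rule = 2)$y
  }))
}

# O(n^2) mutual nearest-neighbor matching with explicit tie rejection.
bf_mutual_nn <- function(p_t, p_t1) {
  n <- nrow(p_t)
  m <- nrow(p_t1)
  res <- list()
  for (a in seq_len(n)) {
    d_a <- sqrt((p_t1$x - p_t$x[a])^2 + (p_t1$y - p_t$y[a])^2)
    if (sum(d_a == min(d_a)) > 1) next
    b <- which.min(d_a)
    d_b <- sqrt((p_t$x - p_t1$x[b])^2 + (p_t$y - p_t1$y[b])^2)
    if (sum(d_b == min(d_b)) > 1) next
    if (which.min(d_b) == a) {
      res[[length(res) + 1]] <- c(i = a, j = b)
    }
  }
  if (length(res) == 0) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  as.data.frame(do.call(rbind, res))
}

# Step table with every step pointing exactly at (or away from) a center.
radial_steps <- function(n, r_range, step_len, center, frame_t = 20,
                         outward = FALSE, seed = 1) {
  set.seed(seed)
  r <- runif(n, r_range[1], r_range[2])
  phi <- runif(n, 0, 2 * pi)
  x0 <- center[1] + r * cos(phi)
  y0 <- center[2] + r * sin(phi)
  sgn <- if (outward) 1 else -1
  data.frame(
    track_id = seq_len(n), frame_t = frame_t,
    x0_um = x0, y0_um = y0,
    x1_um = x0 + sgn * step_len * cos(phi),
    y1_um = y0 + sgn * step_len * sin(phi),
    dt_s = 30
  )
}
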