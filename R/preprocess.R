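#' Flat- and dark-field correction
#'
#' Normalizes every frame as
#' `I_norm = (I - mean(darks)) / (mean(flats) - mean(darks))`, clipped below
#' at a small positive floor. Static detector structure shared by
#' projections and flats (e.g. per-column gain) divides out.
#'
#' @param stack A [simulate_scan()] hologram stack (or a compatible list
#'   with `frames`, `flats`, `darks`, `geometry`).
#' @param floor_value Lower clip for normalized intensities.
#' @return An object of class `normalized_stack`: `frames` (normalized),
#'   `geometry`, `correction_log`.
#' @export
flat_dark_correct <- function(stack, floor_value = 1e-6) {
  stopifnot(!is.null(stack$frames), !is.null(stack$flats), !is.null(stack$darks))
  if (dim(stack$flats)[3] < 1 || dim(stack$darks)[3] < 1)
    stop("need at least one flat and one dark frame", call. = FALSE)
  flat <- apply(stack$flats, c(1, 2), mean)
  dark <- apply(stack$darks, c(1, 2), mean)
  denom <- flat - dark
  if (any(denom <= floor_value * max(abs(denom), 1)))
    stop("flat and dark fields coincide somewhere: denominator below floor",
         call. = FALSE)
  frames <- stack$frames
  for (a in seq_len(dim(frames)[3]))
    frames[, , a] <- pmax((frames[, , a] - dark) / denom, floor_value)
  structure(list(frames = frames, geometry = stack$geometry,
                 correction_log = list(list(step = "flat_dark_correct",
                                            floor = floor_value))),
            class = "normalized_stack")
}

#' @export
print.normalized_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<normalized_stack> %d frames of %d x %d px, %d correction step(s)\n",
              d[3], d[1], d[2], length(x$correction_log)))
  invisible(x)
}

#' Repair hot pixels in a frame
#'
#' Flags pixels whose deviation from their 3x3-neighborhood median exceeds
#' `k_mad` times the global MAD of those deviations, and replaces each by
#' the mean of its valid (in-bounds, unflagged) 8-neighbors; if all
#' neighbors are flagged the neighborhood median is used instead.
#'
#' @param frame 2D matrix.
#' @param k_mad Threshold factor (> 0); default 10.
#' @return List with `frame` (repaired) and `n_repaired`.
#' @export
repair_hot_pixels <- function(frame, k_mad = 10) {
  if (k_mad <= 0) stop("`k_mad` must be positive", call. = FALSE)
  med <- cpp_median_filter(frame, 3L, 3L, 1L, 1L)
  dev <- frame - med
  s <- stats::mad(dev, center = 0)
  if (s == 0) return(list(frame = frame, n_repaired = 0L))
  bad <- which(abs(dev) > k_mad * s, arr.ind = TRUE)
  if (nrow(bad) == 0) return(list(frame = frame, n_repaired = 0L))
  bad_mask <- matrix(FALSE, nrow(frame), ncol(frame))
  bad_mask[bad] <- TRUE
  out <- frame
  ny <- nrow(frame); nx <- ncol(frame)
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1]; j <- bad[k, 2]
    ys <- max(1, i - 1):min(ny, i + 1)
    xs <- max(1, j - 1):min(nx, j + 1)
    nb <- frame[ys, xs]
    ok <- !bad_mask[ys, xs]
    ok[which(ys == i), which(xs == j)] <- FALSE
    out[i, j] <- if (any(ok)) mean(nb[ok]) else med[i, j]
  }
  list(frame = out, n_repaired = nrow(bad))
}

#' @rdname repair_hot_pixels
#' @param stack A `normalized_stack` (all frames repaired in place).
#' @export
repair_hot_pixels_stack <- function(stack, k_mad = 10) {
  n_tot <- 0L
  for (a in seq_len(dim(stack$frames)[3])) {
    r <- repair_hot_pixels(stack$frames[, , a], k_mad)
    stack$frames[, , a] <- r$frame
    n_tot <- n_tot + r$n_repaired
  }
  stack$correction_log <- c(stack$correction_log,
                            list(list(step = "repair_hot_pixels",
                                      k_mad = k_mad, n_repaired = n_tot)))
  stack
}

#' Estimate the rotation-axis offset
#'
#' Cross-correlates each projection at angle `theta` with the horizontally
#' mirrored projection at `theta + 180` degrees (nearest available angle):
#' for an axis offset of `s` pixels the correlation peaks at lag `2 s`.
#' The peak is located at sub-pixel resolution by a parabolic fit and the
#' median over available pairs is returned (signed, in pixels).
#'
#' @param stack A `normalized_stack` covering at least 180 degrees.
#' @param max_pairs Number of (theta, theta+180) pairs to average over.
#' @param tol_deg Largest admissible mismatch between `theta + 180` and the
#'   nearest recorded angle, in degrees.
#' @return Signed offset in pixels.
#' @export
find_rotation_axis <- function(stack, max_pairs = 8L, tol_deg = 1) {
  ang <- stack$geometry$angles
  if (max(ang) - min(ang) < 180)
    stop("stack must cover at least 180 degrees", call. = FALSE)
  pick <- unique(round(seq(1, length(ang) %/% 2, length.out = max_pairs)))
  offs <- c()
  for (i in pick) {
    target <- ang[i] + 180
    j <- which.min(abs(ang - target))
    if (abs(ang[j] - target) > tol_deg) next
    p1 <- stack$frames[, , i]
    p2 <- stack$frames[, , j][, rev(seq_len(ncol(stack$frames))), drop = FALSE]
    offs <- c(offs, xcorr_shift(p1, p2) / 2)
  }
  if (length(offs) == 0)
    stop("no opposing projection pairs within tolerance", call. = FALSE)
  stats::median(offs)
}

# horizontal shift (in pixels) maximizing the row-wise cross-correlation of
# two equally sized images, sub-pixel via parabolic interpolation of the
# correlation peak
xcorr_shift <- function(a, b) {
  a <- sweep(a, 1, rowMeans(a))
  b <- sweep(b, 1, rowMeans(b))
  nx <- ncol(a)
  A <- t(apply(a, 1, stats::fft))
  B <- t(apply(b, 1, stats::fft))
  cc <- colSums(Re(t(apply(A * Conj(B), 1, function(r) stats::fft(r, inverse = TRUE)))))
  lags <- fft_freqs(nx) * nx
  k <- which.max(cc)
  km <- if (k == 1) nx else k - 1
  kp <- if (k == nx) 1 else k + 1
  y1 <- cc[km]; y2 <- cc[k]; y3 <- cc[kp]
  denom <- y1 - 2 * y2 + y3
  frac <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  lags[k] + frac
}

#' Shift all frames to center the rotation axis
#'
#' Resamples every frame horizontally by `-offset` pixels (linear
#' interpolation, edge value continuation) so that the rotation axis falls
#' on the detector center column.
#'
#' @param stack A `normalized_stack`.
#' @param offset Signed axis offset in pixels, from [find_rotation_axis()].
#' @return The shifted stack with an appended correction-log entry.
#' @export
apply_axis_shift <- function(stack, offset) {
  if (abs(offset) < 1e-9) return(stack)
  nx <- dim(stack$frames)[2]
  x_out <- seq_len(nx) + offset
  x0 <- pmin(pmax(floor(x_out), 1), nx)
  x1 <- pmin(x0 + 1, nx)
  f <- pmin(pmax(x_out - x0, 0), 1)
  for (a in seq_len(dim(stack$frames)[3])) {
    fr <- stack$frames[, , a]
    stack$frames[, , a] <- fr[, x0] * rep(1 - f, each = nrow(fr)) +
      fr[, x1] * rep(f, each = nrow(fr))
  }
  stack$correction_log <- c(stack$correction_log,
                            list(list(step = "apply_axis_shift",
                                      offset = offset)))
  stack
}
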