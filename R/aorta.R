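#' Canny edge detection on one slice
#'
#' Sobel gradients, non-maximum suppression along the quantised gradient
#' direction, then hysteresis thresholding: weak edge pixels survive only
#' in 8-connected components that contain at least one strong pixel.
#'
#' @param slice 2D numeric matrix.
#' @param low,high hysteresis thresholds on the gradient magnitude
#'   (8-bit scale defaults 50 and 150).
#' @return logical edge matrix.
#' @export
canny_edges <- function(slice, low = 50, high = 150) {
  img <- as.matrix(slice)
  nr <- nrow(img); nc <- ncol(img)
  pad <- function(m) m[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  p <- pad(img)
  ix <- function(di, dj) p[(1:nr) + 1 + di, (1:nc) + 1 + dj]
  # Sobel (x = row direction)
  gx <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  gy <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)          # in (-pi, pi]
  # quantise to 4 directions: 0 = row, 1 = diag(+,+), 2 = col, 3 = diag(+,-)
  sector <- floor(((ang + pi) / (pi / 4)) %% 8 + 0.5) %% 4
  pm <- mag[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  mx <- function(di, dj) pm[(1:nr) + 1 + di, (1:nc) + 1 + dj]
  keep <- matrix(FALSE, nr, nc)
  n1 <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  for (s in 0:3) {
    d <- n1[[s + 1]]
    sel <- sector == s
    keep[sel] <- mag[sel] >= mx(d[1], d[2])[sel] &
                 mag[sel] >= mx(-d[1], -d[2])[sel]
  }
  weak <- keep & mag > low
  strong <- keep & mag > high
  if (!any(strong)) return(strong)
  lab <- cpp_label2d(weak)
  good <- unique(lab[strong])
  weak & (lab %in% good[good > 0])
}

#' Detect the ascending aorta as a spatial reference point
#'
#' Circular Hough transform on superior slices: edges from the Canny
#' detector vote, per candidate radius, through an annulus matched filter
#' (FFT correlation); the best-supported circle in the 25-60 px radius
#' range is accepted per slice (one circle per slice -- the radius range is
#' chosen so only the aorta matches near the heart) and the arithmetic mean
#' of the per-slice centres is the reference point used for coronary
#' cluster identification.
#'
#' @param vol an [image_volume()] (at least `max(slice_range)` slices).
#' @param slice_range slice indices to search (default 5th-9th slice).
#' @param r_min,r_max circle radius bounds in px.
#' @param canny hysteresis thresholds for the edge detector.
#' @param min_support minimum fraction of the circle perimeter that must be
#'   covered by edge votes for a detection to be accepted.
#' @return an object of class `reference_point` with fields `center`
#'   (row, col), `radius` (px), `slice_range`, `per_slice`.
#' @export
detect_aorta_center <- function(vol, slice_range = 5:9, r_min = 25, r_max = 60,
                                canny = c(50, 150), min_support = 0.3) {
  stopifnot(inherits(vol, "image_volume"), r_min < r_max)
  d <- dim(vol$voxels)
  if (d[3] < max(slice_range))
    stop(sprintf("volume has %d slices; slice range needs %d", d[3],
                 max(slice_range)))
  hits <- list()
  for (k in slice_range) {
    e <- canny_edges(vol$voxels[, , k], canny[1], canny[2])
    h <- hough_best_circle(e, r_min, r_max, min_support)
    if (!is.null(h)) hits[[length(hits) + 1L]] <- c(h, slice = k)
  }
  if (!length(hits))
    stop("aorta not detected: no circle with radius in [", r_min, ", ", r_max,
         "] px found in slices ", min(slice_range), "-", max(slice_range))
  m <- do.call(rbind, hits)
  structure(list(center = c(row = mean(m[, "row"]), col = mean(m[, "col"])),
                 radius = mean(m[, "r"]),
                 slice_range = slice_range,
                 slices_used = m[, "slice"],
                 per_slice = m),
            class = "reference_point")
}

#' @export
print.reference_point <- function(x, ...) {
  cat(sprintf("<reference_point> aorta centre (row %.1f, col %.1f), radius %.1f px, slices %s\n",
              x$center["row"], x$center["col"], x$radius,
              paste(range(x$slice_range), collapse = "-")))
  invisible(x)
}

# Best circle (row, col, r, support) by annulus matched filtering of the
# edge image over integer radii; votes are normalised by the perimeter so
# radii compete fairly.  Returns NULL when no circle reaches min_support.
hough_best_circle <- function(edges, r_min, r_max, min_support = 0.3) {
  nr <- nrow(edges); nc <- ncol(edges)
  if (!any(edges)) return(NULL)
  fe <- stats::fft(matrix(as.numeric(edges), nr, nc))
  best <- NULL
  for (r in seq(ceiling(r_min), floor(r_max))) {
    th <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * r * 2)))
    di <- round(r * cos(th)); dj <- round(r * sin(th))
    ring <- unique(cbind(di, dj))
    kern <- matrix(0, nr, nc)
    kern[cbind((ring[, 1] %% nr) + 1, (ring[, 2] %% nc) + 1)] <- 1
    acc <- Re(stats::fft(fe * stats::fft(kern), inverse = TRUE)) / (nr * nc)
    support <- max(acc) / nrow(ring)
    if (support >= min_support && (is.null(best) || support > best["support"])) {
      w <- which.max(acc)
      best <- c(row = ((w - 1) %% nr) + 1, col = ((w - 1) %/% nr) + 1,
                r = r, support = support)
    }
  }
  best
}
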