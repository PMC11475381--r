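#' CT image volume
#'
#' A 3D scalar voxel grid with anisotropic spacing, the container handed
#' between all imaging stages.  Intensities are grey values in \[0, 255\]
#' after windowing (see [normalize_volume()]); world coordinates of voxel
#' `(i, j, k)` (1-based) are `origin + (c(i, j, k) - 1) * spacing` in mm.
#'
#' @param voxels 3D numeric array of grey intensities.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-dimensional array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  if (any(!is.finite(voxels)))
    stop("voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$voxels), max(x$voxels), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Binary candidate-voxel volume
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing in mm (inherited from the source volume).
#' @param origin world coordinate of voxel (1,1,1) in mm.
#' @param threshold_used the grey-intensity threshold that produced the mask.
#' @return an object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          threshold_used = NA_real_) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("mask must be a 3-dimensional array")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 threshold_used = threshold_used),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d, %d foreground voxels (threshold %s)\n",
              d[1], d[2], d[3], sum(x$mask),
              format(x$threshold_used)))
  invisible(x)
}

#' Crop a volume to the cardiac region
#'
#' Applies a fixed fractional bounding box, the deterministic stand-in for
#' the automatic cardiac-region crop; the default keeps the central 60%
#' in-plane and all slices.  The origin is updated so world coordinates of
#' retained voxels are unchanged.
#'
#' @param vol an [image_volume()].
#' @param crop_spec 2 x 3 matrix of `(min, max)` fractions per axis in
#'   \[0, 1\].
#' @return the cropped [image_volume()].
#' @export
crop_cardiac_region <- function(vol,
                                crop_spec = rbind(c(0.2, 0.2, 0),
                                                  c(0.8, 0.8, 1))) {
  stopifnot(inherits(vol, "image_volume"))
  crop_spec <- as.matrix(crop_spec)
  if (!all(dim(crop_spec) == c(2, 3)))
    stop("crop_spec must be a 2 x 3 matrix of (min, max) fractions")
  if (any(crop_spec < 0) || any(crop_spec > 1))
    stop("crop fractions must lie in [0, 1]")
  d <- dim(vol$voxels)
  idx <- vector("list", 3)
  axis_names <- c("x", "y", "z")
  for (a in 1:3) {
    lo <- crop_spec[1, a]; hi <- crop_spec[2, a]
    if (lo >= hi)
      stop(sprintf("crop produces empty volume on axis %s (min %.2f >= max %.2f)",
                   axis_names[a], lo, hi))
    i0 <- floor(lo * d[a]) + 1L
    i1 <- ceiling(hi * d[a])
    if (i1 < i0)
      stop(sprintf("crop produces empty volume on axis %s", axis_names[a]))
    idx[[a]] <- i0:i1
  }
  vox <- vol$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  new_origin <- vol$origin +
    (c(idx[[1]][1], idx[[2]][1], idx[[3]][1]) - 1) * vol$spacing
  image_volume(vox, vol$spacing, new_origin)
}

#' Window/level normalisation to 8-bit grey
#'
#' Linearly maps the window `c(lo, hi)` onto \[0, 255\], clipping outside.
#' All grey-intensity thresholds in the segmentation stage (125-145) are in
#' this 8-bit vocabulary, so raw Hounsfield-unit volumes must be windowed
#' before filtering.  The default window is the identity for data already
#' in \[0, 255\].
#'
#' @param vol an [image_volume()].
#' @param window numeric length-2 `c(lo, hi)` intensity window.
#' @return the windowed [image_volume()].
#' @export
normalize_volume <- function(vol, window = c(0, 255)) {
  stopifnot(inherits(vol, "image_volume"), length(window) == 2,
            window[2] > window[1])
  v <- (vol$voxels - window[1]) / (window[2] - window[1]) * 255
  v[v < 0] <- 0
  v[v > 255] <- 255
  image_volume(v, vol$spacing, vol$origin)
}

#' World coordinates of voxel indices
#'
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @param spacing,origin volume geometry in mm.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(idx, spacing, origin = c(0, 0, 0)) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}
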