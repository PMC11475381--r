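#' Digital stenosed-tube CT phantom
#'
#' A straight tube of known radius profile embedded in a noisy background,
#' the ground-truth fixture for the geometry stages.  The tube runs along
#' the third (slice) axis through the volume centre; its radius profile is
#' uniform `r0_vox` with an optional cosine-tapered stenosis of given
#' diameter-reduction severity centred mid-tube.  Voxels whose centre lies
#' within `r(z)` of the axis get `tube_intensity`; optional additive
#' Gaussian noise (SD `noise_sigma`) is clipped to \[0, 255\].
#'
#' @param shape volume dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param r0_vox tube reference radius in voxels (>= 2).
#' @param severity fractional diameter reduction of the stenosis in
#'   \[0, 1); 0 gives a uniform tube.
#' @param stenosis_length axial extent of the cosine taper, voxels.
#' @param tube_intensity,background_intensity grey levels.  The defaults
#'   place the lumen at the top of the 125-145 thresholdable band over a
#'   dark epicardial-fat-like background, as in a windowed CCTA.
#' @param partial_volume render coverage-weighted boundary voxels
#'   (CT-like partial-volume edges) instead of hard binary edges.
#' @param noise_sigma Gaussian noise SD (0 = noise free).
#' @param margin empty slices at both tube ends.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list with `vol` ([image_volume()]), `truth` ([binary_volume()]),
#'   `axis` (n x 3 world mm), `true_radius_mm` per axis point, `meta`.
#' @export
make_tube_phantom <- function(shape = c(48, 48, 110), spacing = c(1, 1, 1),
                              r0_vox = 4, severity = 0, stenosis_length = 30,
                              tube_intensity = 145, background_intensity = 30,
                              partial_volume = FALSE,
                              noise_sigma = 0, margin = 5, seed = 1) {
  stopifnot(r0_vox >= 2, severity >= 0, severity < 1)
  if (2 * margin + 2 >= shape[3]) stop("zero-length axis: volume too short")
  # axis on a voxel centre: digital tubes with even (half-integer)
  # symmetry are degenerate for medial-axis thinning (no unique middle
  # voxel), which real masks never exhibit
  cx <- (shape[1] + 1) %/% 2
  cy <- (shape[2] + 1) %/% 2
  kz <- (margin + 1):(shape[3] - margin)
  zc <- (shape[3] + 1) %/% 2    # throat on a voxel centre (grid-aligned truth)
  r_of_k <- function(k) {
    r <- rep(r0_vox, length(k))
    if (severity > 0) {
      d <- abs(k - zc)
      inside <- d <= stenosis_length / 2
      r[inside] <- r0_vox * (1 - severity / 2 *
                               (1 + cos(2 * pi * d[inside] / stenosis_length)))
    }
    r
  }
  if (max(r_of_k(kz)) + max(cx, cy) > max(shape[1:2]))
    stop("tube exits volume")
  vol <- array(background_intensity, shape)
  truth <- array(FALSE, shape)
  ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
  jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d2 <- (ii - cx)^2 + (jj - cy)^2
  rk <- r_of_k(kz)
  dd <- sqrt(d2)
  for (a in seq_along(kz)) {
    m <- d2 <= rk[a]^2
    sl <- vol[, , kz[a]]
    if (partial_volume) {
      # in-plane voxel coverage of the disc, approximated by the clamped
      # signed distance to the circle (CT-like partial-volume edge)
      cov <- pmin(pmax(rk[a] - dd + 0.5, 0), 1)
      sl <- background_intensity + (tube_intensity - background_intensity) * cov
    } else {
      sl[m] <- tube_intensity
    }
    vol[, , kz[a]] <- sl
    truth[, , kz[a]] <- m
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sigma), shape)
    vol[vol < 0] <- 0; vol[vol > 255] <- 255
  }
  axis <- cbind((cx - 1) * spacing[1], (cy - 1) * spacing[2],
                (kz - 1) * spacing[3])
  list(vol = image_volume(vol, spacing),
       truth = binary_volume(truth, spacing),
       axis = axis,
       true_radius_mm = rk * spacing[1],
       meta = list(r0_vox = r0_vox, severity = severity,
                   min_radius_mm = min(rk) * spacing[1],
                   min_radius_z = zc, slices = kz, seed = seed))
}

# rasterise a tube along a polyline axis (voxel coords, radius in voxels
# in-plane; the k component is scaled by dz/dx so the radius is isotropic
# in mm).  Returns updated (vol, mask).
rasterize_tube <- function(vol, mask, axis_vox, radius_vox, intensity,
                           zscale) {
  d <- dim(vol)
  # sample the axis densely
  seg <- diff(axis_vox)
  lens <- sqrt(rowSums(seg^2))
  npts <- pmax(2, ceiling(lens / 0.25))
  pts <- do.call(rbind, lapply(seq_len(nrow(seg)), function(s) {
    tt <- seq(0, 1, length.out = npts[s])
    cbind(axis_vox[s, 1] + tt * seg[s, 1],
          axis_vox[s, 2] + tt * seg[s, 2],
          axis_vox[s, 3] + tt * seg[s, 3],
          radius_vox[s] + tt * (radius_vox[s + 1] - radius_vox[s]))
  }))
  for (p in seq_len(nrow(pts))) {
    r <- pts[p, 4]
    rz <- r / zscale
    i0 <- max(1, floor(pts[p, 1] - r)); i1 <- min(d[1], ceiling(pts[p, 1] + r))
    j0 <- max(1, floor(pts[p, 2] - r)); j1 <- min(d[2], ceiling(pts[p, 2] + r))
    k0 <- max(1, floor(pts[p, 3] - rz)); k1 <- min(d[3], ceiling(pts[p, 3] + rz))
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    for (k in k0:k1) {
      dz2 <- ((k - pts[p, 3]) * zscale)^2
      if (dz2 > r^2) next
      ir <- i0:i1; jr <- j0:j1
      di2 <- (ir - pts[p, 1])^2
      dj2 <- (jr - pts[p, 2])^2
      m <- outer(di2, dj2, `+`) + dz2 <= r^2
      if (!any(m)) next
      blk <- vol[ir, jr, k]
      blk[m] <- intensity
      vol[ir, jr, k] <- blk
      mb <- mask[ir, jr, k]
      mb[m] <- TRUE
      mask[ir, jr, k] <- mb
    }
  }
  list(vol = vol, mask = mask)
}

#' Digital coronary CT phantom with known labels
#'
#' Emulates the anatomy the segmentation stage relies on: a bright aorta
#' cylinder spanning all slices (detectable by the circular Hough transform
#' on the superior slices), two coronary-like tube trees sprouting from
#' points adjacent to the aorta wall (the left tree bifurcates), and one
#' distant decoy vessel of similar calibre standing in for a pulmonary
#' branch.  Tube intensities sit in the 125-145 thresholdable band and may
#' taper distally; additive Gaussian noise is clipped to \[0, 255\].
#'
#' @param shape volume dimensions (default 256 x 256 x 48).
#' @param spacing voxel spacing in mm (default 0.458 x 0.458 x 0.625).
#' @param aorta_center aorta (row, col) in px.
#' @param aorta_radius aorta radius in px (must lie in \[25, 60\]);
#'   set to `NA` to omit the aorta.
#' @param aorta_intensity,background_intensity grey levels.
#' @param tube_radius_vox coronary tube radius in in-plane voxels.
#' @param proximal_intensity,distal_intensity coronary grey levels at the
#'   ostium and at the distal end (linear taper).
#' @param noise_sigma Gaussian noise SD.
#' @param mirror flip the phantom left-right (label symmetry checks).
#' @param seed RNG seed.
#' @return list with `vol`, `labels` (0 background, 1 aorta, 2 left tree,
#'   3 right tree, 4 decoy), `truth` (coronary mask = labels 2 | 3), and
#'   `meta`.
#' @export
make_coronary_phantom <- function(shape = c(256, 256, 48),
                                  spacing = c(0.458, 0.458, 0.625),
                                  aorta_center = c(110, 128),
                                  aorta_radius = 40,
                                  aorta_intensity = 200,
                                  background_intensity = 30,
                                  tube_radius_vox = 3.5,
                                  proximal_intensity = 145,
                                  distal_intensity = 128,
                                  noise_sigma = 10, mirror = FALSE,
                                  seed = 1) {
  if (!is.na(aorta_radius) && (aorta_radius < 25 || aorta_radius > 60))
    stop("aorta radius must lie within the detectable 25-60 px range")
  vol <- array(background_intensity, shape)
  labels <- array(0L, shape)
  zscale <- spacing[3] / spacing[1]

  if (!is.na(aorta_radius)) {
    ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
    jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    disc <- (ii - aorta_center[1])^2 + (jj - aorta_center[2])^2 <= aorta_radius^2
    for (k in seq_len(shape[3])) {
      sl <- vol[, , k]; sl[disc] <- aorta_intensity; vol[, , k] <- sl
      lb <- labels[, , k]; lb[disc] <- 1L; labels[, , k] <- lb
    }
  }

  # helix-like coronary courses: start at the aorta wall around slice 12,
  # drift in-plane while descending so slices see elongated cross-sections
  make_course <- function(theta0, dtheta, rad_wall, k0, k1, drift) {
    kk <- seq(k0, k1, by = 1)
    tt <- seq(0, 1, length.out = length(kk))
    th <- theta0 + dtheta * tt
    rr <- rad_wall + drift * tt
    cbind(aorta_center[1] + rr * sin(th),
          aorta_center[2] + rr * cos(th),
          kk)
  }
  wall <- if (is.na(aorta_radius)) 40 else aorta_radius + tube_radius_vox + 1
  # left coronary tree (bifurcating) exits toward image right (higher
  # columns); right coronary toward image left -- the radiological axial view
  left_main <- make_course(pi / 2 - 0.15, -0.9, wall, 12, 34, 55)
  left_branch_start <- 12
  lad <- left_main[seq_len(left_branch_start), ]
  # two daughters after the short main stem
  n_rest <- nrow(left_main) - left_branch_start + 1
  d1 <- left_main[left_branch_start:nrow(left_main), ]
  t2 <- seq(0, 1, length.out = n_rest)
  d2 <- cbind(d1[1, 1] + (d1[, 1] - d1[1, 1]) * 0.4 + 40 * t2,
              d1[1, 2] + (d1[, 2] - d1[1, 2]) * 0.7 + 25 * t2,
              d1[, 3])
  right <- make_course(-pi / 2 - 0.2, -0.8, wall, 12, 40, 60)
  decoy_col <- if (mirror) shape[2] - 30 else 30
  decoy <- cbind(seq(30, 200, length.out = 25), decoy_col, seq(8, 40,
                                                               length.out = 25))

  paint <- function(axis, label, taper = TRUE) {
    n <- nrow(axis)
    inten <- if (taper)
      seq(proximal_intensity, distal_intensity, length.out = n)
    else rep(proximal_intensity, n)
    mask <- array(FALSE, shape)
    for (s in seq_len(n - 1)) {
      res <- rasterize_tube(vol, mask, axis[s:(s + 1), , drop = FALSE],
                            rep(tube_radius_vox, 2),
                            (inten[s] + inten[s + 1]) / 2, zscale)
      vol <<- res$vol
      mask <- res$mask
    }
    prev <- labels[mask]
    if (any(prev > 1L & prev != label))
      stop("geometry collision between phantom vessels")
    labels[mask & labels == 0L] <<- label
    mask
  }
  paint(lad, 2L)
  paint(d1, 2L)
  paint(d2, 2L)
  paint(right, 3L)
  paint(decoy, 4L, taper = FALSE)

  if (mirror) {
    vol <- vol[, rev(seq_len(shape[2])), , drop = FALSE]
    labels <- labels[, rev(seq_len(shape[2])), , drop = FALSE]
    tmp <- labels == 2L
    labels[labels == 3L] <- 2L
    labels[tmp] <- 3L
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sigma), shape)
    vol[vol < 0] <- 0; vol[vol > 255] <- 255
  }
  list(vol = image_volume(vol, spacing),
       labels = labels,
       truth = binary_volume(labels == 2L | labels == 3L, spacing),
       meta = list(aorta_center = if (mirror)
         c(aorta_center[1], shape[2] + 1 - aorta_center[2]) else aorta_center,
         aorta_radius = aorta_radius, tube_radius_vox = tube_radius_vox,
         noise_sigma = noise_sigma, seed = seed))
}

#' Parametric stenosed 1D mesh
#'
#' Builds a single-vessel [mesh1d()] with a smooth cosine-tapered stenosis:
#' the radius drops from `r0` to `r0 * (1 - severity)` at the throat and
#' recovers, over an axial extent `stenosis_length` centred at
#' `stenosis_center`.  The area ratio at the throat is `(1 - severity)^2`.
#'
#' @param r0 reference radius in cm.
#' @param severity fractional diameter reduction in \[0, 1).
#' @param length total vessel length in cm.
#' @param stenosis_length axial extent of the taper in cm.
#' @param stenosis_center throat position in cm (default mid-vessel).
#' @param spacing node spacing in cm.
#' @return list with `mesh` ([mesh1d()]), `min_radius` (cm), `throat_x`.
#' @export
make_stenosed_mesh1d <- function(r0 = 0.15, severity = 0, length = 10,
                                 stenosis_length = 2,
                                 stenosis_center = length / 2,
                                 spacing = 0.01) {
  if (severity < 0 || severity >= 1)
    stop("severity must lie in [0, 1)")
  n <- as.integer(round(length / spacing)) + 1L
  x <- seq(0, length, length.out = n)
  r <- rep(r0, n)
  d <- abs(x - stenosis_center)
  inside <- d <= stenosis_length / 2
  r[inside] <- r0 * (1 - severity / 2 *
                       (1 + cos(2 * pi * d[inside] / stenosis_length)))
  mesh <- mesh1d(list(list(x = x, r0 = r, parent = 0L, id = "tube")),
                 spacing = spacing)
  list(mesh = mesh, min_radius = r0 * (1 - severity),
       throat_x = stenosis_center)
}
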