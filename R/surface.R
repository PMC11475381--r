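#' Lumen surface mesh by iso-surfacing
#'
#' Extracts a triangulated iso-surface of the binary lumen volume in world
#' (mm) coordinates.  The binary volume is first smoothed with a small
#' Gaussian (in voxel units) so the 0.5 iso-surface tracks the true lumen
#' boundary instead of the voxel staircase; the triangulation marches
#' tetrahedra on the Kuhn cube decomposition, which is watertight across
#' cube faces.
#'
#' @param mask a [binary_volume()].
#' @param smooth_sigma Gaussian pre-smoothing SD in voxels (0 disables).
#' @return an object of class `surface_mesh`: list with `vertices` (n x 3
#'   mm), `faces` (m x 3 vertex indices), `area` (mm^2).
#' @export
extract_surface <- function(mask, smooth_sigma = 0.8) {
  stopifnot(inherits(mask, "binary_volume"))
  arr <- mask$mask
  if (!any(arr)) stop("cannot extract a surface from an empty mask")
  d <- dim(arr)
  # pad by one voxel so components touching the border still close
  vol <- array(0, d + 2L)
  vol[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(arr)
  if (smooth_sigma > 0)
    vol <- cpp_smooth3d(vol, dim(vol), rep(smooth_sigma, 3))
  res <- cpp_march_tets(vol, dim(vol), mask$spacing,
                        mask$origin - mask$spacing, 0.5)
  v <- res$vertices
  f <- res$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  structure(list(vertices = v, faces = f, area = area),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), x$area))
  invisible(x)
}

#' Estimate lumen radii along the centreline
#'
#' The radius at each centreline point is the shortest normal distance
#' from that point to the lumen surface vertices: the minimum Euclidean
#' distance over vertices lying within a one-voxel slab around the plane
#' normal to the local centreline tangent (so end caps and side branches
#' lying along the axis do not contaminate the estimate; when the slab
#' holds no vertex the unrestricted minimum is used).  Circular
#' cross-sections are assumed downstream, so this single scalar per point
#' defines the 1D lumen; the estimate is known to dip at bifurcations
#' where the nearest wall belongs to the sibling branch.  Points with zero
#' radius (on a vertex) or outside the surface bounding box are dropped
#' with a warning.
#'
#' @param tree a `centerline_tree` from [split_branches()].
#' @param surface a `surface_mesh` from [extract_surface()].
#' @param slab axial half-width (mm) of the normal-plane slab.
#' @return the tree with per-point `radius` (mm) filled in (degenerate
#'   points removed).
#' @export
estimate_radii <- function(tree, surface, slab = NULL) {
  stopifnot(inherits(tree, "centerline_tree"),
            inherits(surface, "surface_mesh"))
  v <- surface$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  for (i in seq_along(tree$branches)) {
    b <- tree$branches[[i]]
    pts <- b$points
    inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
              pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
              pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    if (!all(inside)) {
      warning(sprintf("branch %d: %d centreline point(s) outside surface bounding box dropped",
                      i, sum(!inside)))
      b$voxels <- b$voxels[inside, , drop = FALSE]
      b$points <- pts[inside, , drop = FALSE]
      pts <- b$points
    }
    if (nrow(pts) == 0) { b$radius <- numeric(0); tree$branches[[i]] <- b; next }
    if (is.null(slab)) slab <- max(tree$spacing)
    if (nrow(pts) >= 2) {
      tn <- rbind(pts[2, ] - pts[1, ],
                  (pts[pmin(seq_len(nrow(pts)) + 1, nrow(pts)), , drop = FALSE] -
                   pts[pmax(seq_len(nrow(pts)) - 1, 1), , drop = FALSE])[
                     -c(1, nrow(pts)), , drop = FALSE],
                  pts[nrow(pts), ] - pts[nrow(pts) - 1, ])
      tn <- tn / pmax(sqrt(rowSums(tn^2)), 1e-12)
      r <- cpp_min_dist_normal(pts, tn, v, slab)
    } else {
      r <- cpp_min_dist(pts, v)
    }
    zero <- r <= 0
    if (any(zero)) {
      warning(sprintf("branch %d: %d centreline point(s) with zero radius dropped",
                      i, sum(zero)))
      b$voxels <- b$voxels[!zero, , drop = FALSE]
      b$points <- b$points[!zero, , drop = FALSE]
      r <- r[!zero]
    }
    b$radius <- r
    tree$branches[[i]] <- b
  }
  tree
}
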