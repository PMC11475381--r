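#' DBSCAN settings for coronary voxel clustering
#'
#' The defaults group voxel centres within a search radius of 1.6 voxels
#' with at least 2 points (the point itself included) in the search area,
#' which clusters contiguous lumen voxels while isolated voxels become
#' noise.  Distances are Euclidean in voxel-index space.
#'
#' @param eps search radius in voxels.
#' @param min_pts minimum points within the search radius (self included).
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(eps = 1.6, min_pts = 2) {
  stopifnot(eps > 0, min_pts >= 1)
  structure(list(eps = eps, min_pts = as.integer(min_pts)),
            class = "cluster_params")
}

#' Density-based clustering of candidate voxels (DBSCAN)
#'
#' Voxel centres are the spatial points.  Core points have at least
#' `min_pts` points in their eps-neighbourhood; clusters are the sets of
#' core points density-reachable from each other plus the border points
#' they reach.  Border points reachable from two clusters are assigned to
#' the cluster discovered first in lexicographic voxel scan order, which
#' makes the partition deterministic.
#'
#' @param mask a [binary_volume()] (or 3D logical array).
#' @param params a [cluster_params()].
#' @return list with `clusters` (each a list of `voxel_indices` (n x 3,
#'   1-based), `label`, `core` flags, `size`) and `noise` (m x 3 matrix).
#' @export
cluster_voxels <- function(mask, params = cluster_params()) {
  arr <- if (inherits(mask, "binary_volume")) mask$mask else mask
  idx <- which(arr, arr.ind = TRUE)
  colnames(idx) <- NULL
  if (nrow(idx) == 0)
    return(list(clusters = list(), noise = idx))
  res <- cpp_dbscan_grid(idx, dim(arr), params$eps, params$min_pts)
  labs <- res$labels
  clusters <- lapply(sort(unique(labs[labs > 0])), function(l) {
    sel <- labs == l
    list(voxel_indices = idx[sel, , drop = FALSE], label = l,
         core = res$core[sel], size = sum(sel))
  })
  list(clusters = clusters, noise = idx[labs == 0, , drop = FALSE])
}

#' Identify the two coronary clusters
#'
#' Among all clusters the two whose minimum point-to-reference distance is
#' smallest are the coronary arteries; proximity to the aortic centre
#' excludes look-alike pulmonary vessels.  The cluster lying at lower image
#' columns (image left) is labelled the right coronary artery and vice
#' versa, matching the radiological axial view.
#'
#' @param clusters list of clusters from [cluster_voxels()].
#' @param ref a `reference_point` from [detect_aorta_center()].
#' @return list with `left` and `right` clusters (each augmented with
#'   `ref_distance`).
#' @export
select_coronary_clusters <- function(clusters, ref) {
  if (is.list(clusters) && !is.null(clusters$clusters))
    clusters <- clusters$clusters
  if (length(clusters) < 2)
    stop("coronary pair not found: need at least 2 clusters, got ",
         length(clusters))
  refpt <- c(ref$center["row"], ref$center["col"], mean(ref$slices_used))
  dmin <- vapply(clusters, function(cl) {
    di <- sweep(cl$voxel_indices, 2, refpt)
    sqrt(min(rowSums(di^2)))
  }, numeric(1))
  ord <- order(dmin)
  pick <- clusters[ord[1:2]]
  pick[[1]]$ref_distance <- dmin[ord[1]]
  pick[[2]]$ref_distance <- dmin[ord[2]]
  colmean <- vapply(pick, function(cl) mean(cl$voxel_indices[, 2]), numeric(1))
  # image left (lower column) = right coronary artery
  if (colmean[1] <= colmean[2])
    list(right = pick[[1]], left = pick[[2]])
  else
    list(right = pick[[2]], left = pick[[1]])
}

#' Segment the coronary arteries from a CT volume
#'
#' Runs the candidate-mask stage at every grey threshold in
#' `filters$grey_thresholds` (the multi-threshold copies), clusters each
#' copy, selects the two aorta-adjacent clusters per copy, and unions the
#' selected voxels across copies.  Lower thresholds capture low-intensity
#' distal lumen, higher thresholds are cleaner proximally; the union keeps
#' both.  The error "coronary pair not found" propagates only if selection
#' fails at every threshold.
#'
#' @param vol an [image_volume()] (windowed to \[0, 255\]).
#' @param filters a [filter_params()].
#' @param cluster a [cluster_params()].
#' @param ref a `reference_point` from [detect_aorta_center()].
#' @param pre optional precomputed [preprocess_volume()] result.
#' @return a [binary_volume()] of coronary voxels with attributes
#'   `per_threshold` (data frame of per-copy quality: clusters found,
#'   selected sizes, reference distances) and `sides` (left/right masks).
#' @export
segment_coronary <- function(vol, filters = filter_params(),
                             cluster = cluster_params(), ref,
                             pre = NULL) {
  stopifnot(length(filters$grey_thresholds) >= 1)
  if (is.null(pre)) pre <- preprocess_volume(vol, filters)
  d <- dim(pre$denoised$voxels)
  out <- array(FALSE, d)
  left <- array(FALSE, d)
  right <- array(FALSE, d)
  rows <- list()
  ok <- FALSE
  for (t in filters$grey_thresholds) {
    bv <- candidate_mask(pre, t, filters)
    cl <- cluster_voxels(bv, cluster)
    sel <- tryCatch(select_coronary_clusters(cl$clusters, ref),
                    error = function(e) e)
    if (inherits(sel, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = t, n_clusters = length(cl$clusters),
        left_size = NA_integer_, right_size = NA_integer_,
        left_dist = NA_real_, right_dist = NA_real_)
      next
    }
    ok <- TRUE
    out[sel$left$voxel_indices] <- TRUE
    out[sel$right$voxel_indices] <- TRUE
    left[sel$left$voxel_indices] <- TRUE
    right[sel$right$voxel_indices] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = t, n_clusters = length(cl$clusters),
      left_size = sel$left$size, right_size = sel$right$size,
      left_dist = sel$left$ref_distance, right_dist = sel$right$ref_distance)
  }
  if (!ok)
    stop("coronary pair not found at any grey threshold (",
         paste(filters$grey_thresholds, collapse = ", "), ")")
  res <- binary_volume(out, pre$denoised$spacing, pre$denoised$origin,
                       threshold_used = min(filters$grey_thresholds))
  attr(res, "per_threshold") <- do.call(rbind, rows)
  attr(res, "sides") <- list(
    left = binary_volume(left, pre$denoised$spacing, pre$denoised$origin),
    right = binary_volume(right, pre$denoised$spacing, pre$denoised$origin))
  res
}
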