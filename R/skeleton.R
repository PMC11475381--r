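#' Clean the coronary voxel volume before skeletonisation
#'
#' Two DBSCAN passes in voxel-index space: first, clusters found with a
#' 7-voxel search radius and at least 700 points in that radius are removed
#' (the dense aortic-root blob -- a coronary-calibre tube never reaches
#' that density); second, voxels that do not belong to any cluster at a
#' 1.5-voxel radius with at least 3 points are removed (isolated voxels and
#' sub-vessel debris).
#'
#' @param mask a [binary_volume()].
#' @param root_eps,root_min_pts DBSCAN settings of the aortic-root pass.
#' @param vessel_eps,vessel_min_pts DBSCAN settings of the small-vessel pass.
#' @return the cleaned [binary_volume()]; attribute `removed` holds the
#'   per-rule counts.
#' @export
clean_voxel_volume <- function(mask, root_eps = 7, root_min_pts = 700,
                               vessel_eps = 1.5, vessel_min_pts = 3) {
  stopifnot(inherits(mask, "binary_volume"))
  arr <- mask$mask
  if (!any(arr)) stop("volume destroyed by cleaning: input mask is empty")
  idx <- which(arr, arr.ind = TRUE)
  colnames(idx) <- NULL
  res1 <- cpp_dbscan_grid(idx, dim(arr), root_eps, as.integer(root_min_pts))
  root_removed <- res1$labels > 0
  idx2 <- idx[!root_removed, , drop = FALSE]
  n_vessel_removed <- 0L
  if (nrow(idx2)) {
    res2 <- cpp_dbscan_grid(idx2, dim(arr), vessel_eps,
                            as.integer(vessel_min_pts))
    keep <- res2$labels > 0
    n_vessel_removed <- sum(!keep)
    idx2 <- idx2[keep, , drop = FALSE]
  }
  if (nrow(idx2) == 0)
    stop(sprintf(paste0("volume destroyed by cleaning: %d voxels removed as ",
                        "aortic root, %d as small vessels/noise"),
                 sum(root_removed), n_vessel_removed))
  out <- array(FALSE, dim(arr))
  out[idx2] <- TRUE
  res <- binary_volume(out, mask$spacing, mask$origin, mask$threshold_used)
  attr(res, "removed") <- c(aortic_root = sum(root_removed),
                            small_vessels = n_vessel_removed)
  res
}

#' Regularise a segmented voxel volume
#'
#' Deterministic clean-up applied before skeletonisation and surface
#' extraction: Gaussian smoothing of the binary volume re-thresholded at
#' 0.5 (a majority-style filter that removes one-voxel roughness and
#' speckle) followed by cavity filling (background regions not connected
#' to the volume border become foreground -- a lumen is solid, so interior
#' cavities are thresholding dropouts, and a cavity wall would corrupt
#' both the medial axis and the radius estimate).
#'
#' @param mask a [binary_volume()].
#' @param sigma Gaussian SD in voxels (0 skips the smoothing).
#' @return the regularised [binary_volume()].
#' @export
regularize_mask <- function(mask, sigma = 0.8) {
  stopifnot(inherits(mask, "binary_volume"))
  arr <- mask$mask
  if (sigma > 0) {
    sm <- cpp_smooth3d(array(as.numeric(arr), dim(arr)), dim(arr),
                       rep(sigma, 3))
    arr <- array(sm >= 0.5, dim(arr))
  }
  arr <- array(cpp_fill_cavities(arr, dim(arr)), dim(arr))
  binary_volume(arr, mask$spacing, mask$origin, mask$threshold_used)
}

#' Extract the centreline skeleton of a voxel volume
#'
#' Topology-preserving 3D thinning: boundary voxels are removed iteratively
#' (six directional sub-iterations, sequential simple-point deletion) until
#' a one-voxel-wide curve along the vessel axis remains.  Curve end points
#' are preserved, so each branch keeps its full extent up to the erosion of
#' the rounded tube ends.
#'
#' @param mask a [binary_volume()].
#' @return a [binary_volume()] containing the skeleton (subset of `mask`).
#' @export
extract_skeleton <- function(mask) {
  stopifnot(inherits(mask, "binary_volume"))
  sk <- cpp_thin3d(mask$mask, dim(mask$mask))
  binary_volume(array(sk, dim(mask$mask)), mask$spacing, mask$origin,
                mask$threshold_used)
}

# 26-neighbour offsets
.offs26 <- local({
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
})

#' Split a skeleton into individual vessel branches
#'
#' Builds the 26-adjacency graph of skeleton voxels, marks voxels with
#' three or more neighbours as junctions, and traces maximal junction-free
#' paths between end points and junctions.  Spurious one- or two-voxel
#' spurs created by thinning artefacts are pruned.  A purely cyclic
#' component is broken at its lexicographically smallest voxel with a
#' warning.
#'
#' @param skeleton a [binary_volume()] holding the skeleton.
#' @param prune_spurs prune terminal branches shorter than this many voxels
#'   when they attach to a junction (default 6; thinning grows short spurs
#'   at bifurcations and on rough masks).
#' @return an object of class `centerline_tree`: list with `branches`
#'   (each: `voxels` ordered n x 3, `points` n x 3 world mm, `radius`
#'   placeholder), `junctions` (voxel indices), `adjacency` (branch x 2
#'   matrix of junction ids at each branch end, NA for free ends),
#'   `spacing`, `origin`.
#' @export
split_branches <- function(skeleton, prune_spurs = 6) {
  stopifnot(inherits(skeleton, "binary_volume"))
  arr <- skeleton$mask
  idx <- which(arr, arr.ind = TRUE)
  colnames(idx) <- NULL
  n <- nrow(idx)
  if (n == 0) stop("skeleton is empty")
  d <- dim(arr)
  key <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  id_of <- new.env(hash = TRUE, size = n)
  ks <- key(idx)
  for (p in seq_len(n)) assign(as.character(ks[p]), p, envir = id_of)
  # neighbour lists
  nb <- vector("list", n)
  for (p in seq_len(n)) {
    cand <- sweep(.offs26, 2, as.numeric(idx[p, ]), `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
      cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    kk <- as.character(key(cand))
    hit <- vapply(kk, function(s) {
      v <- id_of[[s]]
      if (is.null(v)) NA_integer_ else v
    }, integer(1), USE.NAMES = FALSE)
    nb[[p]] <- hit[!is.na(hit)]
  }
  deg <- lengths(nb)
  is_junc <- deg >= 3
  is_end <- deg <= 1
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  branches <- list()
  trace_from <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = visited_edge)
    cur <- nxt; prev <- start
    while (!is_junc[cur] && !is_end[cur]) {
      nxts <- setdiff(nb[[cur]], prev)
      # drop neighbours already connected to prev (26-adjacency shortcuts)
      nxts <- nxts[!vapply(nxts, function(q)
        !is.null(visited_edge[[ekey(cur, q)]]), logical(1))]
      if (!length(nxts)) break
      # prefer face over edge over corner adjacency for a centred walk
      dd <- rowSums(abs(sweep(idx[nxts, , drop = FALSE], 2,
                              as.numeric(idx[cur, ]))))
      q <- nxts[which.min(dd)]
      assign(ekey(cur, q), TRUE, envir = visited_edge)
      path <- c(path, q)
      prev <- cur; cur <- q
    }
    path
  }
  seeds <- which(is_end | is_junc)
  for (s in seeds) {
    for (q in nb[[s]]) {
      if (!is.null(visited_edge[[ekey(s, q)]])) next
      branches[[length(branches) + 1L]] <- trace_from(s, q)
    }
  }
  # leftover cycles: all-degree-2 components never visited
  seen <- logical(n)
  for (b in branches) seen[b] <- TRUE
  if (!all(seen | FALSE)) {
    rem <- which(!seen)
    while (length(rem)) {
      s <- rem[1]
      if (length(nb[[s]]) == 0) {            # isolated voxel
        branches[[length(branches) + 1L]] <- s
        seen[s] <- TRUE
      } else {
        warning("cyclic skeleton component: cycle broken at voxel (",
                paste(idx[s, ], collapse = ","), ")")
        path <- trace_from(s, nb[[s]][1])
        branches[[length(branches) + 1L]] <- path
        seen[path] <- TRUE
      }
      rem <- which(!seen)
    }
  }
  # prune short spurs that end free and attach to a junction
  keep <- vapply(branches, function(b) {
    free_end <- is_end[b[1]] || is_end[b[length(b)]]
    attached <- is_junc[b[1]] || is_junc[b[length(b)]]
    !(free_end && attached && length(b) < prune_spurs)
  }, logical(1))
  if (!all(keep)) branches <- branches[keep]

  junc_ids <- which(is_junc)
  junc_lookup <- stats::setNames(seq_along(junc_ids), junc_ids)
  adjacency <- t(vapply(branches, function(b) {
    ends <- c(b[1], b[length(b)])
    vapply(ends, function(e)
      if (is_junc[e]) as.integer(junc_lookup[as.character(e)]) else NA_integer_,
      integer(1))
  }, integer(2)))
  world <- voxel_to_world(idx, skeleton$spacing, skeleton$origin)
  structure(list(
    branches = lapply(branches, function(b)
      list(voxels = idx[b, , drop = FALSE],
           points = world[b, , drop = FALSE],
           radius = NULL)),
    junctions = idx[junc_ids, , drop = FALSE],
    adjacency = adjacency,
    spacing = skeleton$spacing,
    origin = skeleton$origin), class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  cat(sprintf("<centerline_tree> %d branches, %d junction voxels\n",
              length(x$branches), nrow(x$junctions)))
  for (i in seq_along(x$branches)) {
    b <- x$branches[[i]]
    len <- sum(sqrt(rowSums(diff(b$points)^2)))
    cat(sprintf("  branch %d: %d voxels, length %.1f mm%s\n", i,
                nrow(b$voxels), len,
                if (!is.null(b$radius)) sprintf(", radius %.2f-%.2f mm",
                                                min(b$radius), max(b$radius))
                else ""))
  }
  invisible(x)
}
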