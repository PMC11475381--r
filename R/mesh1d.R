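#' One-dimensional vessel network mesh
#'
#' Container for the solver's geometry: per vessel, equidistant nodes along
#' the centreline arc length with reference radius `r0` and reference area
#' `A0 = pi * r0^2`, plus rooted-tree connectivity.  All lengths in cm
#' (CGS, matching the solver).
#'
#' @param vessels list; each element a list with `x` (node arc-lengths from
#'   the vessel start, cm), `r0` (cm), `parent` (vessel index, 0 for a
#'   root), optional `id` (character).
#' @param spacing target node spacing in cm.
#' @return an object of class `mesh1d`; each vessel gains `A0`, `length`,
#'   `children` and `terminal` fields.
#' @export
mesh1d <- function(vessels, spacing = 0.01) {
  stopifnot(length(vessels) >= 1, spacing > 0)
  nv <- length(vessels)
  parents <- vapply(vessels, function(v) as.integer(v$parent), integer(1))
  for (i in seq_len(nv)) {
    v <- vessels[[i]]
    if (length(v$x) < 2) stop("vessel ", i, " needs at least 2 nodes")
    if (any(diff(v$x) <= 0)) stop("vessel ", i, ": arc-lengths must increase")
    if (any(v$r0 <= 0)) stop("vessel ", i, ": radii must be positive")
    if (length(v$r0) != length(v$x)) stop("vessel ", i, ": x/r0 length mismatch")
    h <- diff(v$x)
    # short branches cannot quantise to within 5% of the target spacing;
    # only flag vessels long enough for the tolerance to be meaningful
    if (max(abs(h - spacing)) > 0.05 * spacing && length(v$x) > 11)
      warning(sprintf("vessel %d: node spacing deviates from target by up to %.1f%%",
                      i, 100 * max(abs(h - spacing)) / spacing))
    v$A0 <- pi * v$r0^2
    v$length <- v$x[length(v$x)] - v$x[1]
    v$children <- which(parents == i)
    v$terminal <- length(v$children) == 0
    if (is.null(v$id)) v$id <- sprintf("v%d", i)
    vessels[[i]] <- v
  }
  roots <- which(parents == 0)
  if (!length(roots)) stop("mesh has no root vessel")
  structure(list(vessels = vessels, spacing = spacing, roots = roots),
            class = "mesh1d")
}

#' @export
print.mesh1d <- function(x, ...) {
  cat(sprintf("<mesh1d> %d vessel(s), target spacing %.3f cm\n",
              length(x$vessels), x$spacing))
  for (i in seq_along(x$vessels)) {
    v <- x$vessels[[i]]
    cat(sprintf("  %s: %d nodes, L = %.2f cm, r0 %.3f -> %.3f cm, parent %s%s\n",
                v$id, length(v$x), v$length, v$r0[1], v$r0[length(v$r0)],
                if (v$parent == 0) "-" else x$vessels[[v$parent]]$id,
                if (v$terminal) " [terminal]" else ""))
  }
  invisible(x)
}

#' Build an equidistant 1D mesh from a centreline tree
#'
#' Roots the tree at the branch end nearest `root_point` (the aortic
#' reference, so flow starts at the ostium), orients every branch away
#' from the root, and resamples each branch's radius-vs-arc-length profile
#' with shape-preserving PCHIP interpolation onto equidistant nodes.
#' PCHIP is monotone between data points, so interpolated radii never
#' overshoot the local data range and a stenosis minimum is preserved
#' exactly.  The first `trim_nodes` nodes of the root branch are removed
#' because voxels near the aortic ostium are eroded by the root-cleaning
#' pass and under-size the local radius.
#'
#' @param tree a `centerline_tree` with radii (see [estimate_radii()]).
#' @param spacing target node spacing in cm (default 0.01 cm = 0.1 mm, the
#'   fine mesh needed to resolve sudden geometry changes).
#' @param trim_nodes number of initial root-branch nodes to drop
#'   (default 5).
#' @param root_point world point (mm) the root end should be nearest to.
#' @param min_terminal terminal vessels shorter than this (cm) are pruned
#'   recursively: sub-millimetre terminal twigs are thinning artefacts at
#'   junctions, and their tiny end radii would demand unphysically large
#'   characteristic impedances in the outflow beds.
#' @param min_radius trailing nodes of terminal vessels with radii below
#'   this floor (cm, default 0.7 mm) are trimmed: where the mask frays
#'   distally the estimated radius falls to the voxel scale and is no
#'   longer a measurement, and outlets below distal-coronary calibre make
#'   the terminal characteristic impedance exceed any physiological bed
#'   resistance.  Interior minima (stenoses) are never touched.
#' @return a [mesh1d()].
#' @export
build_mesh1d <- function(tree, spacing = 0.01, trim_nodes = 5,
                         root_point = NULL, min_terminal = 0.2,
                         min_radius = 0.07) {
  stopifnot(inherits(tree, "centerline_tree"))
  nb <- length(tree$branches)
  for (b in tree$branches)
    if (is.null(b$radius) || length(b$radius) < 2)
      stop("every branch needs at least 2 points with radii; run estimate_radii() first")
  if (is.null(root_point)) root_point <- tree$branches[[1]]$points[1, ]
  root_point <- as.numeric(root_point)

  # nearest branch end = root; orient and BFS through shared junctions
  endpts <- do.call(rbind, lapply(seq_len(nb), function(i) {
    p <- tree$branches[[i]]$points
    rbind(c(i, 1, p[1, ]), c(i, 2, p[nrow(p), ]))
  }))
  dists <- sqrt(rowSums(sweep(endpts[, 3:5, drop = FALSE], 2, root_point)^2))
  first <- endpts[which.min(dists), 1:2]
  orient <- integer(nb)       # 0 unknown, 1 as stored, 2 reversed
  parent <- rep(NA_integer_, nb)
  ordering <- integer(0)
  orient[first[1]] <- first[2]
  parent[first[1]] <- 0L
  queue <- first[1]
  adj <- tree$adjacency
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ordering <- c(ordering, i)
    # junction at this branch's far end
    far <- if (orient[i] == 1) 2L else 1L
    j <- adj[i, far]
    if (is.na(j)) next
    for (k in seq_len(nb)) {
      if (k == i || orient[k] != 0) next
      if (!is.na(adj[k, 1]) && adj[k, 1] == j) {
        orient[k] <- 1L; parent[k] <- i; queue <- c(queue, k)
      } else if (!is.na(adj[k, 2]) && adj[k, 2] == j) {
        orient[k] <- 2L; parent[k] <- i; queue <- c(queue, k)
      }
    }
  }
  unreached <- which(orient == 0)
  if (length(unreached)) {
    warning(length(unreached),
            " branch(es) not connected to the rooted tree were dropped")
  }
  # map old branch index -> new vessel index
  newidx <- stats::setNames(seq_along(ordering), ordering)
  vessels <- vector("list", length(ordering))
  for (pos in seq_along(ordering)) {
    i <- ordering[pos]
    b <- tree$branches[[i]]
    pts <- b$points; rad <- b$radius
    if (orient[i] == 2) { pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
                          rad <- rev(rad) }
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2)))) / 10   # mm -> cm
    r <- rad / 10
    L <- s[length(s)]
    if (L < spacing) {
      warning(sprintf("branch %d shorter than the mesh spacing; collapsed", i))
      nnode <- 2L
    } else nnode <- as.integer(round(L / spacing)) + 1L
    xq <- seq(0, L, length.out = nnode)
    # deduplicate arc-lengths for interpolation; PCHIP needs >= 3 knots,
    # a 2-point branch is linear anyway
    keep <- c(TRUE, diff(s) > 1e-9)
    rq <- if (sum(keep) >= 3) signal::pchip(s[keep], r[keep], xq)
          else stats::approx(s[keep], r[keep], xout = xq, rule = 2)$y
    par <- if (is.na(parent[i]) || parent[i] == 0) 0L else
      as.integer(newidx[as.character(parent[i])])
    if (par == 0L && trim_nodes > 0 && nnode > trim_nodes + 1) {
      xq <- xq[-(1:trim_nodes)] - xq[trim_nodes + 1]
      rq <- rq[-(1:trim_nodes)]
    }
    vessels[[pos]] <- list(x = xq, r0 = rq, parent = par,
                           id = sprintf("v%d", pos))
  }
  # trim sub-resolution tails of terminal vessels and prune short or
  # fully sub-resolution artefact terminals (never the root), repeating
  # because a drop can expose a new frayed terminal
  repeat {
    parents <- vapply(vessels, `[[`, integer(1), "parent")
    is_term <- !(seq_along(vessels) %in% parents)
    for (i in which(is_term)) {
      v <- vessels[[i]]
      keep <- length(v$r0)
      while (keep > 2 && v$r0[keep] < min_radius) keep <- keep - 1L
      if (keep < length(v$r0)) {
        vessels[[i]]$x <- v$x[1:keep]
        vessels[[i]]$r0 <- v$r0[1:keep]
      }
    }
    lens <- vapply(vessels, function(v) v$x[length(v$x)] - v$x[1], numeric(1))
    small_end <- vapply(vessels, function(v) v$r0[length(v$r0)] < min_radius,
                        logical(1))
    drop <- which(is_term & parents != 0L & (lens < min_terminal | small_end))
    if (!length(drop) || length(vessels) <= 1) break
    k <- drop[1]
    vessels <- vessels[-k]
    for (i in seq_along(vessels)) {
      if (vessels[[i]]$parent > k) vessels[[i]]$parent <-
          vessels[[i]]$parent - 1L
      vessels[[i]]$id <- sprintf("v%d", i)
    }
  }
  mesh1d(vessels, spacing)
}

#' Write / read a 1D mesh as JSON
#'
#' @param mesh a [mesh1d()].
#' @param path file path.
#' @return `read_mesh1d_json` returns a [mesh1d()].
#' @export
write_mesh1d_json <- function(mesh, path) {
  stopifnot(inherits(mesh, "mesh1d"))
  out <- list(spacing = mesh$spacing,
              vessels = lapply(mesh$vessels, function(v)
                list(id = v$id, parent = v$parent, x = v$x, r0 = v$r0)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mesh1d_json
#' @export
read_mesh1d_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vessels <- lapply(seq_len(nrow(as.data.frame(raw$vessels["id"]))), function(i)
    list(id = raw$vessels$id[i], parent = raw$vessels$parent[i],
         x = raw$vessels$x[[i]], r0 = raw$vessels$r0[[i]]))
  mesh1d(vessels, raw$spacing)
}
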