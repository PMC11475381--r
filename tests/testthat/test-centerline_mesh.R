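# Volume cleaning, skeletonisation, branch splitting, surface extraction,
# radius estimation and 1D meshing.

test_that("cleaning spares coronary-calibre tubes and removes root-like blobs", {
  tm <- tube_mask(r = 3, L = 50)
  cleaned <- clean_voxel_volume(tm$mask)
  # a radius-3 tube has far fewer than 700 voxels in any 7-voxel ball
  expect_identical(cleaned$mask, tm$mask$mask)
  # a tube attached to a large sphere (aortic-root stand-in)
  cx <- 20
  arr <- array(FALSE, c(40, 40, 70))
  d2t <- (row(matrix(0, 40, 40)) - cx)^2 + (col(matrix(0, 40, 40)) - cx)^2
  for (k in 11:60) arr[, , k] <- d2t <= 9
  d2s <- outer(outer((seq_len(40) - cx)^2, (seq_len(40) - cx)^2, `+`),
               (seq_len(70) - 8)^2, `+`)
  arr[d2s <= 15^2] <- TRUE
  withblob <- binary_volume(arr, c(1, 1, 1))
  cleaned2 <- clean_voxel_volume(withblob)
  rem <- attr(cleaned2, "removed")
  expect_gt(rem[["aortic_root"]], 10000)        # sphere gone
  expect_gt(sum(cleaned2$mask), 700)            # distal tube body retained
  expect_lt(mean(d2s[cleaned2$mask] <= 15^2), 0.2)  # few sphere voxels left
})

test_that("scattered voxels are removed by the small-vessel pass", {
  arr <- array(FALSE, c(30, 30, 30))
  pts <- cbind(c(3, 10, 20, 27), c(5, 22, 8, 25), c(4, 12, 20, 28))
  arr[pts] <- TRUE
  arr[13:17, 13:17, 13:17] <- TRUE     # a dense survivor
  cleaned <- clean_voxel_volume(binary_volume(arr, c(1, 1, 1)))
  expect_equal(sum(cleaned$mask), 125L)
  expect_equal(attr(cleaned, "removed")[["small_vessels"]], 4L)
  lone <- binary_volume(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)), c(1, 1, 1))
  expect_error(clean_voxel_volume(lone), "volume destroyed by cleaning")
})

test_that("a straight tube thins to a single centred path", {
  tm <- tube_mask(r = 4, L = 60)
  sk <- extract_skeleton(tm$mask)
  idx <- which(sk$mask, arr.ind = TRUE)
  expect_true(all(tm$mask$mask[sk$mask]))   # skeleton is a subset of the mask
  dev <- sqrt((idx[, 1] - tm$centre)^2 + (idx[, 2] - tm$centre)^2)
  expect_lte(max(dev), 1)
  # single voxel-wide path: one branch, no junctions
  tree <- split_branches(sk)
  expect_length(tree$branches, 1)
  expect_equal(nrow(tree$junctions), 0)
})

test_that("thinning preserves topology and isolated voxels", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  sk <- extract_skeleton(binary_volume(one, c(1, 1, 1)))
  expect_identical(sk$mask, one)
  two <- tube_mask(r = 2, L = 40)$mask$mask
  arr <- array(FALSE, c(dim(two)[1] + 14, dim(two)[2], 40))
  arr[1:dim(two)[1], , ] <- two
  arr[dim(two)[1] + 10, 7, 10:30] <- TRUE    # second, separate line
  sk2 <- extract_skeleton(binary_volume(arr, c(1, 1, 1)))
  tree <- split_branches(sk2)
  expect_length(tree$branches, 2)
})

test_that("a Y-shaped volume splits into three branches around one junction", {
  ym <- fixture("y_mask", y_mask)
  sk <- extract_skeleton(ym)
  tree <- split_branches(sk)
  expect_length(tree$branches, 3)
  expect_gte(nrow(tree$junctions), 1)
  # the three branch far-ends are spatially distinct
  ends <- t(vapply(tree$branches, function(b) b$points[nrow(b$points), ],
                   numeric(3)))
  expect_equal(nrow(unique(round(ends))), 3)
})

test_that("total centreline length of a slender tube is within 3%", {
  tm <- tube_mask(r = 2, L = 206, margin = 3)
  sk <- extract_skeleton(tm$mask)
  tree <- split_branches(sk)
  len <- sum(vapply(tree$branches, function(b)
    sum(sqrt(rowSums(diff(b$points)^2))), numeric(1)))
  true_len <- (length(tm$slices) - 1)
  expect_lt(abs(len - true_len) / true_len, 0.03)
})

test_that("iso-surface areas match analytic sphere and cylinder", {
  arr <- array(FALSE, c(31, 31, 31))
  d2 <- outer(outer((1:31 - 16)^2, (1:31 - 16)^2, `+`), (1:31 - 16)^2, `+`)
  arr[d2 <= 100] <- TRUE
  surf <- extract_surface(binary_volume(arr, c(1, 1, 1)))
  expect_lt(abs(surf$area - 4 * pi * 100) / (4 * pi * 100), 0.05)
  tm <- tube_mask(r = 4, L = 60, margin = 3)
  st <- extract_surface(tm$mask)
  lateral <- 2 * pi * 4 * (length(tm$slices) - 1)
  caps <- 2 * pi * 16
  expect_lt(abs(st$area - (lateral + caps)) / lateral, 0.05)
  # single voxel: a small closed surface
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  s1 <- extract_surface(binary_volume(one, c(1, 1, 1)), smooth_sigma = 0)
  expect_gt(nrow(s1$faces), 0)
  expect_gt(s1$area, 0)
})

test_that("radius estimates recover tube and stenosis geometry", {
  tm <- tube_mask(r = 4, L = 60)
  sk <- extract_skeleton(tm$mask)
  tree <- estimate_radii(split_branches(sk), extract_surface(tm$mask))
  r <- tree$branches[[1]]$radius
  expect_true(all(abs(r - 4) <= 0.5))
  ph <- make_tube_phantom(severity = 0.5, noise_sigma = 0)
  sk2 <- extract_skeleton(ph$truth)
  tree2 <- estimate_radii(split_branches(sk2), extract_surface(ph$truth))
  b <- tree2$branches[[1]]
  expect_lt(abs(min(b$radius) - ph$meta$min_radius_mm), 0.5)
  zmin <- b$voxels[which.min(b$radius), 3]
  expect_lte(abs(zmin - ph$meta$min_radius_z), 2)
})

test_that("PCHIP meshing is shape preserving and equidistant", {
  # linear radius profile reproduced exactly
  tree <- structure(list(
    branches = list(list(voxels = cbind(1:11, 1, 1),
                         points = cbind(seq(0, 20, 2), 0, 0),
                         radius = seq(4, 2, length.out = 11))),
    junctions = matrix(numeric(0), 0, 3),
    adjacency = matrix(NA_integer_, 1, 2),
    spacing = c(1, 1, 1), origin = c(0, 0, 0)), class = "centerline_tree")
  mesh <- build_mesh1d(tree, spacing = 0.01, trim_nodes = 0)
  v <- mesh$vessels[[1]]
  expect_equal(length(v$x), 201)
  expect_equal(v$r0, seq(0.4, 0.2, length.out = 201), tolerance = 1e-9)
  expect_true(all(abs(diff(v$x) - 0.01) <= 0.05 * 0.01))
  # no undershoot below local minima: {4,4,2,4,4} dips to exactly 2
  tree$branches[[1]]$points <- cbind(seq(0, 40, 10), 0, 0)
  tree$branches[[1]]$voxels <- cbind(1:5, 1, 1)
  tree$branches[[1]]$radius <- c(4, 4, 2, 4, 4)
  mesh2 <- build_mesh1d(tree, spacing = 0.01, trim_nodes = 0)
  expect_equal(min(mesh2$vessels[[1]]$r0), 0.2, tolerance = 1e-12)
  expect_lte(max(mesh2$vessels[[1]]$r0), 0.4 + 1e-12)
  # node-count arithmetic: 10 cm at 0.01 cm spacing
  tree$branches[[1]]$points <- cbind(seq(0, 100, length.out = 11), 0, 0)
  tree$branches[[1]]$radius <- rep(3, 11)
  mesh3 <- build_mesh1d(tree, spacing = 0.01, trim_nodes = 0)
  expect_lte(abs(length(mesh3$vessels[[1]]$x) - 1001), 1)
})

test_that("root-branch trimming drops the configured initial nodes", {
  tree <- structure(list(
    branches = list(list(voxels = cbind(1:11, 1, 1),
                         points = cbind(seq(0, 10, 1), 0, 0),
                         radius = rep(3, 11))),
    junctions = matrix(numeric(0), 0, 3),
    adjacency = matrix(NA_integer_, 1, 2),
    spacing = c(1, 1, 1), origin = c(0, 0, 0)), class = "centerline_tree")
  m0 <- build_mesh1d(tree, spacing = 0.01, trim_nodes = 0)
  m5 <- build_mesh1d(tree, spacing = 0.01, trim_nodes = 5)
  expect_equal(length(m0$vessels[[1]]$x) - length(m5$vessels[[1]]$x), 5L)
  expect_equal(m5$vessels[[1]]$x[1], 0)
})

test_that("mesh JSON round-trips", {
  mesh <- bifurcation_mesh()
  path <- tempfile(fileext = ".json")
  write_mesh1d_json(mesh, path)
  back <- read_mesh1d_json(path)
  expect_equal(length(back$vessels), 3)
  for (i in 1:3) {
    expect_equal(back$vessels[[i]]$x, mesh$vessels[[i]]$x)
    expect_equal(back$vessels[[i]]$r0, mesh$vessels[[i]]$r0)
    expect_equal(back$vessels[[i]]$parent, mesh$vessels[[i]]$parent)
  }
})
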