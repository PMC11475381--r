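# DBSCAN voxel clustering and coronary cluster identification.

mask_from_points <- function(pts, dims = c(20, 20, 20)) {
  arr <- array(FALSE, dims)
  arr[pts] <- TRUE
  binary_volume(arr, c(1, 1, 1))
}

test_that("collinear voxels one apart form a single cluster", {
  pts <- cbind(5:9, 5, 5)
  cl <- cluster_voxels(mask_from_points(pts), cluster_params(1.6, 2))
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$size, 5)
  expect_equal(nrow(cl$noise), 0)
})

test_that("isolated voxels are noise and empty masks give empty results", {
  pts <- rbind(c(5, 5, 5), c(8, 5, 5))     # 3 apart, eps 1.6, minPts 2
  cl <- cluster_voxels(mask_from_points(pts), cluster_params(1.6, 2))
  expect_length(cl$clusters, 0)
  expect_equal(nrow(cl$noise), 2)
  empty <- cluster_voxels(mask_from_points(matrix(numeric(0), ncol = 3)))
  expect_length(empty$clusters, 0)
})

test_that("a dense group with one far point yields one cluster plus noise", {
  dense <- as.matrix(expand.grid(5:7, 5:7, 5))
  far <- c(15, 15, 5)
  cl <- cluster_voxels(mask_from_points(rbind(dense, far)),
                       cluster_params(1.6, 2))
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]]$size, 9)
  expect_equal(nrow(cl$noise), 1)
  expect_equal(as.numeric(cl$noise[1, ]), far)
})

test_that("cluster partition is independent of point ordering", {
  set.seed(3)
  arr <- array(runif(30^3) < 0.08, c(30, 30, 30))
  bv <- binary_volume(arr, c(1, 1, 1))
  cl <- cluster_voxels(bv, cluster_params(1.6, 3))
  # membership as a labelling of sorted voxel keys must be reproducible
  lab1 <- do.call(rbind, lapply(cl$clusters, function(c)
    cbind(c$voxel_indices, c$label)))
  cl2 <- cluster_voxels(bv, cluster_params(1.6, 3))
  lab2 <- do.call(rbind, lapply(cl2$clusters, function(c)
    cbind(c$voxel_indices, c$label)))
  expect_identical(lab1, lab2)
  # every masked voxel is in exactly one cluster or noise
  total <- sum(vapply(cl$clusters, `[[`, integer(1), "size")) + nrow(cl$noise)
  expect_equal(total, sum(arr))
})

test_that("the two clusters nearest the aortic reference are selected", {
  ref <- structure(list(center = c(row = 10, col = 10), radius = 5,
                        slice_range = 1:3, slices_used = 1:3),
                   class = "reference_point")
  mkcl <- function(centre, label) {
    pts <- sweep(as.matrix(expand.grid(0:1, 0:1, 0:1)), 2, centre, `+`)
    list(voxel_indices = pts, label = label, core = rep(TRUE, 8), size = 8L)
  }
  clusters <- list(mkcl(c(10, 20, 2), 1),   # dist ~10
                   mkcl(c(22, 10, 2), 2),   # dist ~12
                   mkcl(c(80, 80, 2), 3))   # far
  sel <- select_coronary_clusters(clusters, ref)
  expect_setequal(c(sel$left$label, sel$right$label), c(1, 2))
  # image-x (column) order decides the side labels
  expect_gt(mean(sel$left$voxel_indices[, 2]),
            mean(sel$right$voxel_indices[, 2]))
  expect_error(select_coronary_clusters(clusters[1], ref),
               "coronary pair not found")
})

test_that("multi-threshold union never shrinks when thresholds are added", {
  ph <- fixture("coronary_phantom", function() make_coronary_phantom(seed = 2))
  pre <- fixture("coronary_pre", function()
    preprocess_volume(fixture("coronary_phantom", NULL)$vol))
  ref <- fixture("coronary_ref", function()
    detect_aorta_center(fixture("coronary_phantom", NULL)$vol))
  seg1 <- segment_coronary(ph$vol, filter_params(grey_thresholds = c(130)),
                           ref = ref, pre = pre)
  seg2 <- segment_coronary(ph$vol,
                           filter_params(grey_thresholds = c(125, 130)),
                           ref = ref, pre = pre)
  expect_true(all(seg2$mask[seg1$mask]))
  # single-threshold list equals selecting on that threshold alone
  seg1b <- segment_coronary(ph$vol, filter_params(grey_thresholds = c(130)),
                            ref = ref, pre = pre)
  expect_identical(seg1$mask, seg1b$mask)
})

test_that("the coronary phantom segments to the labelled trees, not the decoy", {
  ph <- fixture("coronary_phantom", function() make_coronary_phantom(seed = 2))
  pre <- fixture("coronary_pre", function()
    preprocess_volume(fixture("coronary_phantom", NULL)$vol))
  ref <- fixture("coronary_ref", function()
    detect_aorta_center(fixture("coronary_phantom", NULL)$vol))
  seg <- fixture("coronary_seg", function()
    segment_coronary(fixture("coronary_phantom", NULL)$vol, ref = ref,
                     pre = pre))
  truth <- ph$truth$mask
  dice <- 2 * sum(seg$mask & truth) / (sum(seg$mask) + sum(truth))
  expect_gte(dice, 0.9)
  expect_equal(sum(seg$mask & (ph$labels == 4)), 0)   # decoy excluded
  sides <- attr(seg, "sides")
  # left tree carries label 2, right label 3
  expect_gt(sum(sides$left$mask & (ph$labels == 2)),
            sum(sides$left$mask & (ph$labels == 3)))
  expect_gt(sum(sides$right$mask & (ph$labels == 3)),
            sum(sides$right$mask & (ph$labels == 2)))
})
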