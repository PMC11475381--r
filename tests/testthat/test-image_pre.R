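# Per-slice filtering chain: noise estimation, de-noising, vesselness,
# thresholding with contour-area removal.

test_that("crop keeps world coordinates and rejects degenerate boxes", {
  vol <- image_volume(array(runif(32 * 32 * 6, 0, 255), c(32, 32, 6)),
                      spacing = c(0.5, 0.5, 1), origin = c(1, 2, 3))
  full <- crop_cardiac_region(vol, rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(full$voxels, vol$voxels)
  half <- crop_cardiac_region(vol, rbind(c(0.5, 0.5, 0), c(1, 1, 1)))
  expect_equal(dim(half$voxels), c(16, 16, 6))
  # world coordinate of the first retained voxel is unchanged
  expect_equal(half$origin, vol$origin + c(16, 16, 0) * vol$spacing)
  expect_error(crop_cardiac_region(vol, rbind(c(0.5, 0, 0), c(0.5, 1, 1))),
               "empty volume on axis x")
})

test_that("noise SD estimator recovers the generating sigma and scales", {
  expect_equal(estimate_noise_sigma(matrix(7, 64, 64)), 0)
  base <- matrix(100, 128, 128)
  base[40:90, 40:90] <- 180
  set.seed(42)
  n1 <- matrix(rnorm(128^2, 0, 10), 128)
  s1 <- estimate_noise_sigma(base + n1)
  expect_lt(abs(s1 - 10) / 10, 0.2)
  s2 <- estimate_noise_sigma(base + 2 * n1)
  expect_lt(abs(s2 / s1 - 2), 0.2)
})

test_that("non-local means reduces noise variance without range expansion", {
  clean <- matrix(100, 96, 96)
  clean[30:70, 30:70] <- 200
  expect_lt(max(abs(denoise_slice(clean, 0) - clean)), 1)
  set.seed(1)
  noisy <- matrix(120 + rnorm(96^2, 0, 10), 96)
  dn <- denoise_slice(noisy, 10)
  expect_lt(var(as.vector(dn)), var(as.vector(noisy)))
  expect_gte(min(dn), min(noisy))
  expect_lte(max(dn), max(noisy))
})

test_that("non-local means treats identical textured regions identically", {
  set.seed(5)
  tex <- matrix(100 + rnorm(24 * 96, 0, 15), 24, 96)
  sl <- matrix(50, 96, 96)
  sl[10:33, ] <- tex
  sl[60:83, ] <- tex
  dn <- denoise_slice(sl, 5)
  expect_equal(dn[10:33, ], dn[60:83, ], tolerance = 1e-10)
})

test_that("vesselness scores ridges high, background and blobs low", {
  expect_true(all(vesselness_filter(matrix(50, 64, 64)) == 0))
  line <- matrix(0, 128, 128)
  line[62:65, ] <- 200                        # bright line of width 4
  vl <- vesselness_filter(line)
  expect_gt(mean(vl[62:65, 20:108]), 10 * mean(vl[c(1:40, 90:128), ]))
  disc <- matrix(0, 128, 128)
  d2 <- (row(disc) - 64)^2 + (col(disc) - 64)^2
  disc[d2 <= 30^2] <- 200                     # isotropic blob, radius 30
  vd <- vesselness_filter(disc)
  expect_lt(mean(vd[d2 <= 20^2]), mean(vl[62:65, 20:108]))
})

test_that("binarisation removes components strictly larger than the area threshold", {
  sl <- matrix(0, 80, 80)
  sl[2:41, 2:26] <- 200        # 40 x 25 = 1000 px blob
  sl[60:69, 60:64] <- 200      # 10 x 5 = 50 px blob
  m <- binarize_and_filter(sl, 125, 900)
  expect_false(any(m[2:41, 2:26]))
  expect_true(all(m[60:69, 60:64]))
  expect_false(any(binarize_and_filter(matrix(10, 40, 40), 125, 900)))
  sq <- matrix(0, 40, 40)
  sq[4:33, 4:33] <- 200        # exactly 900 px survives ("larger than")
  expect_equal(sum(binarize_and_filter(sq, 125, 900)), 900L)
  sq[4:34, 4:33] <- 200        # 930 px is removed
  expect_equal(sum(binarize_and_filter(sq, 125, 900)), 0L)
})

test_that("masks are monotone in the grey threshold", {
  ph <- fixture("tube_sigma10", function()
    make_tube_phantom(severity = 0.3, noise_sigma = 10, seed = 11))
  pre <- fixture("tube_sigma10_pre", function()
    preprocess_volume(fixture("tube_sigma10", NULL)$vol))
  m_low <- candidate_mask(pre, 125)
  m_high <- candidate_mask(pre, 140)
  expect_true(all(m_low$mask[m_high$mask]))
})

test_that("the chain keeps nearly all lumen voxels of a clean phantom and is idempotent", {
  ph <- make_tube_phantom(noise_sigma = 0, partial_volume = FALSE,
                          tube_intensity = 135)
  pre <- preprocess_volume(ph$vol)
  m <- candidate_mask(pre, 125)          # phantom intensity minus 10
  kept <- sum(m$mask & ph$truth$mask) / sum(ph$truth$mask)
  expect_gte(kept, 0.95)
  # already-binarised phantom: a second pass changes nothing
  bin <- image_volume(array(ifelse(m$mask, 255, 0), dim(m$mask)),
                      ph$vol$spacing)
  m2 <- candidate_mask(preprocess_volume(bin), 125)
  expect_identical(m2$mask, m$mask)
})
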