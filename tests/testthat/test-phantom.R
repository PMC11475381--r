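# Phantom generators: ground truth consistency and reproducibility.

test_that("tube phantom mask volume matches the analytic cylinder", {
  ph <- make_tube_phantom(noise_sigma = 0)
  L <- length(ph$meta$slices)
  expect_lt(abs(sum(ph$truth$mask) - pi * 4^2 * L) / (pi * 16 * L), 0.05)
  expect_equal(nrow(ph$axis), L)
  expect_true(all(ph$true_radius_mm == 4))
})

test_that("phantoms are byte-identical under a fixed seed", {
  a <- make_tube_phantom(noise_sigma = 10, seed = 9)
  b <- make_tube_phantom(noise_sigma = 10, seed = 9)
  expect_identical(a$vol$voxels, b$vol$voxels)
  cc <- make_tube_phantom(noise_sigma = 10, seed = 10)
  expect_false(identical(a$vol$voxels, cc$vol$voxels))
  p1 <- make_coronary_phantom(seed = 4, shape = c(128, 128, 24),
                              aorta_center = c(60, 64), aorta_radius = 26)
  p2 <- make_coronary_phantom(seed = 4, shape = c(128, 128, 24),
                              aorta_center = c(60, 64), aorta_radius = 26)
  expect_identical(p1$vol$voxels, p2$vol$voxels)
})

test_that("degenerate tube specs are rejected", {
  expect_error(make_tube_phantom(shape = c(48, 48, 8), margin = 5),
               "zero-length axis")
  expect_error(make_tube_phantom(r0_vox = 40), "exits volume")
  expect_error(make_stenosed_mesh1d(severity = 1), "severity")
})

test_that("stenosed 1D mesh hits the prescribed throat", {
  for (sev in c(0, 0.5)) {
    st <- make_stenosed_mesh1d(r0 = 0.15, severity = sev)
    v <- st$mesh$vessels[[1]]
    expect_equal(min(v$r0), 0.15 * (1 - sev), tolerance = 1e-12)
    expect_equal(v$x[which.min(v$r0)], if (sev > 0) st$throat_x else 0)
    # area ratio at the throat
    expect_equal(min(v$A0) / (pi * 0.15^2), (1 - sev)^2, tolerance = 1e-12)
    expect_equal(v$A0, pi * v$r0^2)
  }
})

test_that("coronary phantom labels partition the vessels and mirror swaps sides", {
  ph <- fixture("coronary_phantom", function() make_coronary_phantom(seed = 2))
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L, 2L, 3L, 4L))
  expect_identical(ph$truth$mask, ph$labels == 2L | ph$labels == 3L)
  m <- make_coronary_phantom(seed = 2, mirror = TRUE)
  expect_equal(sum(m$labels == 2L), sum(ph$labels == 3L))
  expect_equal(sum(m$labels == 3L), sum(ph$labels == 2L))
})

test_that("a phantom without aorta aborts the reference detection", {
  ph <- make_coronary_phantom(seed = 2, aorta_radius = NA,
                              shape = c(128, 128, 24),
                              aorta_center = c(60, 64))
  expect_error(detect_aorta_center(ph$vol), "aorta not detected")
})
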