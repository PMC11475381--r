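# Hough-circle aortic landmark detection.

disc_volume <- function(centre = c(60, 70), radius = 40, nslice = 10,
                        side = 160, intensity = 200, bg = 30) {
  arr <- array(bg, c(side, side, nslice))
  d2 <- (row(matrix(0, side, side)) - centre[1])^2 +
        (col(matrix(0, side, side)) - centre[2])^2
  disc <- d2 <= radius^2
  for (k in seq_len(nslice)) {
    sl <- arr[, , k]
    sl[disc] <- intensity
    arr[, , k] <- sl
  }
  image_volume(arr)
}

test_that("a disc of known centre and radius is recovered within 2 px", {
  vol <- disc_volume(centre = c(60, 70), radius = 40)
  ref <- detect_aorta_center(vol)
  expect_lt(abs(ref$center["row"] - 60), 2)
  expect_lt(abs(ref$center["col"] - 70), 2)
  expect_lt(abs(ref$radius - 40), 2)
  expect_equal(unname(ref$slice_range), 5:9)
})

test_that("detection is translation-equivariant and deterministic", {
  v1 <- disc_volume(centre = c(60, 70))
  v2 <- disc_volume(centre = c(75, 58))
  r1 <- detect_aorta_center(v1)
  r2 <- detect_aorta_center(v2)
  expect_lt(abs((r2$center["row"] - r1$center["row"]) - 15), 1)
  expect_lt(abs((r2$center["col"] - r1$center["col"]) - (-12)), 1)
  r1b <- detect_aorta_center(v1)
  expect_identical(r1$center, r1b$center)
})

test_that("circles outside the radius range are rejected", {
  small <- disc_volume(radius = 15)
  expect_error(detect_aorta_center(small), "aorta not detected")
  # radii 40 and 70 present: the 40 px circle wins (70 out of range)
  vol <- disc_volume(centre = c(45, 45), radius = 40, side = 200)
  d2 <- (row(matrix(0, 200, 200)) - 120)^2 + (col(matrix(0, 200, 200)) - 120)^2
  big <- d2 <= 70^2
  for (k in 1:10) {
    sl <- vol$voxels[, , k]
    sl[big & sl < 100] <- 200
    vol$voxels[, , k] <- sl
  }
  ref <- detect_aorta_center(vol)
  expect_lt(abs(ref$radius - 40), 3)
  expect_lt(abs(ref$center["row"] - 45), 3)
})

test_that("too few slices is an input error", {
  vol <- disc_volume(nslice = 4)
  expect_error(detect_aorta_center(vol), "slices")
})
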