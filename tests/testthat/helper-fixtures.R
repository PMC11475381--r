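# Shared fixtures built in code.  Heavy phantoms are memoised per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small straight digital tube mask (isotropic 1 mm), axis on a voxel
# centre (even-symmetric digital tubes are degenerate for thinning)
tube_mask <- function(r = 4, L = 60, pad = 4, margin = 3) {
  cx <- ceiling(r) + pad + 1
  side <- 2 * cx - 1
  arr <- array(FALSE, c(side, side, L))
  d2 <- (row(matrix(0, side, side)) - cx)^2 + (col(matrix(0, side, side)) - cx)^2
  m <- d2 <= r^2
  for (k in (margin + 1):(L - margin)) arr[, , k] <- m
  list(mask = binary_volume(arr, c(1, 1, 1)), centre = cx,
       slices = (margin + 1):(L - margin))
}

# Y-shaped tube mask: stem along z splitting into two straight daughters
y_mask <- function(r = 3, L = 60) {
  arr <- array(FALSE, c(51, 51, L))
  paint_ball <- function(x, y, z) {
    i0 <- max(1, floor(x - r)); i1 <- min(51, ceiling(x + r))
    j0 <- max(1, floor(y - r)); j1 <- min(51, ceiling(y + r))
    k0 <- max(1, floor(z - r)); k1 <- min(L, ceiling(z + r))
    for (k in k0:k1) {
      d2 <- outer((i0:i1 - x)^2, (j0:j1 - y)^2, `+`) + (k - z)^2
      blk <- arr[i0:i1, j0:j1, k]
      blk[d2 <= r^2] <- TRUE
      arr[i0:i1, j0:j1, k] <<- blk
    }
  }
  for (z in seq(4, L / 2, by = 0.5)) paint_ball(26, 26, z)
  for (z in seq(L / 2, L - 4, by = 0.5)) {
    off <- (z - L / 2) * 0.55
    paint_ball(26 - off, 26, z)
    paint_ball(26 + off, 26, z)
  }
  binary_volume(arr, c(1, 1, 1))
}

# uniform single-vessel mesh
uniform_mesh <- function(r0 = 0.15, L = 10, spacing = 0.01) {
  make_stenosed_mesh1d(r0 = r0, severity = 0, length = L,
                       spacing = spacing)$mesh
}

# symmetric bifurcation mesh
bifurcation_mesh <- function(r_parent = 0.15, r_daughter = 0.12, L = 2,
                             spacing = 0.01) {
  mk <- function(L, r, parent, id) {
    n <- round(L / spacing) + 1
    list(x = seq(0, L, length.out = n), r0 = rep(r, n),
         parent = parent, id = id)
  }
  mesh1d(list(mk(L, r_parent, 0L, "p"),
              mk(L, r_daughter, 1L, "d1"),
              mk(L, r_daughter, 1L, "d2")), spacing)
}

# rigid-wall law: wave speed scaled up ~1000x so area changes are negligible
rigid_wall <- function() wall_law(k1 = 2e13, k3 = 8.65e11)

test_bed <- function(vessel = 1, R1 = 1.5e4, R2 = 8e4, R3 = 2e4)
  windkessel_bed(vessel, R1, R2, R3)
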