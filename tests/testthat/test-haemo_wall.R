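# Wall constitutive law, wave speed, perfusion targets and Murray
# distribution: scalar relations with closed-form oracles.

test_that("wave speed follows the exponential-radius law", {
  b <- blood_properties()
  w <- wall_law()
  # large-radius limit: sqrt(2 k3 / (3 rho))
  expect_equal(wave_speed(50), sqrt(2 * 8.65e5 / (3 * 1.06)), tolerance = 1e-6)
  expect_equal(wave_speed(0.1),
               sqrt(2 / (3 * 1.06) * (2e7 * exp(-22.53 * 0.1) + 8.65e5)),
               tolerance = 1e-12)
  r <- seq(0.02, 0.5, by = 0.01)
  expect_true(all(diff(wave_speed(r)) < 0))   # k2 < 0: decreasing
  expect_error(wave_speed(-1), "r0 > 0")
})

test_that("tube law matches its closed form and is monotone in area", {
  blood <- blood_properties()
  wall <- wall_law()
  A0 <- 0.07
  c0 <- wave_speed(sqrt(A0 / pi))
  expect_equal(tube_law(A0, A0), wall$Pext + wall$P0)
  # A = 4 A0 with b = 2: elastic term is 3 rho c0^2
  expect_equal(tube_law(4 * A0, A0) - wall$Pext - wall$P0,
               3 * blood$rho * c0^2, tolerance = 1e-12)
  As <- seq(0.2, 3, by = 0.1) * A0
  expect_true(all(diff(tube_law(As, A0)) > 0))
  expect_error(tube_law(-0.1, A0), "non-positive area")
  # viscoelastic term adds Gamma / A0^{3/2} * dA/dt
  wv <- wall_law(Gamma = 100)
  expect_equal(tube_law(A0, A0, wall = wv, dA_dt = 0.01) -
                 tube_law(A0, A0, wall = wv),
               100 / (A0 * sqrt(A0)) * 0.01)
})

test_that("MAP weighting and total coronary resistance are in CGS", {
  pt <- perfusion_targets()
  expect_equal(pt$MAP, (2 * 80 + 120) / 3)
  R <- total_resistance(perfusion_targets(Qcor_left = 1), "left")
  expect_equal(R, (280 / 3) * 1333.22, tolerance = 1e-12)   # 1.244e5
  expect_equal(total_resistance(perfusion_targets(Qcor_left = 2), "left"),
               R / 2)
  expect_error(total_resistance(perfusion_targets(Qcor_right = 0), "right"),
               "positive")
})

test_that("Murray power-law distribution splits flow and resistance", {
  mesh <- bifurcation_mesh(r_daughter = 0.12)
  beds <- distribute_terminals(mesh, Rcor = 1e5)
  f <- vapply(beds, `[[`, numeric(1), "fraction")
  expect_equal(sum(f), 1)
  expect_equal(f, c(0.5, 0.5))
  expect_equal(beds[[1]]$RTf, 2e5)
  # radii 0.1 and 0.2: flow ratio 2^2.27
  mk <- function(L, r, parent, id) list(x = seq(0, L, length.out = 11),
                                        r0 = rep(r, 11), parent = parent,
                                        id = id)
  m2 <- mesh1d(list(mk(1, 0.25, 0L, "p"), mk(1, 0.1, 1L, "a"),
                    mk(1, 0.2, 1L, "b")), spacing = 0.1)
  beds2 <- distribute_terminals(m2, Rcor = 1e5)
  f2 <- vapply(beds2, `[[`, numeric(1), "fraction")
  expect_equal(f2[2] / f2[1], 2^2.27, tolerance = 1e-10)
  expect_equal(f2, c(1, 2^2.27) / (1 + 2^2.27), tolerance = 1e-10)
  # single terminal: RTf = Rcor, R2/R3 split 0.79/0.21 of (RTf - R1)
  m1 <- uniform_mesh(spacing = 0.1, L = 1)
  b1 <- distribute_terminals(m1, Rcor = 1.244e5)[[1]]
  expect_equal(b1$RTf, 1.244e5)
  expect_equal(b1$R1 + b1$R2 + b1$R3, b1$RTf)
  expect_equal(b1$R2 / b1$R3, 0.79 / 0.21)
  expect_equal(b1$R1, 1.06 * wave_speed(0.15) / (pi * 0.15^2))
})

test_that("unphysical terminal impedance is rejected", {
  m1 <- uniform_mesh(spacing = 0.1, L = 1)
  expect_error(distribute_terminals(m1, Rcor = 10, wall = rigid_wall()),
               "characteristic impedance exceeds bed resistance")
})

test_that("windkessel bed reaches the steady series-resistance identity", {
  bed <- test_bed()
  st <- NULL
  for (i in 1:400) {
    up <- bed_step(bed, st, Q_in = 1, dt = 0.05, t = 0.05 * i)
    st <- up$state
  }
  Rtot <- bed$R1 + bed$R2 + bed$R3
  expect_lt(abs((up$P_in - bed$Pven) - Rtot) / Rtot, 1e-3)
})

test_that("windkessel bed stays at rest and reacts to ventricular compression", {
  bed <- windkessel_bed(1, 1.5e4, 8e4, 2e4,
                        PLV = function(t) ifelse(t >= 0.1, 5e4, 0))
  # Q = 0, constant PLV, states at Pven: equilibrium
  rest <- bed_step(test_bed(), c(test_bed()$Pven, test_bed()$Pven),
                   Q_in = 0, dt = 0.01, t = 0.01)
  expect_equal(rest$state, c(test_bed()$Pven, test_bed()$Pven),
               tolerance = 1e-10)
  # a PLV step at fixed inflow raises the coupling pressure (the
  # intramyocardial compression opposing forward flow into the bed)
  st <- c(bed$Pven + 1 * (bed$R2 + bed$R3), bed$Pven + 1 * bed$R3)
  before <- bed_step(bed, st, Q_in = 1, dt = 0.005, t = 0.05)
  after <- bed_step(bed, before$state, Q_in = 1, dt = 0.005, t = 0.105)
  expect_gt(after$P_in, before$P_in)
})
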