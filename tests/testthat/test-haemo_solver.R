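# Coupled 1D-0D solver: closed-form oracles, conservation, symmetry,
# convergence order and cFFR behaviour.

test_that("steady viscous pressure drop matches the closed form", {
  # near-rigid tube: Delta P = 22 pi mu Q L / A^2
  for (r in c(0.1, 0.15, 0.2)) {
    mesh <- uniform_mesh(r0 = r, L = 10)
    sol <- solve_1d0d(mesh, 1.0, list(test_bed()), wall = rigid_wall(),
                      mode = "steady")
    A <- pi * r^2
    dp_ref <- 22 * pi * 0.04 * 1 * 10 / A^2
    dp <- sol$P_mean[1] - sol$P_mean[length(sol$P_mean)]
    expect_lt(abs(dp - dp_ref) / dp_ref, 0.01)
  }
})

test_that("zero viscosity gives zero steady loss and cFFR of 1", {
  mesh <- uniform_mesh()
  sol <- solve_1d0d(mesh, 1.0, list(test_bed()),
                    blood = blood_properties(mu = 0), mode = "steady")
  expect_lt(max(abs(sol$P_mean - sol$P_mean[1])) / sol$P_mean[1], 1e-10)
  cffr <- vapply(seq_len(nrow(sol$nodes)), function(n)
    compute_cffr(sol, n)$cffr, numeric(1))
  expect_true(all(abs(cffr - 1) < 1e-6))
})

test_that("steady outlet pressure satisfies the Windkessel series identity", {
  mesh <- uniform_mesh(L = 2)
  bed <- test_bed()
  sol <- solve_1d0d(mesh, 1.0, list(bed), blood = blood_properties(mu = 0),
                    mode = "steady")
  Pout <- sol$P_mean[length(sol$P_mean)]
  expect_lt(abs((Pout - bed$Pven) - 1.0 * (bed$R1 + bed$R2 + bed$R3)) /
              (bed$R1 + bed$R2 + bed$R3), 1e-3)
})

test_that("junction mass balance holds to 1e-8 through a pulsatile run", {
  mesh <- bifurcation_mesh(L = 1.5)
  plv <- default_plv_waveform("left")
  beds <- distribute_terminals(mesh, total_resistance(perfusion_targets(),
                                                      "left"), PLV = plv)
  sol <- solve_1d0d(mesh, default_inflow_waveform("left"), beds,
                    config = solver_config(dt = 2e-3, cycles = 1))
  expect_lt(sol$junction_imbalance, 1e-8)
})

test_that("a symmetric bifurcation splits flow exactly evenly", {
  mesh <- bifurcation_mesh()
  beds <- distribute_terminals(mesh, 1.244e5)
  sol <- solve_1d0d(mesh, 2.0, beds, mode = "steady")
  q1 <- sol$Q_mean[sol$nodes$vessel == 2]
  q2 <- sol$Q_mean[sol$nodes$vessel == 3]
  expect_lt(max(abs(q1 - q2)) / max(abs(q1)), 1e-8)
})

test_that("temporal accuracy is second order (error ratio ~4 when dt halves)", {
  mesh <- uniform_mesh(L = 2)
  qf <- function(t) 2.5 * (1 + 0.3 * sin(2 * pi * t / 0.8))
  attr(qf, "period") <- 0.8
  run <- function(nstep) solve_1d0d(mesh, qf, list(test_bed()),
                                    config = solver_config(dt = 0.8 / nstep,
                                                           cycles = 1)
                                    )$inlet_series
  ref <- run(3200)
  e1 <- sqrt(mean((run(200) - ref[seq(16, 3200, 16)])^2))
  e2 <- sqrt(mean((run(400) - ref[seq(8, 3200, 8)])^2))
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
})

test_that("the pulsatile solution becomes periodic within tolerance", {
  mesh <- uniform_mesh(L = 2)
  plv <- default_plv_waveform("left")
  beds <- distribute_terminals(mesh, total_resistance(perfusion_targets(),
                                                      "left"), PLV = plv)
  sol <- solve_1d0d(mesh, default_inflow_waveform("left"), beds,
                    config = solver_config(dt = 2e-3, cycles = 5))
  expect_lt(min(sol$periodicity), 0.005)
})

test_that("cFFR decreases downstream and with stenosis severity", {
  # monotone non-increasing along an unbranched vessel at steady flow
  mesh <- uniform_mesh()
  sol <- solve_1d0d(mesh, 1.0, list(test_bed()), mode = "steady")
  cffr <- vapply(seq_len(nrow(sol$nodes)), function(n)
    compute_cffr(sol, n)$cffr, numeric(1))
  expect_true(all(diff(cffr) <= 1e-12))
  expect_equal(cffr[1], 1)
  # strictly decreasing across severity, everything else fixed
  vals <- vapply(c(0, 0.3, 0.5, 0.7), function(sev) {
    m <- make_stenosed_mesh1d(r0 = 0.15, severity = sev)$mesh
    beds <- distribute_terminals(m, total_resistance(
      perfusion_targets(Qcor_left = 1), "left"))
    s <- solve_1d0d(m, 1.0, beds, mode = "steady")
    compute_cffr(s, list(vessel = "tube", x = 9.5))$cffr
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("cFFR location handling validates inputs", {
  mesh <- uniform_mesh(L = 2)
  sol <- solve_1d0d(mesh, 1.0, list(test_bed()), mode = "steady")
  expect_error(compute_cffr(sol, 10000), "location outside mesh")
  expect_error(compute_cffr(sol, list(vessel = "nope", x = 1)),
               "valid vessel ids")
  r <- compute_cffr(sol, list(vessel = "tube", x = 1))
  expect_equal(r$x, 1, tolerance = 0.01)
  expect_equal(compute_cffr(sol, 1)$cffr, 1)
})

test_that("solver aborts on non-positive areas with a node id", {
  mesh <- uniform_mesh(L = 1, spacing = 0.05)
  # absurd inflow collapses the tube
  expect_error(solve_1d0d(mesh, -1e5, list(test_bed()), mode = "steady"),
               "Newton|area")
})
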