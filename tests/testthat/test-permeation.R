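test_that("a monotonic pass through the gate counts one up-crossing", {
  traj <- traj_from_z(seq(-50, 50, length.out = 201))
  cc <- countCrossings(traj, -5, 5)
  expect_equal(cc@nUp, 1L)
  expect_equal(cc@nDown, 0L)
})

test_that("oscillation inside the gate produces no crossings", {
  z <- 4 * sin(seq(0, 20 * pi, length.out = 500))   # bounded in (-4, 4)
  cc <- countCrossings(traj_from_z(z), -5, 5)
  expect_equal(cc@nUp + cc@nDown, 0L)
})

test_that("partial gate entries and retreats are not double-counted", {
  # below -> inside -> below -> through: exactly one up-crossing
  z <- c(-10, -2, -8, -1, -7, 0, 6, 10)
  cc <- countCrossings(traj_from_z(z), -5, 5)
  expect_equal(cc@nUp, 1L)
  expect_equal(cc@nDown, 0L)
  # symmetric down passage
  ccd <- countCrossings(traj_from_z(rev(z)), -5, 5)
  expect_equal(ccd@nDown, 1L)
  expect_equal(ccd@nUp, 0L)
})

test_that("periodic boundary jumps are not mistaken for gate crossings", {
  Lz <- 100
  # ion jittering across the periodic boundary at +/-50, never near the gate
  z <- rep(c(49, -49), 50)
  cc <- countCrossings(traj_from_z(z, box = c(40, 40, Lz)), -5, 5)
  expect_equal(cc@nUp + cc@nDown, 0L)
  # steady upward drift from below the gate: each of the five circuits
  # crosses the gate exactly once
  z2 <- ((seq(-50, -50 + 5 * Lz, by = 2) + Lz / 2) %% Lz) - Lz / 2
  cc2 <- countCrossings(traj_from_z(z2, box = c(40, 40, Lz)), -5, 5)
  expect_equal(cc2@nUp, 5L)
  expect_equal(cc2@nDown, 0L)
})

test_that("gate wider than the box is rejected", {
  expect_error(countCrossings(traj_from_z(c(0, 1), box = c(40, 40, 8)),
                              -5, 5), "wider")
})

test_that("hysteresis net count tracks the single-plane oracle on drift", {
  set.seed(31)
  n_walk <- 400
  Lz <- 400   # wide box so no walk reaches a periodic image of the gate
  steps <- matrix(rnorm(300 * n_walk, mean = 0.5, sd = 1.0), 300)
  zu <- apply(steps, 2, cumsum) - 50
  zw <- ((zu + Lz / 2) %% Lz) - Lz / 2
  traj <- traj_from_z(zw, box = c(40, 40, Lz))
  cc <- countCrossings(traj, -5, 5)
  oracle_net <- single_plane_net(zu, 0)
  net <- cc@nUp - cc@nDown
  expect_lte(abs(net - oracle_net), max(2, 0.02 * abs(oracle_net)))
})

test_that("current converts net crossings with the elementary charge", {
  expect_equal(ionicCurrent(7L, 160, 1), 7 * 1.602176634e-19 / 160e-9 * 1e9,
               tolerance = 1e-12)
  expect_equal(round(ionicCurrent(7L, 160, 1), 5), 0.00701)
  expect_equal(ionicCurrent(0L, 100, 1), 0)
  expect_lt(ionicCurrent(5L, 100, -1), 0)
})

test_that("conductance reproduces the current-to-pS chain", {
  est <- conductance(0.007, 200)
  expect_equal(est@g, 35)
  expect_equal(est@gCorrected, 35 / 3, tolerance = 1e-12)
  expect_equal(round(est@gCorrected, 2), 11.67)
  est2 <- conductance(0.023 + 0.001, 200)
  expect_equal(est2@g, 120)
  expect_error(conductance(0.01, 0), "non-zero")
})

test_that("selectivity ratios flag unbounded and undefined cases", {
  expect_equal(as.numeric(selectivityRatio(0.023, 0.001)), 23)
  r <- selectivityRatio(0.02, 0)
  expect_true(is.infinite(r))
  expect_equal(attr(r, "flag"), "unbounded")
  r0 <- selectivityRatio(0, 0)
  expect_true(is.nan(r0))
  expect_equal(attr(r0, "flag"), "undefined")
  expect_equal(as.numeric(selectivityRatio(0.01, -0.01)), 1)
})

test_that("one resident ion in a 1660.5 A^3 bin reads 1 M", {
  r <- 10
  dz <- 1660.5 / (pi * r^2)
  traj <- traj_from_z(rep(0, 50), box = c(40, 40, 60))
  prof <- concentrationProfile(traj, radius = r,
                               zEdges = c(-dz / 2, dz / 2, 3 * dz))
  expect_equal(unname(prof@molarity[1, "NA"]), 1.0, tolerance = 1e-4)
  expect_equal(unname(prof@molarity[2, "NA"]), 0)
  expect_error(concentrationProfile(traj, 0, c(-1, 1)), "radius")
})

test_that("a uniform field-free gas recovers its bulk concentration", {
  traj <- simulateIonTrajectory(nIons = 200, voltage = 0, D = 0.5,
                                poreRadius = 20, poreLength = 80,
                                dt = 2, nSteps = 4000, stride = 4,
                                seed = 8)
  bulk_M <- 200 / (pi * 20^2 * 80) / (6.02214076e23 * 1e-27)
  prof <- concentrationProfile(traj, radius = 20,
                               zEdges = seq(-40, 40, by = 10))
  m <- prof@molarity[, "NA"]
  expect_true(all(abs(m - bulk_M) < 0.1 * bulk_M))
  expect_equal(mean(m), bulk_M, tolerance = 0.02)
})

test_that("density-flux maps localise a stationary ion and conserve mass", {
  traj <- traj_from_z(rep(10.2, 30), box = c(40, 40, 60))
  m <- densityFluxMap(traj, spacing = 2)
  expect_equal(sum(m@density > 0), 1L)
  expect_equal(sum(m@density) * 2^3, 1, tolerance = 1e-9)
  expect_equal(max(abs(m@flux)), 0)
})

test_that("a constant-velocity ion yields axial flux at its speed", {
  v <- 0.25   # A/ps with dt = 1
  z <- seq(-25, 25, by = v)
  traj <- traj_from_z(z, box = c(40, 40, 60))
  m <- densityFluxMap(traj, spacing = 4)
  fz <- m@flux[, , , 3]
  expect_true(all(abs(fz[fz != 0] - v) < 1e-9))
  # mass conservation on a diffusing cloud
  traj2 <- simulateIonTrajectory(nIons = 50, voltage = 0, D = 0.3,
                                 poreRadius = 15, poreLength = 50,
                                 dt = 1, nSteps = 500, stride = 5, seed = 2)
  m2 <- densityFluxMap(traj2, spacing = 3)
  expect_equal(sum(m2@density) * 3^3, 50, tolerance = 0.01)
  expect_error(densityFluxMap(traj2, 1000), "larger")
})

test_that("block-averaged currents vanish without an applied field", {
  traj <- simulateIonTrajectory(nIons = 120, voltage = 0, D = 0.2,
                                poreRadius = 10, poreLength = 60,
                                dt = 2, nSteps = 10000, stride = 5,
                                seed = 12)
  mc <- measureCurrent(traj, -5, 5, nBlocks = 20)
  expect_lt(abs(mc$I), 3 * mc$se + 1e-12)
})
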