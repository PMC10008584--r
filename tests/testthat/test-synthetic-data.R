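test_that("generators are deterministic for a fixed seed", {
  a <- simulateMetadata(nParticles = 30, pPLN = 0.4, seed = 99)
  b <- simulateMetadata(nParticles = 30, pPLN = 0.4, seed = 99)
  expect_identical(records(a$table), records(b$table))
  expect_identical(a$groundTruth$states, b$groundTruth$states)

  t1 <- simulateIonTrajectory(nIons = 10, nSteps = 200, stride = 5,
                              seed = 7)
  t2 <- simulateIonTrajectory(nIons = 10, nSteps = 200, stride = 5,
                              seed = 7)
  expect_identical(t1@z, t2@z)
})

test_that("degenerate state fractions produce pure tables", {
  sim <- simulateMetadata(nParticles = 20, pPLN = 1, seed = 3)
  st <- assignStates(sim$table, ClassStateMap(), verbose = FALSE)
  expect_true(all(records(st)$state == "PLN"))
  expect_true(all(sim$groundTruth$states == "PLN"))
})

test_that("simulated tables mirror the layout of expandSymmetry", {
  sim <- simulateMetadata(nParticles = 15, pPLN = 0.5, seed = 5)
  rec <- records(sim$table)
  expect_true(all(table(rec$particle_id) == 12L))
  expect_setequal(unique(rec$rot_deg), seq(0, 300, by = 60))
  expect_equal(rec$position_index,
               as.integer(round(rec$rot_deg / 60) %% 6))
  expect_equal(rec$hemichannel_index, as.integer(rec$tilt_flipped))
})

test_that("the overall PLN fraction tracks the generator truth", {
  sim <- simulateMetadata(nParticles = 8000, pPLN = 0.57, seed = 1)
  st <- assignStates(sim$table, ClassStateMap(), verbose = FALSE)
  est <- estimateStateFraction(st)
  expect_lt(est@ciLow, 0.57)
  expect_gt(est@ciHigh, 0.57)
})

test_that("exact ring probabilities reduce to Bernoulli products at J = 0", {
  d <- exactRingDistribution(0.3, 0)
  k <- vapply(names(d), function(s) sum(strsplit(s, "")[[1]] == "P"),
              numeric(1))
  expect_equal(unname(d), unname(0.3^k * 0.7^(6 - k)), tolerance = 1e-12)
  expect_equal(sum(exactRingDistribution(0.57, 0.8)), 1, tolerance = 1e-12)
  # the solved field reproduces the requested marginal
  marg <- sum(exactRingDistribution(0.57, 0.8) *
                (substr(names(exactRingDistribution(0.57, 0.8)), 1, 1) == "P"))
  expect_equal(marg, 0.57, tolerance = 1e-5)
})

test_that("strong coupling drives rings towards uniformity", {
  d <- exactRingDistribution(0.5, 3)
  expect_gt(d[["PPPPPP"]] + d[["FFFFFF"]], 0.95)
  sim <- simulateMetadata(nParticles = 300, pPLN = 0.5, couplingJ = 3,
                          seed = 13)
  uniform <- rowSums(sim$groundTruth$states == "PLN") %in% c(0L, 6L)
  expect_gt(mean(uniform), 0.9)
})

test_that("the Gibbs sampler matches exact enumeration in total variation", {
  settings <- list(c(0.57, 0.8), c(0.3, -0.5), c(0.5, 1.5))
  code_of <- vapply(0:63, connexon:::.codeToString, character(1))
  set.seed(41)
  for (s in settings) {
    p <- s[1]; J <- s[2]
    ex <- exactRingDistribution(p, J)
    h <- connexon:::.isingFieldForMarginal(p, J)
    draw <- connexon:::.gibbsRings(200000L, h, J, 500L)
    emp <- tabulate(as.integer(draw %*% 2L^(0:5)) + 1L, 64) / nrow(draw)
    tv <- 0.5 * sum(abs(emp - unname(ex[match(code_of, names(ex))])))
    expect_lt(tv, 0.01)
  }
})

test_that("unattainable marginals are refused", {
  expect_error(simulateMetadata(10, pPLN = 1, couplingJ = 2, seed = 1),
               "unattainable")
})

test_that("closed-form current follows the Nernst-Planck arithmetic", {
  # hand computation: v = D qE/kT; I = q c A v e
  D <- 0.1
  qEkT <- 0.01                       # 1/A
  A <- 100                           # A^2 -> radius sqrt(100/pi)
  r <- sqrt(A / pi)
  Lz <- 60
  conc <- 6.02214076e-4              # ions/A^3 (~1 M)
  n <- conc * A * Lz
  # choose voltage to realise qE/kT = 0.01/A at 300 K
  kT <- 8.617333262e-5 * 300
  V_mV <- qEkT * kT * Lz * 1e3
  I <- closedFormCurrent(nIons = n, charge = 1, D = D, poreRadius = r,
                         poreLength = Lz, voltage = V_mV)
  expect_equal(I, 9.6e-3, tolerance = 0.01)
  expect_equal(I, 1 * conc * A * (D * qEkT) * 1.602176634e-19 * 1e21,
               tolerance = 1e-10)
  # linearity and null
  expect_equal(closedFormCurrent(n, D = 2 * D, poreRadius = r,
                                 poreLength = Lz, voltage = V_mV), 2 * I,
               tolerance = 1e-12)
  expect_equal(closedFormCurrent(n, voltage = 0), 0)
  expect_error(closedFormCurrent(n, boxZ = 120, poreLength = 60),
               "uniform")
  expect_error(closedFormCurrent(
    n, wells = data.frame(z = 0, depth_kT = 2, width = 5)), "wells")
})

test_that("field-free mean-square displacement recovers 2D", {
  traj <- simulateIonTrajectory(nIons = 50, voltage = 0, D = 0.1,
                                poreRadius = 60, poreLength = 300,
                                dt = 1, nSteps = 2000, stride = 1,
                                seed = 23)
  zu <- connexon:::.unwrapZ(traj@z, traj@box[3])
  Dhat <- var(as.vector(diff(zu))) / (2 * traj@dt)
  expect_equal(Dhat, 0.1, tolerance = 0.05)
})

test_that("a deep Gaussian well concentrates occupancy at its centre", {
  wells <- data.frame(z = 15, depth_kT = 3, width = 4)
  traj <- simulateIonTrajectory(nIons = 80, voltage = 0, D = 0.2,
                                poreRadius = 10, poreLength = 80,
                                wells = wells, dt = 1, nSteps = 20000,
                                stride = 20, seed = 29)
  prof <- concentrationProfile(traj, radius = 10,
                               zEdges = seq(-40, 40, by = 8))
  centres <- head(prof@zEdges, -1) + 4
  well_bin <- which.min(abs(centres - 15))
  far_bins <- which(abs(centres - 15) > 20)
  expect_equal(unname(which.max(prof@molarity[, 1])), well_bin)
  # Boltzmann enhancement exp(U/kT) at the well floor, within a factor ~2
  enh <- prof@molarity[well_bin, 1] / mean(prof@molarity[far_bins, 1])
  expect_gt(enh, exp(3) / 2.5)
})

test_that("unstable drift settings and inconsistent ion counts are caught", {
  expect_error(simulateIonTrajectory(nIons = 5, voltage = 8000, D = 5,
                                     poreRadius = 10, poreLength = 10,
                                     dt = 10, nSteps = 10, seed = 1),
               "unstable")
  expect_warning(simulateIonTrajectory(nIons = 5, concentration = 5,
                                       nSteps = 50, seed = 1),
                 "differs")
})

test_that("trajectories round-trip through the columnar text format", {
  traj <- simulateIonTrajectory(nIons = c(4, 3), species = c("NA", "CL"),
                                charge = c(1, -1), nSteps = 100,
                                stride = 10, voltage = 150, seed = 77)
  f <- withr::local_tempfile(fileext = ".txt")
  writeTrajectory(traj, f)
  back <- readTrajectory(f)
  expect_equal(back@z, traj@z, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back@species, traj@species)
  expect_equal(back@charge, traj@charge)
  expect_equal(back@voltage, 150)
  expect_equal(back@box, traj@box)
})

test_that("toy pores round-trip through PDB at coordinate precision", {
  toy <- simulateToyPore(data.frame(z = c(0, 20), radius = c(10, 6),
                                    nAtoms = 12))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeAtomsPDB(toy, f)
  back <- loadStructure(f)
  expect_equal(nrow(back@coords), nrow(toy@coords))
  expect_equal(back@coords, toy@coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(simulateToyPore(data.frame(z = 0, radius = -1, nAtoms = 12)),
               "radius")
  expect_error(simulateToyPore(data.frame(z = 0, radius = 5, nAtoms = 4)),
               "at least 8")
})
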