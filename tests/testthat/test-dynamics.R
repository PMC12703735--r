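nveConfig <- function(nSteps, dt = 0.5, stride = 10L) {
  cfg <- defaultConfig()$md
  cfg$temperature <- 0
  cfg$thermostat <- "none"
  cfg$n_steps <- nSteps
  cfg$dt <- dt
  cfg$save_stride <- stride
  cfg
}

displacedHarmonic <- function(dx = 0.1) {
  hd <- harmonicDiatomicFixture()
  x <- atomCoords(hd@structure)
  x[2, 1] <- x[2, 1] + dx
  list(spec = hd, start = Structure(atomSpecies(hd@structure), x, id = "hd0"))
}

test_that("NVE conserves total energy on the harmonic diatomic", {
  f <- displacedHarmonic()
  tr <- runMD(f$spec@calculator, f$start, nveConfig(20000))
  etot <- tr@ePot + tr@eKin
  expect_lt(max(abs(etot - etot[1])), 1e-6)
  expect_lt(energyDrift(tr), 1e-4)
})

test_that("energy error scales as dt^2 on the harmonic fixture", {
  f <- displacedHarmonic()
  d1 <- energyDrift(runMD(f$spec@calculator, f$start, nveConfig(4000, 0.5, 4L)))
  d2 <- energyDrift(runMD(f$spec@calculator, f$start, nveConfig(8000, 0.25, 8L)))
  expect_gt(d1 / d2, 3)
  expect_lt(d1 / d2, 5)
})

test_that("a zero-temperature start at the minimum stays static", {
  w <- waterFixture()
  tr <- runMD(w@calculator, w@structure, nveConfig(200, stride = 20L))
  drift <- max(abs(tr@positions - c(tr@positions[, , 1])))
  expect_lt(drift, 1e-10)
})

test_that("MD is deterministic under seed and frames are uniformly spaced", {
  w <- waterFixture()
  cfg <- defaultConfig()$md
  cfg$temperature <- 300; cfg$thermostat <- "langevin"; cfg$n_steps <- 400L
  t1 <- runMD(w@calculator, w@structure, cfg)
  t2 <- runMD(w@calculator, w@structure, cfg)
  expect_identical(t1@positions, t2@positions)
  expect_identical(t1@ePot, t2@ePot)
  expect_equal(diff(t1@times), rep(cfg$dt * cfg$save_stride, nFrames(t1) - 1))
})

test_that("langevin thermostat equilibrates toward the setpoint", {
  ## a short plumbing check; the tight 5% band over 50 ps lives in the
  ## acceptance suite
  w <- waterFixture()
  cfg <- defaultConfig()$md
  cfg$temperature <- 450; cfg$thermostat <- "langevin"; cfg$friction <- 0.02
  cfg$n_steps <- 20000L; cfg$save_stride <- 20L; cfg$seed <- 5L
  tr <- runMD(w@calculator, w@structure, cfg)
  avgT <- mean(tr@temperature[-(1:200)])
  expect_gt(avgT, 0.85 * 450)
  expect_lt(avgT, 1.15 * 450)
})

test_that("force blow-up aborts with the stable prefix", {
  co <- diatomicFixture()
  start <- Structure(atomSpecies(co@structure),
                     rbind(c(0, 0, 0), c(0.35, 0, 0)))  # deep repulsive wall
  cfg <- nveConfig(2000, stride = 1L)
  expect_warning(tr <- runMD(co@calculator, start, cfg, fAbort = 50),
                 "blow-up")
  expect_lt(nFrames(tr), 2001)
})

test_that("minimization reaches the Morse minimum from a stretched start", {
  co <- diatomicFixture()
  r0 <- co@calculator@bonds$r0[1]
  start <- Structure(atomSpecies(co@structure),
                     rbind(c(0, 0, 0), c(1.2 * r0, 0, 0)))
  opt <- minimizeStructure(co@calculator, start, fTol = 1e-8)
  expect_equal(internalCoordinate(atomCoords(opt), c(1, 2)), r0,
               tolerance = 1e-4)

  ## starting at the minimum returns essentially the input
  again <- minimizeStructure(co@calculator, opt, fTol = 1e-6)
  expect_lt(max(abs(atomCoords(again) - atomCoords(opt))), 1e-6)
})

test_that("a frozen bond is preserved exactly through minimization", {
  co <- diatomicFixture()
  opt <- minimizeStructure(co@calculator, co@structure,
                           frozen = list(idx = c(1L, 2L), value = 2.0),
                           fTol = 1e-6)
  expect_equal(internalCoordinate(atomCoords(opt), c(1, 2)), 2.0,
               tolerance = 1e-6)

  w <- waterFixture()
  optA <- minimizeStructure(w@calculator, w@structure,
                            frozen = list(idx = c(2L, 1L, 3L), value = 1.9),
                            fTol = 1e-5)
  expect_equal(internalCoordinate(atomCoords(optA), c(2, 1, 3)), 1.9,
               tolerance = 1e-6)
})

test_that("relaxed bond scan finds the minimum at the grid point nearest r0", {
  co <- diatomicFixture()
  r0 <- co@calculator@bonds$r0[1]
  grid <- seq(0.8, 2.0, by = 0.05)
  sc <- relaxedScan(co@calculator, co@structure,
                    list(kind = "bond", idx = c(1L, 2L), grid = grid))
  expect_true(all(sc$points$converged))
  best <- sc$points$value[which.min(sc$points$energy)]
  expect_equal(best, grid[which.min(abs(grid - r0))])

  ## single-point scan returns one minimized energy
  one <- relaxedScan(co@calculator, co@structure,
                     list(kind = "bond", idx = c(1L, 2L), grid = r0))
  expect_equal(nrow(one$points), 1)
  expect_equal(one$points$energy, -co@calculator@bonds$De[1],
               tolerance = 1e-8)
})

test_that("relaxed scans are invariant to rigid placement of the input", {
  co <- diatomicFixture()
  grid <- seq(1.0, 1.8, by = 0.1)
  spec <- list(kind = "bond", idx = c(1L, 2L), grid = grid)
  e1 <- relaxedScan(co@calculator, co@structure, spec)$points$energy
  moved <- Structure(atomSpecies(co@structure),
                     sweep(atomCoords(co@structure), 2, c(-5, 3, -2)))
  e2 <- relaxedScan(co@calculator, moved, spec)$points$energy
  expect_equal(e1, e2, tolerance = 1e-7)
})

test_that("ethane-like torsion profile is 3-fold periodic", {
  e <- ethaneFixture()
  grid <- seq(0, 360, by = 15)
  sc <- relaxedScan(e@calculator, e@structure,
                    list(kind = "dihedral", idx = c(3L, 1L, 2L, 6L),
                         grid = grid))
  expect_true(all(sc$points$converged))
  rel <- relativeEnergies(sc$points$energy)
  shifted <- rel[match((grid + 120) %% 360, grid %% 360)]
  expect_equal(rel, shifted, tolerance = 0.02 * max(rel))
  expect_gt(max(rel), 0.05)   # a real barrier, not numerical noise
})
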