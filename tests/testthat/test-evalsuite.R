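test_that("relative energies honor both reference conventions", {
  expect_equal(relativeEnergies(c(-5, -3, -4), "lowest"), c(0, 2, 1))
  expect_equal(relativeEnergies(c(-5, -3, -4), "first"), c(0, 2, 1))
  expect_equal(relativeEnergies(c(2, 2, 2), "lowest"), c(0, 0, 0))
  expect_equal(relativeEnergies(c(3, 1, 5), "first"), c(0, -2, 2))
})

test_that("error statistics match a direct recomputation", {
  expect_equal(errorStats(1:5, 1:5), list(rmse = 0, mae = 0))
  expect_equal(errorStats(3:7, 1:5), list(rmse = 2, mae = 2))
  set.seed(8)
  p <- rnorm(20); r <- rnorm(20)
  st <- errorStats(p, r)
  expect_equal(st$rmse, sqrt(mean((p - r)^2)), tolerance = 1e-12)
  expect_equal(st$mae, mean(abs(p - r)), tolerance = 1e-12)
  expect_error(errorStats(1:3, 1:4), "equal length")
})

test_that("cutoff tables group conformers as a brute-force filter does", {
  set.seed(12)
  ref <- c(runif(60, 0, 120), runif(30, 120, 350), runif(10, 350, 600))
  pred <- list(m1 = ref + rnorm(100, sd = 3), m2 = ref + rnorm(100, sd = 9))
  cuts <- c(50, 100, 200, 300, 400, Inf)

  cum <- cutoffRmse(ref, pred, cuts, "cumulative")
  int <- cutoffRmse(ref, pred, cuts, "interval")

  for (m in names(pred)) for (ci in seq_along(cuts)) {
    idx <- which(ref < cuts[ci])
    row <- cum@table[cum@table$method == m & cum@table$cutoff == cuts[ci], ]
    expect_equal(row$n, length(idx))
    expect_equal(row$rmse, sqrt(mean((pred[[m]][idx] - ref[idx])^2)),
                 tolerance = 1e-12)
    lo <- c(0, head(cuts, -1))[ci]
    idx2 <- which(ref >= lo & ref < cuts[ci])
    row2 <- int@table[int@table$method == m & int@table$cutoff == cuts[ci], ]
    expect_equal(row2$n, length(idx2))
  }

  ## cumulative counts never decrease with the cutoff
  n1 <- cum@table$n[cum@table$method == "m1"]
  expect_true(all(diff(n1) >= 0))

  ## exact predictions give zero RMSE everywhere
  z <- cutoffRmse(ref, list(exact = ref), cuts, "cumulative")
  expect_true(all(z@table$rmse == 0))

  ## a single infinite cutoff degenerates to the plain error statistics
  one <- cutoffRmse(ref, pred["m1"], Inf, "cumulative")
  expect_equal(one@table$rmse, errorStats(pred$m1, ref)$rmse)

  ## empty groups are flagged, not zero
  e <- cutoffRmse(rep(75, 5), list(m = rep(75, 5)), c(50, 100), "cumulative")
  expect_true(is.na(e@table$rmse[e@table$cutoff == 50]))
})

test_that("trajectory cross-evaluation cancels constant offsets", {
  w <- waterFixture()
  cfg <- defaultConfig()$md
  cfg$temperature <- 300; cfg$thermostat <- "langevin"; cfg$n_steps <- 300L
  tr <- runMD(w@calculator, w@structure, cfg)

  ## self-evaluation is exact
  self <- suppressWarnings(crossEvaluate(tr, w@calculator))
  expect_lt(self$rmse, 1e-10)

  ## shifting every atomic reference moves totals but not relative series
  shifted <- w@calculator
  shifted@atomicRef <- shifted@atomicRef + 2
  off <- suppressWarnings(crossEvaluate(tr, shifted))
  expect_lt(off$rmse, 1e-10)

  expect_warning(crossEvaluate(tr, w@calculator, nFrames = 1e5),
                 "frames available")
})

analyticDiatomicTrajectory <- function(k = 1.0, r0 = 1.2, massFactor = 1,
                                       nfr = 4096, dt = 2, A = 0.05) {
  m <- atomicMasses(c("C", "C")) * massFactor
  mu <- prod(m) / sum(m)
  om <- sqrt(k * ACC_CONV / mu)
  tt <- (0:(nfr - 1)) * dt
  pos <- array(0, c(2, 3, nfr)); vel <- array(0, c(2, 3, nfr))
  for (i in seq_len(nfr)) {
    d <- A * cos(om * tt[i]); vd <- -A * om * sin(om * tt[i])
    pos[, , i] <- rbind(c(-(r0 + d) / 2, 0, 0), c((r0 + d) / 2, 0, 0))
    vel[, , i] <- rbind(c(-vd / 2, 0, 0), c(vd / 2, 0, 0))
  }
  ek <- vapply(seq_len(nfr), function(i)
    0.5 * sum(m * rowSums(vel[, , i]^2)) / ACC_CONV, 0)
  new("Trajectory", species = c("C", "C"), masses = m, dt = dt, times = tt,
      positions = pos, velocities = vel,
      ePot = 0.5 * k * (A * cos(om * tt))^2, eKin = ek, temperature = ek)
}

test_that("VDOS peaks at the closed-form harmonic wavenumber", {
  k <- 1.0
  tr <- analyticDiatomicTrajectory(k)
  mu <- prod(tr@masses) / sum(tr@masses)
  expected <- sqrt(k * ACC_CONV / mu) / (2 * pi * 2.99792458e-5)
  sp <- vdos(tr, smoothingWidth = 20, segment = "all")
  peak <- sp@wavenumber[which.max(sp@intensity)]
  bin <- diff(sp@wavenumber[1:2])
  expect_lt(abs(peak - expected), bin + 1e-9)
  expect_equal(max(sp@intensity), 1)
})

test_that("doubling the masses shifts the VDOS peak by 1/sqrt(2)", {
  sp1 <- vdos(analyticDiatomicTrajectory(massFactor = 1), segment = "all")
  sp2 <- vdos(analyticDiatomicTrajectory(massFactor = 2), segment = "all")
  p1 <- sp1@wavenumber[which.max(sp1@intensity)]
  p2 <- sp2@wavenumber[which.max(sp2@intensity)]
  bin <- diff(sp1@wavenumber[1:2])
  expect_lt(abs(p2 - p1 / sqrt(2)), bin + 1e-9)
})

test_that("VDOS peak location is stable under stride-2 subsampling", {
  tr <- analyticDiatomicTrajectory()
  keep <- seq(1, nFrames(tr), by = 2)
  tr2 <- new("Trajectory", species = tr@species, masses = tr@masses,
             dt = tr@dt * 2, times = tr@times[keep],
             positions = tr@positions[, , keep],
             velocities = tr@velocities[, , keep],
             ePot = tr@ePot[keep], eKin = tr@eKin[keep],
             temperature = tr@temperature[keep])
  p1 <- with(list(s = vdos(tr, segment = "all")),
             s@wavenumber[which.max(s@intensity)])
  s2 <- vdos(tr2, segment = "all")
  p2 <- s2@wavenumber[which.max(s2@intensity)]
  expect_lt(abs(p1 - p2), diff(s2@wavenumber[1:2]) + 1e-9)
})

test_that("zero velocities give a flat zero spectrum", {
  tr <- analyticDiatomicTrajectory(A = 0.05)
  tr@velocities[] <- 0
  sp <- vdos(tr, segment = "all")
  expect_true(all(sp@intensity == 0))
})

test_that("RDF of a rigid diatomic occupies a single bin at the bond length", {
  pos <- array(0, c(2, 3, 5))
  for (i in 1:5) pos[, , i] <- rbind(c(0, 0, 0), c(1.0, 0, 0))
  tr <- new("Trajectory", species = c("C", "O"),
            masses = atomicMasses(c("C", "O")), dt = 1, times = 0:4,
            positions = pos, velocities = array(0, c(2, 3, 5)),
            ePot = numeric(5), eKin = numeric(5), temperature = numeric(5))
  g <- rdf(tr, c("C", "O"), rMax = 2, nBins = 20)
  expect_equal(sum(g$counts > 0), 1)
  expect_equal(g$r[g$counts > 0], 1.05)   # the bin containing 1.0
  ## repeating a static frame equals the single-frame histogram shape
  expect_equal(g$g, rdf(tr, c("C", "O"), 2, 20)$g)
  expect_warning(rdf(tr, c("N", "N"), 2, 20), "no N-N pair")
})

test_that("low-temperature MD puts the first RDF peak at the Morse minimum", {
  co <- diatomicFixture()
  cfg <- defaultConfig()$md
  cfg$temperature <- 40; cfg$thermostat <- "langevin"; cfg$n_steps <- 3000L
  tr <- runMD(co@calculator, co@structure, cfg)
  g <- rdf(tr, c("C", "O"), rMax = 3, nBins = 60)
  peak <- g$r[which.max(g$g)]
  expect_lt(abs(peak - co@calculator@bonds$r0[1]), 3 / 60 + 1e-9)
})
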