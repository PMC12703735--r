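test_that("descriptors are invariant under rotation, translation, permutation", {
  tw <- twelveAtomFixture()
  st <- randomStructure(tw, seed = 21)
  cfg <- descriptorConfig()
  f0 <- featurize(st, cfg)$features
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- Structure(atomSpecies(st), atomCoords(st) %*% t(R) + 3.5)
  expect_lt(max(abs(featurize(rot, cfg)$features - f0)), 1e-10)

  ## swapping two hydrogens permutes rows and nothing else
  hi <- which(atomSpecies(st) == "H")[1:2]
  perm <- seq_len(nAtoms(st)); perm[hi] <- rev(hi)
  sw <- Structure(atomSpecies(st)[perm], atomCoords(st)[perm, ])
  expect_lt(max(abs(featurize(sw, cfg)$features[perm, ] - f0)), 1e-10)
})

test_that("isolated atoms have zero features and gradients", {
  far <- Structure(c("C", "C"), rbind(c(0, 0, 0), c(100, 0, 0)))
  fz <- featurize(far, descriptorConfig(), gradients = TRUE)
  expect_true(all(fz$features == 0))
  expect_true(all(fz$gradients == 0))
})

test_that("feature gradients match central differences", {
  w <- waterFixture()
  st <- randomStructure(w, seed = 31)
  cfg <- waterDcfg()
  fz <- featurize(st, cfg, gradients = TRUE)
  x0 <- atomCoords(st)
  h <- 1e-6
  for (a in 1:3) for (d in 1:3) {
    xp <- x0; xp[a, d] <- xp[a, d] + h
    xm <- x0; xm[a, d] <- xm[a, d] - h
    num <- (featurize(Structure(atomSpecies(st), xp), cfg)$features -
            featurize(Structure(atomSpecies(st), xm), cfg)$features) / (2 * h)
    expect_lt(max(abs(fz$gradients[, , a, d] - num)), 1e-6)
  }
})

test_that("dataset split is disjoint, exhaustive and deterministic", {
  recs <- waterRecords(10)
  sp <- splitDataset(recs, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  ids <- function(l) vapply(l, function(r) r@structure@id, "")
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$val)), ids(recs))
  sp2 <- splitDataset(recs, 0.8, seed = 4)
  expect_identical(ids(sp2$train), ids(sp$train))
  expect_error(splitDataset(recs[1], 0.8, 1), "at least 2")
  ## arithmetic at the published final dataset scale
  expect_equal(round(0.8 * 8500), 6800)
})

test_that("model energy is extensive and invariant, forces analytic", {
  w <- waterFixture()
  recs <- waterRecords(60)
  sp <- splitDataset(recs, 0.8, seed = 2)
  mod <- trainModel(sp$train, sp$val, fastTrainCfg(3), waterDcfg(),
                    atomicRef = w@calculator@atomicRef)

  st <- randomStructure(w, seed = 8)
  e1 <- calculate(mod, st)$energy
  ## two copies 100 A apart: energy doubles to high precision
  shifted <- sweep(atomCoords(st), 2, c(-100, 0, 0))
  pair <- Structure(rep(atomSpecies(st), 2), rbind(atomCoords(st), shifted))
  expect_equal(calculate(mod, pair)$energy, 2 * e1, tolerance = 1e-8)

  ## permuting the two hydrogens leaves the energy unchanged
  sw <- Structure(atomSpecies(st)[c(1, 3, 2)], atomCoords(st)[c(1, 3, 2), ])
  expect_equal(calculate(mod, sw)$energy, e1, tolerance = 1e-10)

  ## analytic forces = central differences of the predicted energy
  fa <- calculate(mod, st)$forces
  fn <- numericalForces(mod, st)
  expect_lt(max(abs(fa - fn)), 1e-5)

  expect_error(calculate(mod, Structure("N", matrix(0, 1, 3))),
               "not covered")
})

test_that("training history tracks a non-increasing best validation loss", {
  w <- waterFixture()
  recs <- waterRecords(40)
  sp <- splitDataset(recs, 0.8, seed = 6)
  mod <- trainModel(sp$train, sp$val, fastTrainCfg(5), waterDcfg(),
                    atomicRef = w@calculator@atomicRef)
  h <- mod@history
  expect_gt(nrow(h), 5)
  expect_true(all(diff(h$bestValLoss) <= 1e-12))
  expect_true(all(c("trainMaeE", "valMaeE", "trainMaeF", "valMaeF") %in%
                  names(h)))
})

test_that("a force-free fit of constant energies recovers the constant", {
  w <- waterFixture()
  st <- w@structure
  recs <- lapply(1:12, function(k)
    labeledRecord(Structure(atomSpecies(st), atomCoords(st),
                            id = paste0("c", k)),
                  eTotal = -5, forces = matrix(0, 3, 3),
                  atomicRef = w@calculator@atomicRef))
  sp <- splitDataset(recs, 0.8, seed = 9)
  tc <- fastTrainCfg(2)
  tc$force_weight <- 0
  mod <- trainModel(sp$train, sp$val, tc, waterDcfg(),
                    atomicRef = w@calculator@atomicRef)
  pred <- calculate(mod, st)$energy
  target <- cohesiveEnergy(-5, atomSpecies(st), w@calculator@atomicRef)
  expect_equal(pred, target, tolerance = 1e-5)
})

test_that("mixed-environment training sets are rejected", {
  recs <- makeToyDataset(waterFixture(), 6, c("gas", "solvent"), seed = 1)
  expect_error(trainModel(recs[1:8], recs[9:12], fastTrainCfg(1),
                          waterDcfg()),
               "one environment")
})

test_that("direct-solve and mini-batch training agree on an easy problem", {
  w <- waterFixture()
  recs <- waterRecords(80, maxDisp = 0.05)
  sp <- splitDataset(recs, 0.8, seed = 12)
  tcL <- defaultConfig()$training; tcL$optimizer <- "lsq"; tcL$seed <- 1
  modL <- trainModel(sp$train, sp$val, tcL, waterDcfg(),
                     atomicRef = w@calculator@atomicRef)
  test <- waterRecords(20, seed = 77, maxDisp = 0.04)
  predL <- vapply(test, function(r) calculate(modL, r@structure)$energy, 0)
  ref <- vapply(test, eCohesive, 0)
  expect_lt(sqrt(mean((predL - ref)^2)) * EV_TO_KCALMOL, 0.5)
})

test_that("model serialization round-trips through the portable format", {
  w <- waterFixture()
  recs <- waterRecords(30)
  sp <- splitDataset(recs, 0.8, seed = 13)
  mod <- trainModel(sp$train, sp$val, fastTrainCfg(4), waterDcfg(),
                    atomicRef = w@calculator@atomicRef)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(mod, f)
  back <- loadModel(f)
  st <- randomStructure(w, seed = 55)
  expect_equal(calculate(back, st)$energy, calculate(mod, st)$energy,
               tolerance = 1e-12)
  expect_equal(calculate(back, st)$forces, calculate(mod, st)$forces,
               tolerance = 1e-10)
})
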