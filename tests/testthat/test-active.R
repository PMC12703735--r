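## two cheap committee models over the same data, different seeds
committeePair <- function() {
  w <- waterFixture()
  recs <- waterRecords(40)
  sp <- splitDataset(recs, 0.8, seed = 3)
  m1 <- trainModel(sp$train, sp$val, fastTrainCfg(101), waterDcfg(),
                   atomicRef = w@calculator@atomicRef)
  m2 <- trainModel(sp$train, sp$val, fastTrainCfg(202), waterDcfg(),
                   atomicRef = w@calculator@atomicRef)
  list(w = w, m1 = m1, m2 = m2)
}

test_that("disagreement scores are |E1 - E2| recomputed directly", {
  cp <- committeePair()
  pool <- perturbConformers(cp$w@structure, defaultConfig()$perturbation, 5)
  sc <- disagreementScores(cp$m1, cp$m2, pool)
  expect_true(all(sc >= 0))
  brute <- vapply(pool, function(st)
    abs(calculate(cp$m1, st)$energy - calculate(cp$m2, st)$energy), 0)
  expect_equal(sc, brute, tolerance = 1e-12)

  ## identical models disagree nowhere
  expect_true(all(disagreementScores(cp$m1, cp$m1, pool) == 0))

  ## constant-offset models disagree by exactly the offset
  m3 <- cp$m1
  off <- which(seq_along(m3@theta) > length(m3@theta) - length(m3@elements))
  m3@theta[off] <- m3@theta[off] + 0.5   # +0.5 eV per atom offset
  expect_equal(disagreementScores(cp$m1, m3, pool),
               rep(0.5 * 3, length(pool)), tolerance = 1e-10)
})

test_that("selection ranks by descending score with stable ties", {
  structs <- as.list(letters[1:4])   # only order matters here
  cfg <- list(disagreement_threshold = 0, n_select = 3L)
  sel <- selectForLabeling(c(5, 1, 4, 2), structs, cfg)
  expect_equal(sel$indices, c(1L, 3L, 4L))

  cfg$disagreement_threshold <- Inf
  expect_length(selectForLabeling(c(5, 1, 4, 2), structs, cfg)$indices, 0)

  cfg$disagreement_threshold <- 0; cfg$n_select <- 2L
  expect_equal(selectForLabeling(c(3, 3, 3, 3), structs, cfg)$indices,
               c(1L, 2L))
})

test_that("MD-driven sampling flags exactly the frames the oracle would", {
  cp <- committeePair()
  mdcfg <- defaultConfig()$md
  mdcfg$temperature <- 200; mdcfg$thermostat <- "langevin"
  mdcfg$n_steps <- 200L; mdcfg$seed <- 9L
  out <- mdDrivenSampling(cp$m1, cp$m2, cp$w@structure, mdcfg, 0.01)
  ## brute-force re-evaluation of the same trajectory
  tr <- runMD(cp$m1, cp$w@structure, mdcfg)
  brute <- vapply(seq_len(nFrames(tr)), function(k)
    abs(tr@ePot[k] - calculate(cp$m2,
        Structure(tr@species, tr@positions[, , k]))$energy), 0)
  expect_equal(out$allScores, brute, tolerance = 1e-10)
  expect_equal(length(out$structures), sum(brute > 0.01))

  ## same model on both sides flags nothing
  none <- mdDrivenSampling(cp$m1, cp$m1, cp$w@structure, mdcfg, 1e-12)
  expect_length(none$structures, 0)

  ## zero threshold with a nondegenerate pair flags every frame
  all <- mdDrivenSampling(cp$m1, cp$m2, cp$w@structure, mdcfg, 0)
  expect_length(all$structures, nFrames(tr))
})

test_that("a huge threshold terminates the loop after one cycle", {
  w <- waterFixture()
  seedData <- waterRecords(30)
  alcfg <- defaultConfig()$active_learning
  alcfg$disagreement_threshold <- 1e6
  alcfg$max_cycles <- 4L
  st <- runALLoop(seedData, w@calculator, alcfg, fastTrainCfg(),
                  waterDcfg())
  expect_equal(st@cycle, 1)
  expect_equal(st@terminationReason, "converged")
  expect_equal(st@log$nAdded, 0)
  expect_length(st@dataset, 30)
})

test_that("the loop is deterministic and grows the dataset monotonically", {
  w <- waterFixture()
  seedData <- waterRecords(30)
  alcfg <- defaultConfig()$active_learning
  alcfg$max_cycles <- 2L
  alcfg$md_steps <- 150L
  tc <- fastTrainCfg()
  s1 <- runALLoop(seedData, w@calculator, alcfg, tc, waterDcfg())
  s2 <- runALLoop(seedData, w@calculator, alcfg, tc, waterDcfg())
  expect_identical(s1@log, s2@log)
  expect_true(all(diff(s1@log$nDataset) >= 0))
  expect_gte(length(s1@dataset), 30)
  ids <- vapply(s1@dataset, function(r) r@structure@id, "")
  expect_false(anyDuplicated(ids) > 0)
})
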