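test_that("Morse diatomic has -De at r0 and vanishing energy at large r", {
  co <- diatomicFixture()
  De <- co@calculator@bonds$De[1]
  r0 <- co@calculator@bonds$r0[1]
  at <- function(r) Structure(c("C", "O"), rbind(c(0, 0, 0), c(r, 0, 0)))
  ev <- calculate(co@calculator, at(r0))
  expect_equal(ev$energy, -De, tolerance = 1e-12)
  expect_lt(max(abs(ev$forces)), 1e-10)
  expect_equal(calculate(co@calculator, at(40))$energy, 0, tolerance = 1e-8)
})

test_that("solvent and gas energies differ by exactly the shift term", {
  for (spec in list(waterFixture(), ethaneFixture(), twelveAtomFixture())) {
    st <- randomStructure(spec, seed = 7)
    eg <- calculate(spec@calculator, st, "gas")$energy
    es <- calculate(spec@calculator, st, "solvent")$energy
    ## recompute the shift independently from the smooth coordination term
    x <- atomCoords(st)
    sig <- spec@calculator@solventSigma[atomSpecies(st)]
    rc <- spec@calculator@coordCutoff
    shift <- 0
    n <- nAtoms(st)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (r < rc) shift <- shift + (sig[i] + sig[j]) * 0.5 * (cos(pi * r / rc) + 1)
    }
    expect_equal(es - eg, unname(shift), tolerance = 1e-12)
  }
})

test_that("analytic forces match central differences on random fixtures", {
  specs <- list(waterFixture(), ethaneFixture(), twelveAtomFixture())
  for (k in 1:12) {
    spec <- specs[[(k - 1) %% 3 + 1]]
    st <- randomStructure(spec, seed = 100 + k, scale = 0.08)
    for (env in c("gas", "solvent")) {
      fa <- calculate(spec@calculator, st, env)$forces
      fn <- numericalForces(spec@calculator, st, env)
      expect_lt(max(abs(fa - fn)), 1e-4)
    }
  }
})

test_that("cohesive energy implements the atomization identity", {
  tab <- c(A = -3.0)
  names(tab) <- "C"   # reuse a supported symbol as the toy element
  expect_equal(cohesiveEnergy(-10.0, c("C", "C"), c(C = -3.0)), -4.0)
  expect_equal(cohesiveEnergy(sum(c(C = -3.0)[c("C", "C")]), c("C", "C"),
                              c(C = -3.0)), 0)
  expect_equal(cohesiveEnergy(0, character(0), c(C = -3.0)), 0)
  expect_error(cohesiveEnergy(-1, c("C", "S"), c(C = -3.0)), "S")
})

test_that("cohesive energy is linear in e_total and additive in composition", {
  tab <- c(C = -1.03, H = -0.58, O = -2.04)
  set.seed(3)
  for (k in 1:20) {
    e1 <- rnorm(1); e2 <- rnorm(1)
    comp1 <- sample(names(tab), sample(1:5, 1), replace = TRUE)
    comp2 <- sample(names(tab), sample(1:5, 1), replace = TRUE)
    expect_equal(cohesiveEnergy(e1 + e2, c(comp1, comp2), tab),
                 cohesiveEnergy(e1, comp1, tab) + cohesiveEnergy(e2, comp2, tab),
                 tolerance = 1e-12)
  }
})

test_that("harmonic diatomic frequency matches the closed form", {
  k <- 1.7; r0 <- 1.3
  hd <- harmonicDiatomicFixture(k, r0, c("C", "C"))
  m <- atomicMasses(c("C", "C"))
  mu <- prod(m) / sum(m)
  expected <- sqrt(k * ACC_CONV / mu) / (2 * pi * 2.99792458e-5)
  nm <- hessianNormalModes(hd@structure, hd@calculator)
  expect_equal(nModes(nm), 1)
  expect_equal(modeFrequencies(nm), expected, tolerance = 1e-3)
})

test_that("normal modes are invariant under rigid translation", {
  w <- waterFixture()
  nm1 <- hessianNormalModes(w@structure, w@calculator)
  shifted <- Structure(atomSpecies(w@structure),
                       sweep(atomCoords(w@structure), 2, c(-1, -1, -1)),
                       id = "shifted")
  nm2 <- hessianNormalModes(shifted, w@calculator)
  expect_equal(modeFrequencies(nm1), modeFrequencies(nm2), tolerance = 0.1)
})

test_that("normal modes are invariant under rigid rotation", {
  w <- waterFixture()
  nm1 <- hessianNormalModes(w@structure, w@calculator)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- Structure(atomSpecies(w@structure),
                       atomCoords(w@structure) %*% t(R), id = "rotated")
  nm2 <- hessianNormalModes(rotated, w@calculator)
  expect_equal(modeFrequencies(nm1), modeFrequencies(nm2), tolerance = 0.1)
})

test_that("mode computation refuses structures away from a minimum", {
  w <- waterFixture()
  far <- Structure(atomSpecies(w@structure),
                   atomCoords(w@structure) * 1.2, id = "stretched")
  expect_error(hessianNormalModes(far, w@calculator), "not at a minimum")
})

test_that("calculator registry stores and retrieves by name", {
  registerCalculator("test-water", waterFixture()@calculator)
  expect_true("test-water" %in% listCalculators())
  expect_identical(getCalculator("test-water")@name,
                   waterFixture()@calculator@name)
  expect_error(getCalculator("no-such-calc"), "no calculator registered")
})
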