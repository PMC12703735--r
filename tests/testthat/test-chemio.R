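test_that("XYZ parsing echoes coordinates and flags bad input", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule", "H 0 0 0", "H 0 0 0.74"), f)
  st <- readStructures(f, "xyz")
  expect_length(st, 1)
  expect_equal(atomSpecies(st[[1]]), c("H", "H"))
  expect_equal(atomCoords(st[[1]])[2, ], c(x = 0, y = 0, z = 0.74))

  writeLines(c("two", "comment", "H 0 0 0"), f)
  expect_error(readStructures(f, "xyz"), "line 1")

  writeLines(c("1", "", "X 0 0 0"), f)
  expect_error(readStructures(f, "xyz"), "unknown element")
})

test_that("extXYZ captures per-frame energy, environment and forces", {
  f <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("2", "energy=-1.25 env=solvent",
               "H 0 0 0 0.1 0 0", "H 0 0 0.74 -0.1 0 0"), f)
  rec <- readStructures(f, "extxyz")[[1]]
  expect_s4_class(rec, "LabeledRecord")
  expect_equal(eTotal(rec), -1.25)
  expect_equal(rec@environment, "solvent")
  expect_equal(atomForces(rec)[1, 1], 0.1)
})

test_that("write/read round-trip is exact for species and tight for floats", {
  set.seed(42)
  recs <- lapply(1:10, function(k) {
    n <- sample(2:6, 1)
    Structure(sample(c("C", "H", "O", "N"), n, replace = TRUE),
              matrix(rnorm(3 * n, sd = 2), n, 3), id = paste0("s", k))
  })
  f <- withr::local_tempfile(fileext = ".xyz")
  writeStructures(recs, f, "xyz")
  back <- readStructures(f, "xyz")
  expect_length(back, 10)
  for (k in 1:10) {
    expect_identical(atomSpecies(back[[k]]), atomSpecies(recs[[k]]))
    expect_lt(max(abs(atomCoords(back[[k]]) - atomCoords(recs[[k]]))), 1e-8)
  }

  ## labeled records through extXYZ keep energies and forces
  w <- waterFixture()
  labs <- labelStructures(list(w@structure), w@calculator, "gas")
  writeStructures(labs, f, "extxyz")
  lback <- readStructures(f, "extxyz")[[1]]
  expect_equal(eTotal(lback), eTotal(labs[[1]]), tolerance = 1e-10)
  expect_equal(eCohesive(lback), eCohesive(labs[[1]]), tolerance = 1e-10)
  expect_lt(max(abs(atomForces(lback) - atomForces(labs[[1]]))), 1e-8)

  ## empty list round-trips to an empty file
  writeStructures(list(), f, "xyz")
  expect_length(readStructures(f, "xyz"), 0)
})

test_that("SDF reader extracts the first molecule's atom block", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("methane", "  toy", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "    1.0900    0.0000    0.0000 H   0  0",
               "  1  2  1  0", "M  END", "$$$$"), f)
  st <- readStructures(f, "sdf")[[1]]
  expect_equal(atomSpecies(st), c("C", "H"))
  expect_equal(unname(atomCoords(st)[2, 1]), 1.09)
})

test_that("mode files parse, normalize columns and reject bad norms", {
  hd <- harmonicDiatomicFixture()
  nm <- hessianNormalModes(hd@structure, hd@calculator)
  f <- withr::local_tempfile(fileext = ".modes")
  writeModeFile(nm, f)
  back <- readModeFile(f)
  expect_equal(nModes(back), 1)
  expect_equal(dim(back@modes), c(6, 1))
  expect_equal(sqrt(sum(back@modes^2)), 1, tolerance = 1e-10)
  expect_equal(modeFrequencies(back), modeFrequencies(nm), tolerance = 1e-5)

  ## a 12-atom nonlinear molecule gives a 36 x 30 eigenvector matrix
  tw <- twelveAtomFixture()
  nm12 <- hessianNormalModes(tw@structure, tw@calculator)
  writeModeFile(nm12, f)
  back12 <- readModeFile(f)
  expect_equal(dim(back12@modes), c(36, 30))

  ## column norm far from unity is a format error
  writeLines(c("2 1", "C 0 0 0", "C 1.2 0 0", "mode 1 500.0",
               "0.5 0 0", "0 0 0"), f)
  expect_error(readModeFile(f), "deviates from unity")
})

test_that("config loading merges defaults and fails fast on unknown keys", {
  cfg <- loadConfig(NULL)
  expect_equal(cfg$perturbation$scale_min, 0.96)
  expect_equal(cfg$perturbation$scale_max, 1.10)
  expect_equal(cfg$perturbation$max_displacement, 0.16)
  expect_equal(cfg$nm_sampling$displacement_factor, 0.8)
  expect_equal(cfg$descriptor$cutoff_radius, 6.0)
  expect_equal(cfg$training$force_weight / cfg$training$energy_weight, 10)
  expect_equal(cfg$training$split_fraction, 0.8)
  expect_equal(cfg$md$dt, 0.5)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("md:\n  dt: 1.0", f)
  cfg2 <- loadConfig(f)
  expect_equal(cfg2$md$dt, 1.0)
  expect_equal(cfg2$md$temperature, cfg$md$temperature)

  writeLines("md:\n  tt: 1.0", f)
  expect_error(loadConfig(f), "unknown config key")
  writeLines("descripter:\n  cutoff_radius: 5", f)
  expect_error(loadConfig(f), "descriptor")
})
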