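## Shared fixtures and small utilities for the suite. Template molecules
## are cached inside the package, so repeated calls are cheap.

waterDcfg <- function() descriptorConfig(elements = c("H", "O"))

## a small labeled gas-phase water dataset, deterministic
waterRecords <- function(n = 60, seed = 11, maxDisp = 0.16) {
  pc <- defaultConfig()$perturbation
  pc$max_displacement <- maxDisp
  makeToyDataset(waterFixture(), n, "gas", seed = seed, perturbCfg = pc)
}

## quick settings for trainings whose purpose is plumbing, not accuracy
fastTrainCfg <- function(seed = 1L) {
  tc <- defaultConfig()$training
  tc$max_epochs <- 60L
  tc$min_steps <- 2000L
  tc$seed <- seed
  tc
}

randomStructure <- function(spec, seed, scale = 0.05) {
  set.seed(seed)
  st <- spec@structure
  Structure(atomSpecies(st),
            atomCoords(st) + matrix(stats::runif(3 * nAtoms(st), -scale, scale),
                                    nAtoms(st), 3),
            id = paste0(st@id, "-perturbed"))
}
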