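#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Structure: one molecular geometry
#'
#' The universal currency of the pipeline: a molecule's element symbols and
#' Cartesian coordinates in Angstrom, plus a total charge and a free-text
#' provenance tag recording how the geometry was produced.
#'
#' @slot id character scalar identifier.
#' @slot species character vector of element symbols (one per atom).
#' @slot coords N x 3 numeric matrix, Cartesian Angstrom.
#' @slot charge integer total charge (stored metadata only).
#' @slot provenance free-text tag.
#' @export
setClass("Structure",
  representation(id = "character", species = "character", coords = "matrix",
                 charge = "numeric", provenance = "character"),
  prototype(id = "", charge = 0, provenance = ""))

setValidity("Structure", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be an N x 3 numeric matrix")
  else {
    if (nrow(object@coords) != length(object@species))
      msg <- c(msg, "length(species) must equal nrow(coords)")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
  }
  bad <- setdiff(unique(object@species), .SUPPORTED_ELEMENTS)
  if (length(bad) > 0)
    msg <- c(msg, paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Structure
#'
#' @param species character vector of element symbols.
#' @param coords N x 3 numeric matrix (Angstrom).
#' @param id identifier string.
#' @param charge integer total charge.
#' @param provenance free-text origin tag.
#' @return A [Structure-class] object.
#' @export
Structure <- function(species, coords, id = "", charge = 0, provenance = "") {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  new("Structure", id = as.character(id), species = as.character(species),
      coords = coords, charge = charge, provenance = provenance)
}

#' LabeledRecord: one training example
#'
#' A [Structure-class] together with its environment tag, total and cohesive
#' energies (eV) and forces (eV/Angstrom). The cohesive energy is the total
#' energy minus the sum of isolated-atom reference energies; the identity
#' `eCohesive == eTotal - sum(E_i)` is enforced at construction when a
#' reference table is supplied.
#'
#' @slot structure the geometry.
#' @slot environment "gas" or "solvent".
#' @slot eTotal total energy, eV.
#' @slot eCohesive cohesive energy, eV (NA until references are attached).
#' @slot forces N x 3 matrix, eV/Angstrom.
#' @slot labelSource "oracle" or "model".
#' @export
setClass("LabeledRecord",
  representation(structure = "Structure", environment = "character",
                 eTotal = "numeric", eCohesive = "numeric",
                 forces = "matrix", labelSource = "character"),
  prototype(environment = "gas", eCohesive = NA_real_, labelSource = "oracle"))

setValidity("LabeledRecord", function(object) {
  msg <- character()
  if (!object@environment %in% c("gas", "solvent"))
    msg <- c(msg, "environment must be 'gas' or 'solvent'")
  n <- nrow(object@structure@coords)
  if (!all(dim(object@forces) == c(n, 3)))
    msg <- c(msg, "forces shape must match coords")
  if (!object@labelSource %in% c("oracle", "model"))
    msg <- c(msg, "labelSource must be 'oracle' or 'model'")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledRecord
#'
#' @param structure a [Structure-class].
#' @param eTotal total energy (eV).
#' @param forces N x 3 matrix (eV/Angstrom).
#' @param environment "gas" or "solvent".
#' @param atomicRef optional named vector of isolated-atom energies (eV);
#'   when given, the cohesive energy is computed as
#'   `eTotal - sum(atomicRef[species])`.
#' @param eCohesive cohesive energy, if already known.
#' @param labelSource "oracle" or "model".
#' @return A [LabeledRecord-class].
#' @export
labeledRecord <- function(structure, eTotal, forces, environment = "gas",
                          atomicRef = NULL, eCohesive = NA_real_,
                          labelSource = "oracle") {
  if (!is.null(atomicRef))
    eCohesive <- cohesiveEnergy(eTotal, structure@species, atomicRef)
  new("LabeledRecord", structure = structure, environment = environment,
      eTotal = as.numeric(eTotal), eCohesive = as.numeric(eCohesive),
      forces = forces, labelSource = labelSource)
}

#' NormalModeSet: equilibrium geometry plus vibrational modes
#'
#' @slot equilibrium the equilibrium [Structure-class].
#' @slot modes 3N x n_modes matrix of unit-norm displacement directions
#'   (Cartesian, dimensionless).
#' @slot frequencies wavenumbers, cm^-1 (negative values flag imaginary
#'   modes).
#' @export
setClass("NormalModeSet",
  representation(equilibrium = "Structure", modes = "matrix",
                 frequencies = "numeric"))

setValidity("NormalModeSet", function(object) {
  msg <- character()
  n3 <- 3 * nrow(object@equilibrium@coords)
  if (nrow(object@modes) != n3)
    msg <- c(msg, "modes must have 3N rows")
  if (ncol(object@modes) != length(object@frequencies))
    msg <- c(msg, "one frequency per mode column")
  if (ncol(object@modes) > 0) {
    norms <- sqrt(colSums(object@modes^2))
    if (any(abs(norms - 1) > 1e-8))
      msg <- c(msg, "mode columns must be unit-norm")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: time-ordered molecular dynamics frames
#'
#' Frames are stored as N x 3 x n_frames arrays at a uniform time spacing.
#'
#' @slot species per-atom element symbols.
#' @slot masses per-atom masses, amu.
#' @slot dt frame spacing, fs.
#' @slot times frame times, fs.
#' @slot positions N x 3 x n_frames array, Angstrom.
#' @slot velocities N x 3 x n_frames array, Angstrom/fs.
#' @slot ePot per-frame potential energy, eV.
#' @slot eKin per-frame kinetic energy, eV.
#' @slot temperature per-frame instantaneous temperature, K.
#' @export
setClass("Trajectory",
  representation(species = "character", masses = "numeric", dt = "numeric",
                 times = "numeric", positions = "array", velocities = "array",
                 ePot = "numeric", eKin = "numeric", temperature = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  nf <- length(object@times)
  if (nf < 1) msg <- c(msg, "at least one frame required")
  if (any(object@masses <= 0)) msg <- c(msg, "masses must be positive")
  if (nf >= 2) {
    dts <- diff(object@times)
    if (any(abs(dts - object@dt) > 1e-8 * max(1, object@dt)))
      msg <- c(msg, "frames must be uniformly spaced by dt")
  }
  if (!all(dim(object@positions) == c(length(object@species), 3, nf)))
    msg <- c(msg, "positions must be N x 3 x n_frames")
  if (length(msg)) msg else TRUE
})

#' Calculator: the contract every potential satisfies
#'
#' Virtual base class. Concrete calculators ([ToyCalculator-class],
#' [BaselineModel-class]) implement [calculate()] returning the total (or
#' cohesive) energy in eV and analytic forces in eV/Angstrom; forces are the
#' negative gradient of the energy.
#'
#' @slot name calculator name.
#' @slot supportedElements element symbols the calculator covers.
#' @export
setClass("Calculator", representation("VIRTUAL", name = "character",
                                      supportedElements = "character"))

#' ToyCalculator: analytic reference potential
#'
#' The built-in oracle standing in for a quantum-chemistry reference. The
#' gas-phase energy is a sum of Morse (or harmonic) bond terms, harmonic
#' angle terms, 3-fold cosine torsions and Lennard-Jones interactions for
#' atom pairs three or more bonds apart. The solvent variant adds a smooth
#' per-element coordination-dependent shift; gas and solvent differ by
#' exactly that term.
#'
#' @slot species template species (the calculator is bound to one topology).
#' @slot bonds data.frame (i, j, type, De, a, r0, k).
#' @slot angles data.frame (i, j, k, ktheta, theta0).
#' @slot torsions data.frame (i, j, k, l, v3).
#' @slot lj data.frame (i, j, eps, sigma).
#' @slot solventSigma named per-element solvent shift strength, eV.
#' @slot atomicRef named isolated-atom reference energies, eV.
#' @slot coordCutoff cutoff of the smooth coordination function, Angstrom.
#' @export
setClass("ToyCalculator", contains = "Calculator",
  representation(species = "character", bonds = "data.frame",
                 angles = "data.frame", torsions = "data.frame",
                 lj = "data.frame", solventSigma = "numeric",
                 atomicRef = "numeric", coordCutoff = "numeric"),
  prototype(name = "toy-pes", coordCutoff = 3.0))

#' BaselineModel: trainable atom-centered descriptor potential
#'
#' A per-element linear regression over smooth radial descriptors with
#' analytic forces; the desk-scale trainable potential satisfying the
#' [Calculator-class] contract. Predicted energy is a sum of per-atom
#' contributions, so it is extensive under duplication of non-interacting
#' fragments.
#'
#' @slot elements elements covered by the model.
#' @slot theta parameter vector (per-element descriptor weights + offsets).
#' @slot descriptor descriptor configuration list (see [descriptorConfig()]).
#' @slot featureScale global feature scaling applied before regression.
#' @slot target "cohesive" or "total" training target.
#' @slot environment which environment the model was trained for.
#' @slot atomicRef isolated-atom reference energies used for cohesive
#'   targets (named, eV).
#' @slot history per-epoch training log.
#' @export
setClass("BaselineModel", contains = "Calculator",
  representation(elements = "character", theta = "numeric",
                 descriptor = "list", featureScale = "numeric",
                 target = "character", environment = "character",
                 atomicRef = "numeric", history = "data.frame"),
  prototype(name = "baseline-descriptor", target = "cohesive",
            environment = "gas", featureScale = 1))

#' ToyMoleculeSpec: a toy molecule template
#'
#' Bundles an equilibrium geometry (a true minimum of its own parameters,
#' verified at construction) with the [ToyCalculator-class] that defines its
#' potential-energy surface.
#'
#' @slot id molecule identifier.
#' @slot template template name.
#' @slot structure equilibrium [Structure-class].
#' @slot calculator the molecule's [ToyCalculator-class].
#' @export
setClass("ToyMoleculeSpec",
  representation(id = "character", template = "character",
                 structure = "Structure", calculator = "ToyCalculator"))

#' CutoffReport: RMSE grouped by relative-energy cutoff
#'
#' @slot cutoffs cutoff grid, kcal/mol.
#' @slot mode "cumulative" or "interval".
#' @slot table data.frame with columns cutoff, method, n, rmse (kcal/mol);
#'   empty groups carry NA rmse.
#' @export
setClass("CutoffReport",
  representation(cutoffs = "numeric", mode = "character", table = "data.frame"))

#' Spectrum: a vibrational density of states
#'
#' @slot wavenumber strictly increasing grid, cm^-1.
#' @slot intensity nonnegative intensities, normalized to unit maximum.
#' @slot smoothingWidth Lorentzian smoothing width (FWHM), cm^-1.
#' @export
setClass("Spectrum",
  representation(wavenumber = "numeric", intensity = "numeric",
                 smoothingWidth = "numeric"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavenumber) != length(object@intensity))
    msg <- c(msg, "wavenumber and intensity must align")
  if (any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (any(object@intensity < -1e-12))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SFERecord: one solvation free-energy estimate
#'
#' @slot id molecule identifier.
#' @slot eGas energy in the gas environment at the gas-optimized geometry, eV.
#' @slot eSolv energy in the solvent environment at the solvent-optimized
#'   geometry, eV.
#' @slot delta (eSolv - eGas) in kcal/mol.
#' @slot method method tag (which calculator produced the energies).
#' @export
setClass("SFERecord",
  representation(id = "character", eGas = "numeric", eSolv = "numeric",
                 delta = "numeric", method = "character"))

setValidity("SFERecord", function(object) {
  if (abs(object@delta - (object@eSolv - object@eGas) * EV_TO_KCALMOL) > 1e-8)
    "delta must equal (eSolv - eGas) * 23.0605 kcal/mol" else TRUE
})

#' CorrelationReport: agreement of paired free-energy estimates
#'
#' @slot n number of pairs.
#' @slot pearson Pearson correlation coefficient.
#' @slot slope,intercept least-squares line of prediction on reference.
#' @slot rmse,mae error statistics, kcal/mol.
#' @export
setClass("CorrelationReport",
  representation(n = "numeric", pearson = "numeric", slope = "numeric",
                 intercept = "numeric", rmse = "numeric", mae = "numeric"))

setValidity("CorrelationReport", function(object) {
  msg <- character()
  if (object@n < 2) msg <- c(msg, "n must be >= 2")
  if (is.finite(object@pearson) && abs(object@pearson) > 1 + 1e-12)
    msg <- c(msg, "|pearson| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' ALState: the state of an active-learning campaign
#'
#' @slot cycle number of cycles run.
#' @slot dataset list of [LabeledRecord-class] (grows across cycles).
#' @slot model1,model2 the two committee models from the final cycle.
#' @slot log per-cycle data.frame (maxDisagreement, meanDisagreement,
#'   nAdded, valRmse).
#' @slot terminationReason "converged" or "max_cycles".
#' @export
setClass("ALState",
  representation(cycle = "numeric", dataset = "list", model1 = "ANY",
                 model2 = "ANY", log = "data.frame",
                 terminationReason = "character"))
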