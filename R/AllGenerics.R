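#' Evaluate a calculator on a structure
#'
#' The contract every potential in the pipeline satisfies: given a geometry
#' and an environment tag, return the energy (eV) and analytic forces
#' (eV/Angstrom, negative gradient of the energy).
#'
#' @param calculator a [Calculator-class] object.
#' @param structure a [Structure-class].
#' @param environment "gas" or "solvent".
#' @param ... passed to methods.
#' @return list with elements `energy` (eV; total for the toy oracle, on the
#'   model's training target scale for [BaselineModel-class]) and `forces`
#'   (N x 3, eV/Angstrom).
#' @export
setGeneric("calculate", function(calculator, structure, environment = "gas", ...)
  standardGeneric("calculate"))

#' @describeIn Structure-class number of atoms.
#' @param object,x a Structure (or object containing one).
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn Structure-class element symbols.
#' @export
setGeneric("atomSpecies", function(x) standardGeneric("atomSpecies"))

#' @describeIn Structure-class Cartesian coordinates (Angstrom).
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@coords))
#' @export
setMethod("atomSpecies", "Structure", function(x) x@species)
#' @export
setMethod("atomCoords", "Structure", function(x) x@coords)
#' @export
setMethod("nAtoms", "LabeledRecord", function(x) nrow(x@structure@coords))
#' @export
setMethod("atomSpecies", "LabeledRecord", function(x) x@structure@species)
#' @export
setMethod("atomCoords", "LabeledRecord", function(x) x@structure@coords)
#' @export
setMethod("nAtoms", "Trajectory", function(x) length(x@species))

#' @describeIn Trajectory-class number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@times))

#' @describeIn LabeledRecord-class total energy (eV).
#' @export
setGeneric("eTotal", function(x) standardGeneric("eTotal"))
#' @export
setMethod("eTotal", "LabeledRecord", function(x) x@eTotal)

#' @describeIn LabeledRecord-class cohesive energy (eV).
#' @export
setGeneric("eCohesive", function(x) standardGeneric("eCohesive"))
#' @export
setMethod("eCohesive", "LabeledRecord", function(x) x@eCohesive)

#' @describeIn LabeledRecord-class forces (eV/Angstrom).
#' @export
setGeneric("atomForces", function(x) standardGeneric("atomForces"))
#' @export
setMethod("atomForces", "LabeledRecord", function(x) x@forces)

#' @describeIn NormalModeSet-class number of modes.
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))
#' @export
setMethod("nModes", "NormalModeSet", function(x) ncol(x@modes))

#' @describeIn NormalModeSet-class mode frequencies (cm^-1).
#' @export
setGeneric("modeFrequencies", function(x) standardGeneric("modeFrequencies"))
#' @export
setMethod("modeFrequencies", "NormalModeSet", function(x) x@frequencies)

setMethod("show", "Structure", function(object) {
  cat("Structure", sQuote(object@id), "with", nAtoms(object), "atoms:",
      paste(rle(sort(object@species))$values,
            rle(sort(object@species))$lengths, sep = "", collapse = " "),
      "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "LabeledRecord", function(object) {
  cat(sprintf("LabeledRecord [%s/%s] %d atoms, eTotal = %.6f eV, eCohesive = %.6f eV\n",
              object@environment, object@labelSource, nAtoms(object),
              object@eTotal, object@eCohesive))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms, %d frames, dt = %g fs (%.3f ps)\n",
              nAtoms(object), nFrames(object), object@dt,
              diff(range(object@times)) / 1000))
})

setMethod("show", "NormalModeSet", function(object) {
  cat(sprintf("NormalModeSet: %d atoms, %d modes, frequencies %.1f .. %.1f cm^-1\n",
              nAtoms(object@equilibrium), nModes(object),
              min(object@frequencies), max(object@frequencies)))
})

setMethod("show", "ToyCalculator", function(object) {
  cat(sprintf("ToyCalculator '%s': %d atoms, %d bonds, %d angles, %d torsions, %d LJ pairs\n",
              object@name, length(object@species), nrow(object@bonds),
              nrow(object@angles), nrow(object@torsions), nrow(object@lj)))
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel [%s target, %s]: elements %s, %d parameters\n",
              object@target, object@environment,
              paste(object@elements, collapse = ","), length(object@theta)))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs, best val loss %.3g\n",
                nrow(object@history), min(object@history$valLoss)))
})

setMethod("show", "CutoffReport", function(object) {
  cat(sprintf("CutoffReport (%s cutoffs, kcal/mol):\n", object@mode))
  print(object@table, row.names = FALSE)
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.0f..%.0f cm^-1, peak at %.1f cm^-1 (Lorentzian width %g cm^-1)\n",
              length(object@wavenumber), min(object@wavenumber),
              max(object@wavenumber),
              object@wavenumber[which.max(object@intensity)],
              object@smoothingWidth))
})

setMethod("show", "SFERecord", function(object) {
  cat(sprintf("SFERecord %s [%s]: eGas = %.6f eV, eSolv = %.6f eV, delta = %.3f kcal/mol\n",
              object@id, object@method, object@eGas, object@eSolv, object@delta))
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: n = %d, R = %.4f, slope = %.3f, intercept = %.3f, RMSE = %.3f, MAE = %.3f kcal/mol\n",
              object@n, object@pearson, object@slope, object@intercept,
              object@rmse, object@mae))
})

setMethod("show", "ALState", function(object) {
  cat(sprintf("ALState: %d cycle(s), %d records, terminated: %s\n",
              object@cycle, length(object@dataset), object@terminationReason))
  print(object@log, row.names = FALSE)
})
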