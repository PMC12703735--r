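## Internal unit system: Angstrom / eV / fs / amu.
## Reporting layer converts energies to kcal/mol with a single constant.

#' Unit conversion and physical constants
#'
#' Constants used throughout the package. The internal unit system is
#' Angstrom (length), eV (energy), fs (time) and amu (mass); the reporting
#' layer converts to kcal/mol with `EV_TO_KCALMOL`.
#'
#' @format `EV_TO_KCALMOL` (kcal/mol per eV), `KB_EV` (Boltzmann constant,
#'   eV/K), `ACC_CONV` (acceleration, (Angstrom/fs^2) per (eV/Angstrom/amu)).
#' @name constants
#' @aliases EV_TO_KCALMOL KB_EV ACC_CONV
NULL

#' @export
EV_TO_KCALMOL <- 23.0605

#' @export
KB_EV <- 8.617333262e-5

## 1 (eV/Angstrom)/amu expressed in Angstrom/fs^2; its inverse converts
## amu * (Angstrom/fs)^2 to eV.
#' @export
ACC_CONV <- 9.648533212e-3

## speed of light in cm/fs, for wavenumber conversion
.C_CM_PER_FS <- 2.99792458e-5

## elements the I/O layer accepts; the toy potentials cover the CHON subset
.SUPPORTED_ELEMENTS <- c("H", "C", "N", "O", "S")

.ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Atomic masses for supported elements
#'
#' @param species character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomicMasses <- function(species) {
  bad <- setdiff(unique(species), names(.ELEMENT_MASSES))
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  unname(.ELEMENT_MASSES[species])
}

## angular frequency^2 in fs^-2 from a mass-weighted Hessian eigenvalue
## (eV / Angstrom^2 / amu) is lambda * ACC_CONV; wavenumber follows.
.eigToWavenumber <- function(lambda) {
  sign(lambda) * sqrt(abs(lambda) * ACC_CONV) / (2 * pi * .C_CM_PER_FS)
}

## closed-form harmonic wavenumber from force constant k (eV/A^2) and
## reduced mass mu (amu): (1 / 2 pi c) sqrt(k / mu)
.harmonicWavenumber <- function(k, mu) {
  sqrt(k * ACC_CONV / mu) / (2 * pi * .C_CM_PER_FS)
}
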