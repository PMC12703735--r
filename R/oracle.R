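## Reference-energy layer: internal-coordinate geometry, the analytic toy
## potential-energy surface (the oracle standing in for a quantum-chemistry
## reference), cohesive-energy transformation, and finite-difference normal
## modes.

## ---- internal coordinates and their Cartesian gradients --------------------

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

#' Internal coordinates of a geometry
#'
#' Bond length (Angstrom), bond angle and proper dihedral (radians) between
#' atoms of a coordinate matrix, with optional analytic Cartesian gradients
#' (used by constrained minimization and the toy potential).
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param idx atom indices: 2 for a bond, 3 for an angle (vertex second),
#'   4 for a dihedral.
#' @param grad if `TRUE`, return `list(value, grad)` where `grad` is an
#'   N x 3 matrix (nonzero only on the involved atoms).
#' @return numeric value, or a list when `grad = TRUE`.
#' @export
internalCoordinate <- function(coords, idx, grad = FALSE) {
  switch(as.character(length(idx)),
         "2" = .bondCoord(coords, idx, grad),
         "3" = .angleCoord(coords, idx, grad),
         "4" = .dihedralCoord(coords, idx, grad),
         stop("idx must name 2, 3 or 4 atoms"))
}

.bondCoord <- function(coords, idx, grad = FALSE) {
  d <- coords[idx[1], ] - coords[idx[2], ]
  r <- sqrt(sum(d * d))
  if (!grad) return(r)
  g <- matrix(0, nrow(coords), 3)
  u <- d / r
  g[idx[1], ] <- u
  g[idx[2], ] <- -u
  list(value = r, grad = g)
}

.angleCoord <- function(coords, idx, grad = FALSE) {
  u <- coords[idx[1], ] - coords[idx[2], ]
  v <- coords[idx[3], ] - coords[idx[2], ]
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  uh <- u / nu; vh <- v / nv
  ct <- max(-1, min(1, sum(uh * vh)))
  th <- acos(ct)
  if (!grad) return(th)
  st <- sqrt(max(1e-14, 1 - ct * ct))
  ga <- (ct * uh - vh) / (nu * st)
  gc <- (ct * vh - uh) / (nv * st)
  g <- matrix(0, nrow(coords), 3)
  g[idx[1], ] <- ga
  g[idx[3], ] <- gc
  g[idx[2], ] <- -(ga + gc)
  list(value = th, grad = g)
}

.dihedralCoord <- function(coords, idx, grad = FALSE) {
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  phi <- atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
  if (!grad) return(phi)
  sn1 <- sum(n1 * n1); sn2 <- sum(n2 * n2)
  gi <- -nb2 / sn1 * n1
  gl <- nb2 / sn2 * n2
  s1 <- sum(b1 * b2) / (nb2 * nb2)
  s2 <- sum(b3 * b2) / (nb2 * nb2)
  gj <- -(1 + s1) * gi + s2 * gl
  gk <- s1 * gi - (1 + s2) * gl
  g <- matrix(0, nrow(coords), 3)
  g[idx[1], ] <- gi; g[idx[2], ] <- gj; g[idx[3], ] <- gk; g[idx[4], ] <- gl
  list(value = phi, grad = g)
}

## ---- toy potential ---------------------------------------------------------

## smooth cutoff used by the coordination-dependent solvent term
.fcut <- function(r, rc) ifelse(r < rc, 0.5 * (cos(pi * r / rc) + 1), 0)
.dfcut <- function(r, rc) ifelse(r < rc, -0.5 * pi / rc * sin(pi * r / rc), 0)

## accumulate per-term gradient contributions onto atoms (duplicate-safe)
.accum <- function(g, idx, contrib) {
  s <- rowsum(contrib, idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  g[rows, ] <- g[rows, ] + s
  g
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.toyEnergyForces <- function(calc, coords, environment) {
  n <- nrow(coords)
  e <- 0
  g <- matrix(0, n, 3)
  b <- calc@bonds
  if (nrow(b) > 0) {
    d <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    harm <- b$type == "harmonic"
    dVdr <- numeric(nrow(b))
    if (any(harm)) {
      dr <- r[harm] - b$r0[harm]
      e <- e + sum(0.5 * b$k[harm] * dr^2)
      dVdr[harm] <- b$k[harm] * dr
    }
    if (any(!harm)) {
      ex <- exp(-b$a[!harm] * (r[!harm] - b$r0[!harm]))
      e <- e + sum(b$De[!harm] * (1 - ex)^2 - b$De[!harm])
      dVdr[!harm] <- 2 * b$De[!harm] * b$a[!harm] * ex * (1 - ex)
    }
    gu <- d * (dVdr / r)
    g <- .accum(g, b$i, gu)
    g <- .accum(g, b$j, -gu)
  }
  an <- calc@angles
  if (nrow(an) > 0) {
    u <- coords[an$i, , drop = FALSE] - coords[an$j, , drop = FALSE]
    v <- coords[an$k, , drop = FALSE] - coords[an$j, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    uh <- u / nu; vh <- v / nv
    ct <- pmax(-1, pmin(1, rowSums(uh * vh)))
    st <- sqrt(pmax(1e-14, 1 - ct * ct))
    th <- acos(ct)
    dth <- th - an$theta0
    e <- e + sum(an$ktheta * dth^2)
    pref <- 2 * an$ktheta * dth
    ga <- (ct * uh - vh) / (nu * st) * pref
    gc <- (ct * vh - uh) / (nv * st) * pref
    g <- .accum(g, an$i, ga)
    g <- .accum(g, an$k, gc)
    g <- .accum(g, an$j, -(ga + gc))
  }
  to <- calc@torsions
  if (nrow(to) > 0) {
    b1 <- coords[to$j, , drop = FALSE] - coords[to$i, , drop = FALSE]
    b2 <- coords[to$k, , drop = FALSE] - coords[to$j, , drop = FALSE]
    b3 <- coords[to$l, , drop = FALSE] - coords[to$k, , drop = FALSE]
    n1 <- .rowcross(b1, b2)
    n2 <- .rowcross(b2, b3)
    nb2 <- sqrt(rowSums(b2 * b2))
    phi <- atan2(rowSums(.rowcross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
    e <- e + sum(to$v3 * (1 + cos(3 * phi)))
    pref <- -3 * to$v3 * sin(3 * phi)
    sn1 <- rowSums(n1 * n1); sn2 <- rowSums(n2 * n2)
    gi <- n1 * (-nb2 / sn1)
    gl <- n2 * (nb2 / sn2)
    s1 <- rowSums(b1 * b2) / nb2^2
    s2 <- rowSums(b3 * b2) / nb2^2
    gj <- -(1 + s1) * gi + s2 * gl
    gk <- s1 * gi - (1 + s2) * gl
    g <- .accum(g, to$i, pref * gi)
    g <- .accum(g, to$j, pref * gj)
    g <- .accum(g, to$k, pref * gk)
    g <- .accum(g, to$l, pref * gl)
  }
  lj <- calc@lj
  if (nrow(lj) > 0) {
    d <- coords[lj$i, , drop = FALSE] - coords[lj$j, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    sr6 <- (lj$sigma / r)^6
    e <- e + sum(4 * lj$eps * (sr6^2 - sr6))
    dVdr <- 4 * lj$eps * (-12 * sr6^2 + 6 * sr6) / r
    gu <- d * (dVdr / r)
    g <- .accum(g, lj$i, gu)
    g <- .accum(g, lj$j, -gu)
  }
  if (environment == "solvent" && length(calc@solventSigma) > 0 && n >= 2) {
    rc <- calc@coordCutoff
    sig <- calc@solventSigma[calc@species]
    pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
    pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
    d <- coords[pi_, , drop = FALSE] - coords[pj_, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    inr <- r < rc
    if (any(inr)) {
      w <- (sig[pi_] + sig[pj_])[inr]
      rr <- r[inr]
      e <- e + sum(w * .fcut(rr, rc))
      gu <- d[inr, , drop = FALSE] * (w * .dfcut(rr, rc) / rr)
      g <- .accum(g, pi_[inr], gu)
      g <- .accum(g, pj_[inr], -gu)
    }
  }
  list(energy = e, forces = -g)
}

## Fast internal dispatch used by hot loops (MD, minimization, Hessians):
## avoids S4 object construction and validity checks per evaluation.
.evalCalc <- function(calculator, species, coords, environment = "gas") {
  if (is(calculator, "ToyCalculator")) {
    .toyEnergyForces(calculator, coords, environment)
  } else if (is(calculator, "BaselineModel")) {
    dm <- .designMatrix2(species, coords, calculator@descriptor,
                         calculator@elements)
    list(energy = as.numeric(dm$Ae %*% calculator@theta),
         forces = matrix(-as.numeric(dm$Af %*% calculator@theta),
                         ncol = 3, byrow = TRUE))
  } else {
    calculate(calculator, Structure(species, coords), environment)
  }
}

#' @describeIn calculate analytic toy-potential evaluation. The structure's
#'   species must match the calculator's bonded topology; the solvent
#'   environment adds exactly the coordination-dependent shift term.
#' @export
setMethod("calculate", "ToyCalculator",
  function(calculator, structure, environment = "gas", ...) {
    if (!environment %in% c("gas", "solvent"))
      stop("environment must be 'gas' or 'solvent'")
    if (!identical(structure@species, calculator@species))
      stop("structure species do not match the calculator's bonded topology")
    missing <- setdiff(unique(structure@species), names(calculator@atomicRef))
    if (length(missing) > 0)
      stop("element(s) missing from calculator parameters: ",
           paste(missing, collapse = ", "))
    .toyEnergyForces(calculator, structure@coords, environment)
  })

#' Cohesive energy from a total energy
#'
#' The training target: total molecular energy minus the sum of
#' isolated-atom reference energies, `E_cohesive = E_total - sum_i E_i`.
#'
#' @param eTotal total energy, eV.
#' @param composition element symbols of the molecule (multiset).
#' @param atomicRef named vector of isolated-atom energies, eV.
#' @return cohesive energy, eV.
#' @export
cohesiveEnergy <- function(eTotal, composition, atomicRef) {
  missing <- setdiff(unique(composition), names(atomicRef))
  if (length(missing) > 0)
    stop("element(s) missing from atomic reference table: ",
         paste(missing, collapse = ", "))
  eTotal - sum(atomicRef[composition])
}

#' Label structures with a reference calculator
#'
#' Evaluates each structure and packages energy, cohesive energy and forces
#' into [LabeledRecord-class] objects.
#'
#' @param structures list of [Structure-class] (or a single one).
#' @param calculator a [Calculator-class] with an atomic reference table
#'   (e.g. the toy oracle).
#' @param environment "gas" or "solvent".
#' @param labelSource provenance tag, "oracle" or "model".
#' @return list of [LabeledRecord-class].
#' @export
labelStructures <- function(structures, calculator, environment = "gas",
                            labelSource = "oracle") {
  if (is(structures, "Structure")) structures <- list(structures)
  lapply(structures, function(st) {
    ev <- calculate(calculator, st, environment)
    labeledRecord(st, ev$energy, ev$forces, environment = environment,
                  atomicRef = calculator@atomicRef, labelSource = labelSource)
  })
}

#' Central-difference forces
#'
#' Independent numerical check of a calculator's analytic forces.
#'
#' @param calculator a [Calculator-class].
#' @param structure a [Structure-class].
#' @param environment "gas" or "solvent".
#' @param h displacement step, Angstrom.
#' @return N x 3 matrix of forces, eV/Angstrom.
#' @export
numericalForces <- function(calculator, structure, environment = "gas",
                            h = 1e-5) {
  x0 <- structure@coords
  f <- matrix(0, nrow(x0), 3)
  for (a in seq_len(nrow(x0))) for (d in 1:3) {
    xp <- x0; xp[a, d] <- xp[a, d] + h
    xm <- x0; xm[a, d] <- xm[a, d] - h
    ep <- .evalCalc(calculator, structure@species, xp, environment)$energy
    em <- .evalCalc(calculator, structure@species, xm, environment)$energy
    f[a, d] <- -(ep - em) / (2 * h)
  }
  f
}

## ---- normal modes ----------------------------------------------------------

.isLinearGeometry <- function(coords, tol = 1e-6) {
  if (nrow(coords) <= 2) return(TRUE)
  x <- sweep(coords, 2, colMeans(coords))
  sv <- svd(x)$d
  sv[2] / max(sv[1], 1e-300) < tol
}

#' Normal modes from a finite-difference Hessian
#'
#' Builds the mass-weighted Hessian of a calculator at a minimum by central
#' finite differences of the analytic forces, symmetrizes and diagonalizes
#' it, drops the 6 (5 for linear geometries) near-zero translational and
#' rotational modes, un-mass-weights the retained eigenvectors and
#' normalizes them to unit Euclidean length.
#'
#' @param structure equilibrium [Structure-class] (max |F| must be below
#'   `fMax`).
#' @param calculator a [Calculator-class].
#' @param fdStep finite-difference displacement, Angstrom.
#' @param environment "gas" or "solvent".
#' @param fMax maximum residual force accepted as "at a minimum", eV/Angstrom.
#' @param imagTol magnitude (cm^-1) beyond which a retained negative
#'   eigenvalue triggers an imaginary-frequency warning.
#' @return a [NormalModeSet-class]; frequencies in cm^-1, ascending.
#' @export
hessianNormalModes <- function(structure, calculator, fdStep = 0.005,
                               environment = "gas", fMax = 1e-4,
                               imagTol = 5) {
  x0 <- structure@coords
  n <- nrow(x0)
  f0 <- calculate(calculator, structure, environment)$forces
  if (max(abs(f0)) > fMax)
    stop(sprintf("structure is not at a minimum: max |F| = %.3g eV/A exceeds %g",
                 max(abs(f0)), fMax))
  n3 <- 3 * n
  H <- matrix(0, n3, n3)
  for (a in seq_len(n)) for (d in 1:3) {
    k <- 3 * (a - 1) + d
    xp <- x0; xp[a, d] <- xp[a, d] + fdStep
    xm <- x0; xm[a, d] <- xm[a, d] - fdStep
    fp <- .evalCalc(calculator, structure@species, xp, environment)$forces
    fm <- .evalCalc(calculator, structure@species, xm, environment)$forces
    H[, k] <- -as.numeric(t(fp - fm)) / (2 * fdStep)
  }
  H <- (H + t(H)) / 2
  m3 <- rep(atomicMasses(structure@species), each = 3)
  Hmw <- H / sqrt(outer(m3, m3))
  eig <- eigen(Hmw, symmetric = TRUE)
  freqAll <- .eigToWavenumber(eig$values)
  nDrop <- if (.isLinearGeometry(x0)) 5L else 6L
  keep <- order(abs(freqAll))[-seq_len(nDrop)]
  keep <- keep[order(freqAll[keep])]
  if (length(keep) == 0) {
    warning("structure has no vibrational modes")
    return(new("NormalModeSet", equilibrium = structure,
               modes = matrix(0, n3, 0), frequencies = numeric(0)))
  }
  freqs <- freqAll[keep]
  imag <- which(freqs < -imagTol)
  if (length(imag) > 0)
    warning("imaginary frequency in retained mode(s) ",
            paste(imag, collapse = ", "))
  modes <- eig$vectors[, keep, drop = FALSE] / sqrt(m3)
  modes <- sweep(modes, 2, sqrt(colSums(modes^2)), "/")
  new("NormalModeSet", equilibrium = structure, modes = modes,
      frequencies = freqs)
}

## ---- calculator registry ---------------------------------------------------

.calcRegistry <- new.env(parent = emptyenv())

#' Calculator plugin registry
#'
#' Calculators are registered under a name so pipeline stages can refer to
#' them by string (e.g. in a config file).
#'
#' @param name registry key.
#' @param calculator a [Calculator-class].
#' @return `registerCalculator` returns the calculator invisibly;
#'   `getCalculator` returns the registered object; `listCalculators` the
#'   registered names.
#' @export
registerCalculator <- function(name, calculator) {
  stopifnot(is(calculator, "Calculator"))
  assign(name, calculator, envir = .calcRegistry)
  invisible(calculator)
}

#' @rdname registerCalculator
#' @export
getCalculator <- function(name) {
  if (!exists(name, envir = .calcRegistry))
    stop("no calculator registered under ", sQuote(name),
         "; available: ", paste(listCalculators(), collapse = ", "))
  get(name, envir = .calcRegistry)
}

#' @rdname registerCalculator
#' @export
listCalculators <- function() ls(.calcRegistry)
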