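## Molecular dynamics and geometry machinery: velocity-Verlet NVE/NVT
## (Langevin and velocity-rescale thermostats), FIRE minimization with an
## optional single internal-coordinate constraint (gradient projection onto
## the constraint null space), and relaxed internal-coordinate scans.

.kineticEnergy <- function(v, masses) {
  0.5 * sum(masses * rowSums(v * v)) / ACC_CONV
}

.instantTemperature <- function(eKin, dof) 2 * eKin / (dof * KB_EV)

.maxwellBoltzmann <- function(masses, temperature, rng, removeCOM = TRUE) {
  n <- length(masses)
  if (temperature <= 0) return(matrix(0, n, 3))
  sd <- sqrt(KB_EV * temperature * ACC_CONV / masses)
  v <- matrix(rng$norm(3 * n), n, 3) * sd
  if (removeCOM && n > 1)
    v <- sweep(v, 2, colSums(v * masses) / sum(masses))
  v
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration against any [Calculator-class]. Initial
#' velocities are Maxwell-Boltzmann at the configured temperature
#' (deterministic under `seed`, center-of-mass momentum removed).
#' Thermostats: `"none"` (NVE), `"langevin"` (BAOAB splitting with friction
#' `friction` in 1/fs) or `"rescale"` (velocity rescaling to the target
#' temperature every `rescale_interval` steps).
#'
#' @param calculator a [Calculator-class].
#' @param structure starting [Structure-class].
#' @param cfg MD config block (see [defaultConfig()]): `temperature` (K),
#'   `dt` (fs, default 0.5), `n_steps`, `thermostat`, `friction`,
#'   `rescale_interval`, `save_stride`, `seed`.
#' @param environment "gas" or "solvent".
#' @param fAbort force magnitude (eV/Angstrom) treated as a blow-up; the
#'   run aborts with a warning naming the last stable frame and returns the
#'   frames collected so far.
#' @return a [Trajectory-class] (frames every `save_stride` steps,
#'   including the initial state).
#' @export
runMD <- function(calculator, structure, cfg = defaultConfig()$md,
                  environment = "gas", fAbort = 1e4) {
  stopifnot(cfg$dt > 0, cfg$temperature >= 0)
  masses <- atomicMasses(structure@species)
  n <- length(masses)
  rng <- .seededRNG(if (is.null(cfg$seed)) 1L else cfg$seed)
  thermostat <- match.arg(cfg$thermostat, c("none", "langevin", "rescale"))
  dof <- if (thermostat == "langevin") 3 * n else max(1, 3 * n - 3)
  x <- structure@coords
  v <- .maxwellBoltzmann(masses, cfg$temperature, rng)
  ev <- .evalCalc(calculator, structure@species, x, environment)
  f <- ev$forces
  dt <- cfg$dt
  stride <- max(1L, as.integer(cfg$save_stride))
  nSave <- floor(cfg$n_steps / stride) + 1L
  pos <- array(0, c(n, 3, nSave)); vel <- array(0, c(n, 3, nSave))
  ePot <- numeric(nSave); eKin <- numeric(nSave); temp <- numeric(nSave)
  times <- numeric(nSave)
  record <- function(slot, step) {
    pos[, , slot] <<- x; vel[, , slot] <<- v
    ePot[slot] <<- ev$energy
    eKin[slot] <<- .kineticEnergy(v, masses)
    temp[slot] <<- .instantTemperature(eKin[slot], dof)
    times[slot] <<- step * dt
  }
  record(1L, 0L)
  slot <- 1L
  aborted <- FALSE
  if (thermostat == "langevin") {
    c1 <- exp(-cfg$friction * dt)
    c2m <- sqrt((1 - c1^2) * KB_EV * cfg$temperature * ACC_CONV / masses)
  }
  for (step in seq_len(cfg$n_steps)) {
    acc <- f / masses * ACC_CONV
    if (thermostat == "langevin") {
      v <- v + 0.5 * dt * acc
      x <- x + 0.5 * dt * v
      v <- c1 * v + c2m * matrix(rng$norm(3 * n), n, 3)
      x <- x + 0.5 * dt * v
      ev <- .evalCalc(calculator, structure@species, x, environment)
      f <- ev$forces
      v <- v + 0.5 * dt * (f / masses * ACC_CONV)
    } else {
      x <- x + dt * v + 0.5 * dt^2 * acc
      ev <- .evalCalc(calculator, structure@species, x, environment)
      f <- ev$forces
      v <- v + 0.5 * dt * (acc + f / masses * ACC_CONV)
      if (thermostat == "rescale" && step %% cfg$rescale_interval == 0 &&
          cfg$temperature > 0) {
        tNow <- .instantTemperature(.kineticEnergy(v, masses), dof)
        if (tNow > 0) v <- v * sqrt(cfg$temperature / tNow)
      }
    }
    if (max(abs(f)) > fAbort) {
      warning(sprintf("force blow-up (|F| > %g eV/A) at step %d; last stable frame %d",
                      fAbort, step, slot))
      aborted <- TRUE
      break
    }
    if (step %% stride == 0) {
      slot <- slot + 1L
      record(slot, step)
    }
  }
  traj <- new("Trajectory", species = structure@species, masses = masses,
              dt = dt * stride, times = times[seq_len(slot)],
              positions = pos[, , seq_len(slot), drop = FALSE],
              velocities = vel[, , seq_len(slot), drop = FALSE],
              ePot = ePot[seq_len(slot)], eKin = eKin[seq_len(slot)],
              temperature = temp[seq_len(slot)])
  attr(traj, "aborted") <- aborted
  traj
}

#' Total-energy drift of a trajectory
#'
#' Maximum excursion of `ePot + eKin` from its initial value, normalized
#' per atom and per picosecond of simulated time.
#'
#' @param traj a [Trajectory-class].
#' @return drift in eV/atom/ps.
#' @export
energyDrift <- function(traj) {
  etot <- traj@ePot + traj@eKin
  span <- diff(range(traj@times)) / 1000
  if (span <= 0) return(0)
  max(abs(etot - etot[1])) / nAtoms(traj) / span
}

## Unconstrained minimization: L-BFGS-B on the analytic gradient, then a
## Newton polish through the eigen-pseudoinverse of a finite-difference
## Hessian (translational/rotational null modes dropped), which reaches
## machine-tight force tolerances that quasi-Newton descent alone stalls on.
.minimizeLBFGS <- function(calculator, structure, fTol, maxIter, environment) {
  sp <- structure@species
  shape <- function(p) matrix(p, ncol = 3, byrow = TRUE)
  energyOf <- function(x) .evalCalc(calculator, sp, x, environment)$energy
  forcesOf <- function(x) .evalCalc(calculator, sp, x, environment)$forces
  fdHessian <- function(x, h = 1e-4) {
    n3 <- 3 * nrow(x)
    H <- matrix(0, n3, n3)
    for (a in seq_len(nrow(x))) for (d in 1:3) {
      k <- 3 * (a - 1) + d
      xp <- x; xp[a, d] <- xp[a, d] + h
      xm <- x; xm[a, d] <- xm[a, d] - h
      H[, k] <- -as.numeric(t(forcesOf(xp) - forcesOf(xm))) / (2 * h)
    }
    (H + t(H)) / 2
  }
  x <- structure@coords
  for (round in 1:8) {
    res <- stats::optim(as.numeric(t(x)),
                        fn = function(p) energyOf(shape(p)),
                        gr = function(p) -as.numeric(t(forcesOf(shape(p)))),
                        method = "L-BFGS-B",
                        control = list(maxit = as.integer(maxIter), factr = 1))
    x <- shape(res$par)
    eig <- eigen(fdHessian(x), symmetric = TRUE)
    neg <- which(eig$values < -1e-6)
    if (length(neg) == 0) break
    ## quasi-Newton descent stalls on shallow saddles (soft torsions):
    ## kick along the most negative curvature direction and re-descend
    kick <- 0.2 * shape(eig$vectors[, neg[length(neg)]])
    x <- if (energyOf(x + kick) < energyOf(x - kick)) x + kick else x - kick
  }
  f <- forcesOf(x)
  for (polish in 1:40) {
    if (max(abs(f)) <= fTol) break
    eig <- eigen(fdHessian(x), symmetric = TRUE)
    keep <- eig$values > 1e-6
    g <- -as.numeric(t(f))
    dx <- -as.numeric(eig$vectors[, keep, drop = FALSE] %*%
      (crossprod(eig$vectors[, keep, drop = FALSE], g) / eig$values[keep]))
    if (max(abs(dx)) > 0.25) dx <- dx * 0.25 / max(abs(dx))
    x <- x + shape(dx)
    f <- forcesOf(x)
  }
  if (max(abs(f)) > fTol)
    stop(sprintf("minimization did not converge; residual max |F| = %.3g eV/A",
                 max(abs(f))))
  Structure(sp, x, id = structure@id, charge = structure@charge,
            provenance = paste0(structure@provenance,
                                if (nzchar(structure@provenance)) ";",
                                "minimized"))
}

## Move coords minimally (along the coordinate gradient) until the internal
## coordinate equals `target`; angles wrap on (-pi, pi].
.enforceConstraint <- function(coords, idx, target, tol = 1e-10) {
  for (it in 1:50) {
    ic <- internalCoordinate(coords, idx, grad = TRUE)
    delta <- ic$value - target
    if (length(idx) == 4)
      delta <- atan2(sin(delta), cos(delta))
    if (abs(delta) < tol) break
    g <- as.numeric(t(ic$grad))
    coords <- coords - delta * matrix(g / sum(g * g), ncol = 3, byrow = TRUE)
  }
  coords
}

#' Minimize a structure
#'
#' FIRE (fast inertial relaxation engine) descent on the calculator's
#' potential-energy surface. With `frozen`, a single internal coordinate is
#' held at a target value: forces are projected onto the constraint's null
#' space each step and the coordinate is restored exactly after each move,
#' so the constrained coordinate is preserved to 1e-6 or better while all
#' unconstrained degrees of freedom relax below `fTol`.
#'
#' @param calculator a [Calculator-class].
#' @param structure starting [Structure-class].
#' @param frozen optional `list(idx = atom indices, value = target)`; bond
#'   targets in Angstrom, angle/dihedral targets in radians.
#' @param fTol convergence threshold on the largest unconstrained force
#'   component, eV/Angstrom.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   residual force.
#' @param environment "gas" or "solvent".
#' @return the relaxed [Structure-class].
#' @export
minimizeStructure <- function(calculator, structure, frozen = NULL,
                              fTol = 1e-6, maxIter = 20000L,
                              environment = "gas") {
  if (is.null(frozen))
    return(.minimizeLBFGS(calculator, structure, fTol, maxIter, environment))
  x <- structure@coords
  x <- .enforceConstraint(x, frozen$idx, frozen$value)
  n <- nrow(x)
  v <- matrix(0, n, 3)
  dt <- 0.05; dtMax <- 0.25; alpha <- 0.1
  nUp <- 0L
  projForce <- function(coords) {
    f <- .evalCalc(calculator, structure@species, coords,
                   environment)$forces
    if (!is.null(frozen)) {
      g <- internalCoordinate(coords, frozen$idx, grad = TRUE)$grad
      f <- f - sum(f * g) / sum(g * g) * g
    }
    f
  }
  f <- projForce(x)
  for (it in seq_len(maxIter)) {
    if (max(abs(f)) <= fTol) {
      return(Structure(structure@species, x, id = structure@id,
                       charge = structure@charge,
                       provenance = paste0(structure@provenance,
                                           if (nzchar(structure@provenance)) ";",
                                           "minimized")))
    }
    p <- sum(f * v)
    if (p > 0) {
      nUp <- nUp + 1L
      fn <- sqrt(sum(f * f)); vn <- sqrt(sum(v * v))
      v <- (1 - alpha) * v + alpha * vn * f / fn
      if (nUp > 5L) { dt <- min(dt * 1.1, dtMax); alpha <- alpha * 0.99 }
    } else {
      v[] <- 0; dt <- dt * 0.5; alpha <- 0.1; nUp <- 0L
    }
    v <- v + dt * f
    step <- dt * v
    smax <- max(abs(step))
    if (smax > 0.2) step <- step * (0.2 / smax)
    x <- x + step
    if (!is.null(frozen)) x <- .enforceConstraint(x, frozen$idx, frozen$value)
    f <- projForce(x)
  }
  stop(sprintf("minimization did not converge in %d iterations; residual max |F| = %.3g eV/A",
               maxIter, max(abs(f))))
}

#' Relaxed scan along an internal coordinate
#'
#' Walks a monotone grid of target values for one bond, angle or dihedral,
#' minimizing all other degrees of freedom at each point (each point
#' warm-starts from the previous relaxed geometry). Energies are returned
#' raw; relative-energy conversion is a downstream reporting step so all
#' scan comparisons share one code path.
#'
#' @param calculator a [Calculator-class].
#' @param structure starting [Structure-class] (minimizable at the first
#'   grid point).
#' @param scanSpec `list(kind = "bond"|"angle"|"dihedral", idx = atom
#'   indices (2/3/4, distinct), grid = target values (Angstrom for bonds,
#'   degrees for angles/dihedrals), fTol = per-point relaxation tolerance)`.
#' @param environment "gas" or "solvent".
#' @return list with `points` (data.frame: value, energy (eV), converged)
#'   and `structures` (relaxed geometries); non-converged points are
#'   flagged, not fatal.
#' @export
relaxedScan <- function(calculator, structure, scanSpec,
                        environment = "gas") {
  kind <- match.arg(scanSpec$kind, c("bond", "angle", "dihedral"))
  idx <- scanSpec$idx
  nNeed <- c(bond = 2L, angle = 3L, dihedral = 4L)[[kind]]
  stopifnot(length(idx) == nNeed, !anyDuplicated(idx),
            all(idx >= 1), all(idx <= nAtoms(structure)))
  grid <- scanSpec$grid
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("scan grid must be monotone")
  fTol <- scanSpec$fTol %||% 1e-5
  targets <- if (kind == "bond") grid else grid * pi / 180
  cur <- structure
  energies <- numeric(length(grid))
  converged <- logical(length(grid))
  structures <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    res <- tryCatch(
      minimizeStructure(calculator, cur,
                        frozen = list(idx = idx, value = targets[k]),
                        fTol = fTol, environment = environment),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("scan point %d (value %g) did not converge: %s",
                      k, grid[k], conditionMessage(res)))
      converged[k] <- FALSE
      cur <- Structure(cur@species,
                       .enforceConstraint(cur@coords, idx, targets[k]),
                       id = cur@id)
    } else {
      converged[k] <- TRUE
      cur <- res
    }
    energies[k] <- calculate(calculator, cur, environment)$energy
    structures[[k]] <- cur
  }
  list(points = data.frame(value = grid, energy = energies,
                           converged = converged),
       structures = structures)
}
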