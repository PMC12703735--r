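## Validation analytics: relative energies, RMSE/MAE, cutoff-resolved
## error tables, trajectory cross-evaluation, vibrational density of
## states from the mass-weighted velocity autocorrelation function, and
## radial distribution functions.

#' Relative energies of a series
#'
#' Subtracts the series minimum (`"lowest"`, the relaxed-scan and cutoff
#' convention) or the first element (`"first"`, the trajectory
#' cross-evaluation convention). Units are preserved.
#'
#' @param energies numeric vector (nonempty).
#' @param convention "lowest" or "first".
#' @return numeric vector of the same length.
#' @export
relativeEnergies <- function(energies, convention = c("lowest", "first")) {
  convention <- match.arg(convention)
  stopifnot(length(energies) >= 1)
  if (convention == "lowest") energies - min(energies)
  else energies - energies[1]
}

#' RMSE and MAE of paired series
#'
#' @param pred,ref equal-length numeric vectors.
#' @return list with `rmse` and `mae` (input units).
#' @export
errorStats <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop("pred and ref must have equal length")
  stopifnot(length(pred) >= 1)
  d <- pred - ref
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Cutoff-resolved RMSE report
#'
#' Groups conformers by their reference relative energy (all series must
#' share the same lowest-energy-conformer reference) and reports per-method
#' RMSE within each group: `cumulative` groups contain conformers with
#' `ref < cutoff`; `interval` groups contain `prev_cutoff <= ref < cutoff`
#' (the first interval starts at 0). Empty groups are marked with NA, not
#' zero; cumulative counts are non-decreasing in the cutoff.
#'
#' @param refRel reference relative energies, kcal/mol.
#' @param predRelByMethod named list of predicted relative-energy vectors,
#'   aligned with `refRel`.
#' @param cutoffs increasing cutoff grid, kcal/mol (default the
#'   {50, 100, 200, 300, 400, Inf} grid).
#' @param mode "cumulative" or "interval".
#' @return a [CutoffReport-class].
#' @export
cutoffRmse <- function(refRel, predRelByMethod,
                       cutoffs = c(50, 100, 200, 300, 400, Inf),
                       mode = c("cumulative", "interval")) {
  mode <- match.arg(mode)
  stopifnot(is.list(predRelByMethod), length(predRelByMethod) >= 1,
            !is.null(names(predRelByMethod)), all(diff(cutoffs) > 0))
  for (m in names(predRelByMethod))
    if (length(predRelByMethod[[m]]) != length(refRel))
      stop("method ", sQuote(m), " is not aligned with the reference series")
  lower <- if (mode == "interval") c(0, utils::head(cutoffs, -1)) else
    rep(-Inf, length(cutoffs))
  rows <- list()
  for (ci in seq_along(cutoffs)) {
    idx <- which(refRel >= lower[ci] & refRel < cutoffs[ci])
    for (m in names(predRelByMethod)) {
      rmse <- if (length(idx) == 0) NA_real_ else
        sqrt(mean((predRelByMethod[[m]][idx] - refRel[idx])^2))
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cutoffs[ci], method = m, n = length(idx), rmse = rmse)
    }
  }
  new("CutoffReport", cutoffs = cutoffs, mode = mode,
      table = do.call(rbind, rows))
}

#' Cross-evaluate a trajectory with another calculator
#'
#' The X@Y comparison: re-evaluates each frame geometry of a trajectory
#' generated by method Y with calculator X, converts both energy series to
#' relative energies (default: relative to the first frame) in kcal/mol,
#' and reports RMSE/MAE over the first `nFrames` frames.
#'
#' @param traj a [Trajectory-class] (Y's frames and energies).
#' @param calculator the re-evaluating [Calculator-class] (X).
#' @param convention "first" (default) or "lowest".
#' @param nFrames frames used for the statistics (default 1000; fewer
#'   available frames triggers a warning, not an error).
#' @param environment "gas" or "solvent".
#' @return list with `series` (data.frame: time fs, refRel, predRel in
#'   kcal/mol), `rmse` and `mae` (kcal/mol).
#' @export
crossEvaluate <- function(traj, calculator, convention = "first",
                          nFrames = 1000L, environment = "gas") {
  nf <- nFrames(traj)
  if (nf < nFrames)
    warning(sprintf("only %d frames available (requested %d)", nf, nFrames))
  use <- seq_len(min(nf, nFrames))
  pred <- vapply(use, function(k)
    calculate(calculator,
              Structure(traj@species, traj@positions[, , k]),
              environment)$energy, numeric(1))
  refRel <- relativeEnergies(traj@ePot[use], convention) * EV_TO_KCALMOL
  predRel <- relativeEnergies(pred, convention) * EV_TO_KCALMOL
  stats <- errorStats(predRel, refRel)
  list(series = data.frame(time = traj@times[use], refRel = refRel,
                           predRel = predRel),
       rmse = stats$rmse, mae = stats$mae)
}

## Lorentzian kernel smoothing on an arbitrary grid; width is FWHM.
.lorentzSmooth <- function(x, y, width) {
  if (width <= 0) return(y)
  gamma <- width / 2
  K <- gamma / (pi * (outer(x, x, "-")^2 + gamma^2))
  as.numeric(K %*% y) / rowSums(K)
}

#' Vibrational density of states from the velocity autocorrelation
#'
#' Computes the mass-weighted velocity autocorrelation function
#' `C(t) = < sum_i m_i v_i(t0) . v_i(t0 + t) >` averaged over time origins
#' (every `originStride` frames), takes its real Fourier transform
#' (zero-padded to the next power of two, no window function), maps the
#' frequency axis to wavenumbers via the frame spacing, smooths with a
#' Lorentzian kernel of the stated width (FWHM, default 20 cm^-1) and
#' normalizes to unit maximum.
#'
#' @param traj a [Trajectory-class] with velocities.
#' @param smoothingWidth Lorentzian FWHM, cm^-1.
#' @param segment "last_half" (default: only the second half of the
#'   trajectory enters the average) or "all".
#' @param originStride spacing of time origins, frames.
#' @param maxWavenumber truncate the returned grid, cm^-1.
#' @return a [Spectrum-class].
#' @export
vdos <- function(traj, smoothingWidth = 20, segment = c("last_half", "all"),
                 originStride = 10L, maxWavenumber = 5000) {
  segment <- match.arg(segment)
  v <- traj@velocities
  if (length(v) == 0 || any(!is.finite(v)))
    stop("trajectory has missing or non-finite velocities")
  nf <- nFrames(traj)
  first <- if (segment == "last_half") max(1L, floor(nf / 2)) else 1L
  v <- v[, , first:nf, drop = FALSE]
  nt <- dim(v)[3]
  if (nt < 4) stop("too few frames for a VACF")
  n <- nAtoms(traj)
  ## remove center-of-mass drift (thermostatted runs are diffusive, which
  ## would otherwise bury the vibrational spectrum under a zero-frequency
  ## component)
  mtot <- sum(traj@masses)
  for (k in seq_len(nt)) {
    vcom <- colSums(v[, , k, drop = FALSE][, , 1] * traj@masses) / mtot
    v[, , k] <- sweep(v[, , k, drop = FALSE][, , 1], 2, vcom)
  }
  ## flatten to (3N) x nt with xyz consecutive per atom, mass-weighted
  vm <- matrix(aperm(v, c(2, 1, 3)), nrow = 3 * n, ncol = nt)
  vm <- vm * rep(sqrt(traj@masses), each = 3)
  lagMax <- floor(nt / 2)
  origins <- seq(1L, nt - lagMax, by = max(1L, as.integer(originStride)))
  C <- numeric(lagMax)
  for (t0 in origins) {
    block <- vm[, t0:(t0 + lagMax - 1), drop = FALSE]
    C <- C + as.numeric(crossprod(vm[, t0], block))
  }
  C <- C / length(origins)
  npad <- 2^ceiling(log2(2 * lagMax))
  sp <- Re(stats::fft(c(C, numeric(npad - lagMax))))
  half <- seq_len(npad %/% 2)
  nu <- (half - 1) / (npad * traj@dt) / .C_CM_PER_FS
  keep <- nu <= maxWavenumber
  intensity <- pmax(0, sp[half][keep])
  intensity <- .lorentzSmooth(nu[keep], intensity, smoothingWidth)
  intensity <- pmax(0, intensity)
  if (max(intensity) > 0) intensity <- intensity / max(intensity)
  new("Spectrum", wavenumber = nu[keep], intensity = intensity,
      smoothingWidth = smoothingWidth)
}

#' Radial distribution function of an element pair
#'
#' Histogram of interatomic distances between atoms of the named elements
#' over all frames, normalized by the ideal-gas shell count
#' `4 pi r^2 dr / V` for a finite nonperiodic system (`V` from `boxVolume`;
#' with the default unit volume the curve is a shell-volume-normalized
#' distance density, so peak positions — the quantity compared here — are
#' meaningful while the absolute scale is convention-dependent).
#'
#' @param traj a [Trajectory-class].
#' @param pair character vector of two element symbols.
#' @param rMax histogram range, Angstrom.
#' @param nBins number of bins.
#' @param boxVolume reference volume for the ideal-gas normalization.
#' @return data.frame with columns `r` (bin centers), `g`, `counts`;
#'   zero-row warning when the pair does not occur.
#' @export
rdf <- function(traj, pair, rMax = 6.0, nBins = 100L, boxVolume = 1) {
  stopifnot(rMax > 0, nBins >= 1, length(pair) == 2)
  ia <- which(traj@species == pair[1])
  ib <- which(traj@species == pair[2])
  same <- pair[1] == pair[2]
  pairs <- if (same) {
    if (length(ia) < 2) matrix(integer(), ncol = 2) else t(utils::combn(ia, 2))
  } else {
    as.matrix(expand.grid(i = ia, j = ib))
  }
  if (nrow(pairs) == 0) {
    warning("no ", pair[1], "-", pair[2], " pair in trajectory")
    return(data.frame(r = numeric(0), g = numeric(0), counts = numeric(0)))
  }
  breaks <- seq(0, rMax, length.out = nBins + 1)
  counts <- numeric(nBins)
  nf <- nFrames(traj)
  for (k in seq_len(nf)) {
    x <- traj@positions[, , k]
    d <- sqrt(rowSums((x[pairs[, 1], , drop = FALSE] -
                       x[pairs[, 2], , drop = FALSE])^2))
    d <- d[d < rMax]
    if (length(d) > 0)
      counts <- counts + tabulate(findInterval(d, breaks), nbins = nBins)
  }
  centers <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  dr <- diff(breaks)[1]
  shell <- 4 * pi * centers^2 * dr / boxVolume
  g <- counts / (nf * nrow(pairs)) / shell
  data.frame(r = centers, g = g, counts = counts)
}
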