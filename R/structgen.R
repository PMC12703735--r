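## Nonequilibrium training-structure generation: element filtering,
## scaling + random-displacement perturbation, and normal-mode displacement.

#' Filter structures by allowed elements
#'
#' Keeps exactly the structures whose species are a subset of `allowed`
#' (the published protocol keeps C, H, O, N compounds), preserving order.
#'
#' @param structures list of [Structure-class].
#' @param allowed character vector of allowed element symbols.
#' @param quiet suppress the in/out count message.
#' @return filtered list (possibly empty).
#' @export
filterElements <- function(structures, allowed = c("C", "H", "O", "N"),
                           quiet = FALSE) {
  stopifnot(length(allowed) > 0)
  keep <- vapply(structures, function(st)
    all(atomSpecies(st) %in% allowed), logical(1))
  if (!quiet)
    message(sprintf("filterElements: kept %d of %d structures (allowed: %s)",
                    sum(keep), length(structures),
                    paste(allowed, collapse = ",")))
  structures[keep]
}

#' Scaling grid of a perturbation configuration
#'
#' Inclusive arithmetic grid `scale_min, scale_min + scale_step, ...,
#' scale_max` (floating-point-safe endpoint handling). The defaults
#' 0.96..1.10 step 0.02 give 8 factors.
#'
#' @param cfg perturbation config block (see [defaultConfig()]).
#' @return numeric vector of multiplicative scale factors.
#' @export
scaleGrid <- function(cfg) {
  nsteps <- floor((cfg$scale_max - cfg$scale_min) / cfg$scale_step + 1e-9)
  cfg$scale_min + cfg$scale_step * (0:nsteps)
}

#' Generate nonequilibrium conformers by scaling and random displacement
#'
#' For each factor `s` of the inclusive scale grid and each replicate, the
#' coordinates are scaled about the molecular centroid by `s`, then every
#' Cartesian component is displaced by an independent uniform draw in
#' `[-max_displacement, +max_displacement]`. Deterministic under `seed`;
#' output count is `n_scales * replicates_per_scale`.
#'
#' @param structure a [Structure-class] with at least 2 atoms (scaling about
#'   the centroid is a no-op for a single atom; use a scale grid of `{1.0}`
#'   on a multi-atom system for displacement-only sampling).
#' @param cfg perturbation config block (defaults from [defaultConfig()]):
#'   `scale_min` 0.96, `scale_max` 1.10, `scale_step` 0.02,
#'   `max_displacement` 0.16 Angstrom, `replicates_per_scale` 1.
#' @param seed RNG seed.
#' @return list of perturbed [Structure-class], provenance-tagged with the
#'   scale factor and replicate index.
#' @export
perturbConformers <- function(structure, cfg = defaultConfig()$perturbation,
                              seed = 1L) {
  stopifnot(cfg$scale_min > 0, cfg$scale_min <= cfg$scale_max,
            cfg$scale_step > 0, cfg$max_displacement >= 0)
  if (nAtoms(structure) < 2)
    stop("single-atom structure: centroid scaling is a no-op; ",
         "use displacement-only sampling (scale grid {1.0}) on a larger system")
  grid <- scaleGrid(cfg)
  reps <- as.integer(cfg$replicates_per_scale)
  x0 <- structure@coords
  centroid <- colMeans(x0)
  xc <- sweep(x0, 2, centroid)
  out <- vector("list", length(grid) * reps)
  rng <- .seededRNG(seed)
  k <- 0L
  for (s in grid) for (rep in seq_len(reps)) {
    k <- k + 1L
    disp <- matrix(rng$unif(3 * nrow(x0), -cfg$max_displacement,
                            cfg$max_displacement), ncol = 3)
    coords <- sweep(xc * s, 2, centroid, `+`) + disp
    out[[k]] <- Structure(structure@species, coords,
                          id = sprintf("%s-s%.3f-r%d", structure@id, s, rep),
                          charge = structure@charge,
                          provenance = sprintf("perturb scale=%.3f rep=%d", s, rep))
  }
  out
}

#' Generate conformers by normal-mode displacement
#'
#' For each mode column `m` (unit-norm Cartesian direction) and each signed
#' step `d` in `{+-k * delta : k = 1..steps_per_direction}` with
#' `delta = displacement_factor / steps_per_direction`, emits the
#' equilibrium coordinates displaced by `d * m` (`d` in Angstrom). The
#' defaults (factor 0.8, 5 steps per direction, zero excluded) give
#' 10 conformations per mode; a 12-atom nonlinear molecule (30 modes)
#' yields 300.
#'
#' @param modeset a [NormalModeSet-class].
#' @param cfg normal-mode sampling config block (defaults from
#'   [defaultConfig()]).
#' @return list of [Structure-class], each provenance-tagged with
#'   `(mode index, displacement)`.
#' @export
nmSample <- function(modeset, cfg = defaultConfig()$nm_sampling) {
  stopifnot(cfg$displacement_factor > 0, cfg$steps_per_direction >= 1)
  nm <- nModes(modeset)
  if (nm == 0) {
    warning("modeset has zero modes; returning empty list")
    return(list())
  }
  eq <- modeset@equilibrium
  x0 <- eq@coords
  n <- nrow(x0)
  delta <- cfg$displacement_factor / cfg$steps_per_direction
  steps <- delta * seq_len(cfg$steps_per_direction)
  disps <- c(-rev(steps), steps)
  out <- vector("list", nm * length(disps))
  k <- 0L
  for (mode in seq_len(nm)) {
    mvec <- matrix(modeset@modes[, mode], ncol = 3, byrow = TRUE)
    for (d in disps) {
      k <- k + 1L
      out[[k]] <- Structure(eq@species, x0 + d * mvec,
                            id = sprintf("%s-m%02d-d%+.3f", eq@id, mode, d),
                            charge = eq@charge,
                            provenance = sprintf("nm mode=%d disp=%+.4f", mode, d))
    }
  }
  out
}

## Deterministic RNG stream isolated from the global .Random.seed.
.seededRNG <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    unif = function(n, lo = 0, hi = 1) draw(function() stats::runif(n, lo, hi)),
    norm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    sample = function(x, size, replace = FALSE)
      draw(function() sample(x, size, replace = replace)),
    int = function(n, max) draw(function() sample.int(max, n, replace = TRUE))
  )
}
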