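## Deterministic synthetic-system generator: toy CHON molecules with bond
## graphs and analytic potential parameters, labeled datasets in both
## environments, and the 12-atom compound family used by the sampling and
## cutoff analyses. Real element symbols (C, H, O, N) are used with toy
## parameters so the element filter and element-keyed models are exercised
## realistically; the parameterization is not chemically accurate.

.BOND_PARAMS <- data.frame(
  pair = c("C-H", "O-H", "N-H", "C-C", "C-O", "C-N", "N-N", "O-O", "N-O", "H-H"),
  De = c(3.5, 4.0, 3.8, 3.6, 3.7, 3.6, 2.8, 2.2, 2.5, 4.5),
  a  = c(1.9, 2.2, 2.1, 1.8, 2.0, 1.9, 2.0, 2.2, 2.1, 1.9),
  r0 = c(1.09, 0.96, 1.01, 1.53, 1.43, 1.47, 1.45, 1.48, 1.40, 0.74))

.ANGLE_K <- 3.0                                   # eV/rad^2
.ANGLE_THETA0 <- c(C = 109.471, N = 107.0, O = 104.5) * pi / 180
.TORSION_V3 <- 0.02                               # eV per dihedral term
.LJ_EPS <- c(H = 0.002, C = 0.004, N = 0.004, O = 0.004)    # eV
.LJ_SIGMA <- c(H = 2.4, C = 3.2, N = 3.1, O = 3.0)          # Angstrom
.SOLVENT_SIGMA <- c(H = -0.008, C = -0.015, N = -0.035, O = -0.045)  # eV
.ATOMIC_REF <- c(H = -0.58, C = -1.03, N = -1.49, O = -2.04)         # eV
.VALENCE <- c(C = 4L, N = 3L, O = 2L, H = 1L)

.bondKey <- function(e1, e2) {
  p <- sort(c(e1, e2))
  ## table keys are ordered heavy-major; try both orders
  k1 <- paste(p[1], p[2], sep = "-"); k2 <- paste(p[2], p[1], sep = "-")
  hit <- match(c(k1, k2), .BOND_PARAMS$pair)
  hit <- hit[!is.na(hit)][1]
  if (is.na(hit)) stop("no toy bond parameters for ", k1)
  .BOND_PARAMS[hit, ]
}

.graphDistances <- function(n, bonds) {
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

## Tetrahedral tree embedding on alternating sublattices: even-depth atoms
## bond along +t_i, odd-depth along -t_i, which yields clash-free staggered
## guess geometries for tree molecules.
.embedTree <- function(species, bonds) {
  n <- length(species)
  tdir <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  coords <- matrix(NA_real_, n, 3)
  used <- vector("list", n)
  depth <- rep(NA_integer_, n)
  coords[1, ] <- 0; depth[1] <- 0L; used[[1]] <- integer()
  queue <- 1L
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    sgn <- if (depth[p] %% 2 == 0) 1 else -1
    for (child in adj[[p]]) {
      if (!is.na(depth[child])) next
      k <- setdiff(1:4, used[[p]])[1]
      if (is.na(k)) stop("valence exceeded in tree embedding")
      used[[p]] <- c(used[[p]], k)
      r0 <- .bondKey(species[p], species[child])$r0
      coords[child, ] <- coords[p, ] + sgn * r0 * tdir[k, ]
      depth[child] <- depth[p] + 1L
      used[[child]] <- k   # back-bond occupies the same index on -sgn set
      queue <- c(queue, child)
    }
  }
  if (anyNA(coords)) stop("bond graph is not connected")
  coords
}

#' Build a toy molecule from a bond graph
#'
#' Derives the full analytic potential (Morse bonds from the shared
#' element-pair table, harmonic angles at every bonded triple, 3-fold
#' cosine torsions around every central bond, Lennard-Jones terms for atom
#' pairs three or more bonds apart, per-element solvent shifts and atomic
#' references), embeds the tree on alternating tetrahedral sublattices and
#' relaxes it to a true minimum of its own gas-phase surface (verified:
#' max |F| < 1e-6 eV/Angstrom at construction).
#'
#' @param species element symbols.
#' @param bonds 2-column matrix of bonded atom index pairs (a tree or any
#'   connected graph; embedding requires a tree).
#' @param id molecule identifier.
#' @param template template tag.
#' @param coords optional starting coordinates (skips the tree embedding).
#' @return a [ToyMoleculeSpec-class].
#' @export
makeToyMolecule <- function(species, bonds, id = "toy", template = "custom",
                            coords = NULL) {
  calc <- .buildToyCalculator(species, bonds, id)
  if (is.null(coords)) coords <- .embedTree(species, matrix(as.integer(bonds), ncol = 2))
  guess <- Structure(species, coords, id = id, provenance = "embedded-guess")
  eq <- minimizeStructure(calc, guess, fTol = 5e-8, maxIter = 100000L)
  fmax <- max(abs(calculate(calc, eq)$forces))
  if (fmax >= 1e-6)
    stop(sprintf("fixture '%s' failed to reach a true minimum (max |F| = %.2g)",
                 id, fmax))
  eq@provenance <- "equilibrium"
  new("ToyMoleculeSpec", id = id, template = template, structure = eq,
      calculator = calc)
}

.buildToyCalculator <- function(species, bonds, id = "toy") {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(species)
  bp <- do.call(rbind, lapply(seq_len(nrow(bonds)), function(r)
    .bondKey(species[bonds[r, 1]], species[bonds[r, 2]])))
  bondDf <- data.frame(i = bonds[, 1], j = bonds[, 2], type = "morse",
                       De = bp$De, a = bp$a, r0 = bp$r0, k = NA_real_)
  adj <- lapply(seq_len(n), function(i)
    sort(c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])))
  angles <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (c1 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- data.frame(
          i = cmb[1, c1], j = j, k = cmb[2, c1], ktheta = .ANGLE_K,
          theta0 = .ANGLE_THETA0[[species[j]]])
    }
  }
  angleDf <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(), j = integer(), k = integer(),
               ktheta = numeric(), theta0 = numeric())
  tors <- list()
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j))
      tors[[length(tors) + 1L]] <- data.frame(i = i, j = j, k = k, l = l,
                                              v3 = .TORSION_V3)
  }
  torsDf <- if (length(tors)) do.call(rbind, tors) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               v3 = numeric())
  D <- .graphDistances(n, bonds)
  ljRows <- which(upper.tri(D) & D >= 3, arr.ind = TRUE)
  ljDf <- if (nrow(ljRows)) data.frame(
    i = ljRows[, 1], j = ljRows[, 2],
    eps = sqrt(.LJ_EPS[species[ljRows[, 1]]] * .LJ_EPS[species[ljRows[, 2]]]),
    sigma = (.LJ_SIGMA[species[ljRows[, 1]]] +
             .LJ_SIGMA[species[ljRows[, 2]]]) / 2) else
    data.frame(i = integer(), j = integer(), eps = numeric(),
               sigma = numeric())
  new("ToyCalculator", name = paste0("toy-", id), species = species,
      supportedElements = names(.ATOMIC_REF),
      bonds = bondDf, angles = angleDf, torsions = torsDf,
      lj = ljDf, solventSigma = .SOLVENT_SIGMA,
      atomicRef = .ATOMIC_REF, coordCutoff = 3.0)
}

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, fn) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, fn(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

#' Toy molecule templates
#'
#' Deterministic fixture molecules, each a true minimum of its own analytic
#' surface: a Morse diatomic, a purely harmonic diatomic (for closed-form
#' frequency and energy-conservation checks), a water-like triatomic, an
#' ethane-like 8-atom molecule with a 3-fold torsion, and a family of
#' 12-atom nonlinear molecules (30 vibrational modes each).
#'
#' @param variant which 12-atom compound (1..7); the variants differ in
#'   their four-heavy-atom CHON skeleton.
#' @param k,r0,elements harmonic-diatomic force constant (eV/Angstrom^2),
#'   equilibrium bond length (Angstrom) and element pair.
#' @return a [ToyMoleculeSpec-class].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
diatomicFixture <- function() .cached("diatomic", function()
  makeToyMolecule(c("C", "O"), rbind(c(1L, 2L)), id = "co-diatomic",
                  template = "diatomic"))

#' @rdname fixtures
#' @export
harmonicDiatomicFixture <- function(k = 1.0, r0 = 1.2,
                                    elements = c("C", "C")) {
  bondDf <- data.frame(i = 1L, j = 2L, type = "harmonic", De = NA_real_,
                       a = NA_real_, r0 = r0, k = k)
  calc <- new("ToyCalculator", name = "toy-harmonic-diatomic",
              species = elements, supportedElements = names(.ATOMIC_REF),
              bonds = bondDf,
              angles = data.frame(i = integer(), j = integer(), k = integer(),
                                  ktheta = numeric(), theta0 = numeric()),
              torsions = data.frame(i = integer(), j = integer(),
                                    k = integer(), l = integer(),
                                    v3 = numeric()),
              lj = data.frame(i = integer(), j = integer(), eps = numeric(),
                              sigma = numeric()),
              solventSigma = .SOLVENT_SIGMA, atomicRef = .ATOMIC_REF,
              coordCutoff = 3.0)
  eq <- Structure(elements, rbind(c(0, 0, 0), c(r0, 0, 0)),
                  id = "harmonic-diatomic", provenance = "equilibrium")
  new("ToyMoleculeSpec", id = "harmonic-diatomic", template = "harmonic",
      structure = eq, calculator = calc)
}

#' @rdname fixtures
#' @export
waterFixture <- function() .cached("water", function() {
  th <- .ANGLE_THETA0[["O"]]
  r0 <- .bondKey("O", "H")$r0
  coords <- rbind(c(0, 0, 0),
                  c(r0, 0, 0),
                  c(r0 * cos(th), r0 * sin(th), 0))
  makeToyMolecule(c("O", "H", "H"), rbind(c(1L, 2L), c(1L, 3L)),
                  id = "water", template = "water-like", coords = coords)
})

#' @rdname fixtures
#' @export
ethaneFixture <- function() .cached("ethane", function()
  makeToyMolecule(c("C", "C", "H", "H", "H", "H", "H", "H"),
                  rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L),
                        c(2L, 6L), c(2L, 7L), c(2L, 8L)),
                  id = "ethane", template = "ethane-like"))

.TWELVE_ATOM_SKELETONS <- list(
  list(heavy = c("C", "C", "C", "O"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
  list(heavy = c("C", "C", "O", "C"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
  list(heavy = c("C", "C", "C", "O"), edges = rbind(c(1, 2), c(1, 3), c(1, 4))),
  list(heavy = c("C", "C", "N", "N"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
  list(heavy = c("C", "N", "N", "C"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
  list(heavy = c("N", "C", "C", "N"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))),
  list(heavy = c("C", "N", "C", "N"), edges = rbind(c(1, 2), c(2, 3), c(3, 4))))

.hydrogenate <- function(heavy, edges) {
  species <- heavy
  bonds <- matrix(as.integer(edges), ncol = 2)
  deg <- tabulate(c(bonds), nbins = length(heavy))
  for (a in seq_along(heavy)) {
    nH <- .VALENCE[[heavy[a]]] - deg[a]
    if (nH < 0) stop("valence exceeded at heavy atom ", a)
    for (h in seq_len(nH)) {
      species <- c(species, "H")
      bonds <- rbind(bonds, c(a, length(species)))
    }
  }
  list(species = species, bonds = bonds)
}

#' @rdname fixtures
#' @export
twelveAtomFixture <- function(variant = 1L) {
  stopifnot(variant >= 1, variant <= length(.TWELVE_ATOM_SKELETONS))
  .cached(paste0("twelve-", variant), function() {
    sk <- .TWELVE_ATOM_SKELETONS[[variant]]
    hg <- .hydrogenate(sk$heavy, sk$edges)
    stopifnot(length(hg$species) == 12L)
    makeToyMolecule(hg$species, hg$bonds,
                    id = sprintf("twelve-%d-%s", variant,
                                 paste(sk$heavy, collapse = "")),
                    template = "12-atom nonlinear")
  })
}

#' The seven-compound 12-atom family
#'
#' All seven 12-atom nonlinear variants (the compound set whose normal-mode
#' sampling yields 7 x 300 = 2100 conformers under the default grid).
#'
#' @return list of 7 [ToyMoleculeSpec-class].
#' @export
twelveAtomCompoundSet <- function()
  lapply(seq_along(.TWELVE_ATOM_SKELETONS), twelveAtomFixture)

#' Generate a labeled toy dataset
#'
#' Conformers are drawn by the scaling + random-displacement sampler from
#' the molecule's equilibrium and labeled (total energy, cohesive energy,
#' forces) with the molecule's own oracle in each requested environment.
#' Bitwise-deterministic under `seed`; records for multiple environments
#' are geometry-paired (same conformer ids).
#'
#' @param spec a [ToyMoleculeSpec-class].
#' @param nConformers conformers per environment.
#' @param environments subset of c("gas", "solvent").
#' @param seed RNG seed.
#' @param perturbCfg perturbation config (defaults from [defaultConfig()]).
#' @return list of [LabeledRecord-class] (length
#'   `nConformers * length(environments)`).
#' @export
makeToyDataset <- function(spec, nConformers = 100L, environments = "gas",
                           seed = 1L,
                           perturbCfg = defaultConfig()$perturbation) {
  stopifnot(all(environments %in% c("gas", "solvent")))
  nGrid <- length(scaleGrid(perturbCfg))
  perturbCfg$replicates_per_scale <-
    as.integer(ceiling(nConformers / nGrid))
  conf <- perturbConformers(spec@structure, perturbCfg, seed = seed)
  ## interleave scales before truncation so any prefix spans the scale grid
  reps <- perturbCfg$replicates_per_scale
  ord <- order(rep(seq_len(reps), times = nGrid),
               rep(seq_len(nGrid), each = reps))
  conf <- conf[ord][seq_len(nConformers)]
  out <- list()
  for (env in environments)
    out <- c(out, labelStructures(conf, spec@calculator, env))
  out
}

#' Random toy molecule set
#'
#' Deterministically samples small CHON molecules (1-3 heavy atoms drawn
#' from C/N/O, chain skeletons, hydrogens filling free valences) built on
#' the shared toy parameter tables. Used for the synthetic solvation
#' free-energy recovery study, where across-molecule composition variation
#' generates the spread of solvent offsets.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return list of [ToyMoleculeSpec-class].
#' @export
randomToyMolecules <- function(n = 50L, seed = 1L) {
  rng <- .seededRNG(seed)
  out <- vector("list", n)
  for (m in seq_len(n)) {
    nHeavy <- rng$sample(1:3, 1)
    heavy <- rng$sample(c("C", "N", "O"), nHeavy, replace = TRUE)
    edges <- if (nHeavy > 1)
      cbind(seq_len(nHeavy - 1), 2:nHeavy) else matrix(integer(), ncol = 2)
    hg <- .hydrogenate(heavy, edges)
    out[[m]] <- makeToyMolecule(hg$species, hg$bonds,
                                id = sprintf("rnd-%03d-%s", m,
                                             paste(heavy, collapse = "")),
                                template = "random-chain")
  }
  out
}
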