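## Structure / trajectory / mode-file / config I/O.
##
## The extended-XYZ dialect is fixed: the comment line carries
## whitespace-separated key=value pairs (keys `energy`, `env`), and forces,
## when present, are three trailing per-atom columns fx fy fz. Coordinates
## are Angstrom, energies eV, forces eV/Angstrom.

.splitFields <- function(line) strsplit(trimws(line), "[[:space:]]+")[[1]]

.parseCommentKV <- function(line) {
  out <- list()
  if (!nzchar(trimws(line))) return(out)
  for (tok in .splitFields(line)) {
    if (grepl("=", tok, fixed = TRUE)) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      out[[kv[1]]] <- paste(kv[-1], collapse = "=")
    }
  }
  out
}

#' Read structures from XYZ / extended-XYZ / SDF files
#'
#' Multi-frame XYZ and extended-XYZ are supported; frame order is preserved.
#' For extended-XYZ, an `energy=<eV>` key on the comment line and three
#' trailing per-atom force columns promote the frame to a
#' [LabeledRecord-class] (with `env=<gas|solvent>` honoured). SDF (V2000) is
#' a read-only convenience for hydration-benchmark-style inputs: only the first
#' molecule's atom block is read.
#'
#' @param path input file.
#' @param dialect "xyz", "extxyz" or "sdf".
#' @return list of [Structure-class] (or [LabeledRecord-class] where energy
#'   and forces are present in the file).
#' @export
readStructures <- function(path, dialect = c("extxyz", "xyz", "sdf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "sdf") return(.readSDF(path))
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 0)
      stop("malformed atom count at line ", i, ": ", sQuote(lines[i]))
    if (i + 1L + nat > length(lines))
      stop("truncated frame starting at line ", i)
    frame <- frame + 1L
    kv <- if (dialect == "extxyz") .parseCommentKV(lines[i + 1L]) else list()
    body <- lines[(i + 2L):(i + 1L + nat)]
    fields <- lapply(body, .splitFields)
    nf <- vapply(fields, length, 0L)
    if (any(nf < 4))
      stop("malformed atom line at line ", i + 1L + which(nf < 4)[1])
    species <- vapply(fields, `[`, "", 1L)
    coords <- matrix(vapply(fields, function(f) as.numeric(f[2:4]),
                            numeric(3)), ncol = 3, byrow = TRUE)
    if (any(!is.finite(coords)))
      stop("non-numeric coordinate in frame starting at line ", i)
    st <- Structure(species, coords,
                    id = if (!is.null(kv$id)) kv$id else sprintf("frame%04d", frame),
                    provenance = paste0("read:", basename(path)))
    hasForces <- dialect == "extxyz" && all(nf >= 7)
    hasEnergy <- !is.null(kv$energy)
    if (hasEnergy || hasForces) {
      forces <- if (hasForces)
        matrix(vapply(fields, function(f) as.numeric(f[5:7]), numeric(3)),
               ncol = 3, byrow = TRUE)
      else matrix(NA_real_, nat, 3)
      env <- if (!is.null(kv$env)) kv$env else "gas"
      eC <- if (!is.null(kv$energy_cohesive)) as.numeric(kv$energy_cohesive) else NA_real_
      out[[frame]] <- new("LabeledRecord", structure = st, environment = env,
                          eTotal = if (hasEnergy) as.numeric(kv$energy) else NA_real_,
                          eCohesive = eC, forces = forces,
                          labelSource = if (!is.null(kv$source)) kv$source else "oracle")
    } else {
      out[[frame]] <- st
    }
    i <- i + 2L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  out
}

.readSDF <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("truncated SDF file: ", path)
  counts <- lines[4]
  nat <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(nat)) stop("malformed SDF counts line (line 4)")
  body <- lines[5:(4 + nat)]
  coords <- t(vapply(body, function(l) {
    as.numeric(c(substr(l, 1, 10), substr(l, 11, 20), substr(l, 21, 30)))
  }, numeric(3)))
  species <- trimws(substr(body, 31, 34))
  list(Structure(species, coords, id = trimws(lines[1]),
                 provenance = paste0("read:", basename(path))))
}

#' Write structures to XYZ / extended-XYZ
#'
#' Writing then reading back reproduces species exactly and numeric fields
#' to better than 1e-8 (17 significant digits are written).
#'
#' @param records list of [Structure-class] and/or [LabeledRecord-class]
#'   (a single object is accepted).
#' @param path output file.
#' @param dialect "extxyz" (energies/forces written when present) or "xyz".
#' @return `path`, invisibly.
#' @export
writeStructures <- function(records, path, dialect = c("extxyz", "xyz")) {
  dialect <- match.arg(dialect)
  if (is(records, "Structure") || is(records, "LabeledRecord"))
    records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  for (rec in records) {
    isLab <- is(rec, "LabeledRecord")
    st <- if (isLab) rec@structure else rec
    n <- nAtoms(st)
    writeLines(as.character(n), con)
    comment <- if (nzchar(st@id)) paste0("id=", st@id) else ""
    if (isLab && dialect == "extxyz") {
      comment <- paste(comment, paste0("energy=", fmt(rec@eTotal)),
                       paste0("env=", rec@environment),
                       paste0("source=", rec@labelSource))
      if (is.finite(rec@eCohesive))
        comment <- paste(comment, paste0("energy_cohesive=", fmt(rec@eCohesive)))
    }
    writeLines(trimws(comment), con)
    for (a in seq_len(n)) {
      ln <- paste(st@species[a], fmt(st@coords[a, 1]), fmt(st@coords[a, 2]),
                  fmt(st@coords[a, 3]))
      if (isLab && dialect == "extxyz" && all(is.finite(rec@forces[a, ])))
        ln <- paste(ln, fmt(rec@forces[a, 1]), fmt(rec@forces[a, 2]),
                    fmt(rec@forces[a, 3]))
      writeLines(ln, con)
    }
  }
  invisible(path)
}

#' Read a normal-mode file
#'
#' Plain-text columnar format: a header line `natoms n_modes`, a geometry
#' block of `natoms` lines (`element x y z`), then for each mode a line
#' `mode <k> <frequency_cm-1>` followed by `natoms` rows of displacement
#' components (`dx dy dz`). Mode columns are re-normalized to unit Euclidean
#' length; a column whose norm deviates from unity by more than 1e-3 is a
#' format error.
#'
#' @param path input file.
#' @return a [NormalModeSet-class].
#' @export
readModeFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- suppressWarnings(as.integer(.splitFields(lines[1])))
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("mode file header must be 'natoms n_modes'")
  nat <- hdr[1]; nm <- hdr[2]
  need <- 1 + nat + nm * (1 + nat)
  if (length(lines) < need)
    stop("mode file geometry/mode block shape mismatch: expected ", need,
         " non-blank lines, found ", length(lines))
  geo <- lapply(lines[2:(1 + nat)], .splitFields)
  species <- vapply(geo, `[`, "", 1L)
  coords <- matrix(vapply(geo, function(f) as.numeric(f[2:4]), numeric(3)),
                   ncol = 3, byrow = TRUE)
  eq <- Structure(species, coords, id = "mode-file-equilibrium")
  modes <- matrix(0, 3 * nat, nm)
  freqs <- numeric(nm)
  pos <- 2 + nat
  for (k in seq_len(nm)) {
    mh <- .splitFields(lines[pos])
    if (tolower(mh[1]) != "mode")
      stop("expected 'mode k freq' line for mode ", k)
    freqs[k] <- as.numeric(mh[3])
    blk <- lapply(lines[(pos + 1):(pos + nat)], .splitFields)
    disp <- matrix(vapply(blk, function(f) as.numeric(f[1:3]), numeric(3)),
                   ncol = 3, byrow = TRUE)
    v <- as.numeric(t(disp))
    nrm <- sqrt(sum(v^2))
    if (abs(nrm - 1) > 1e-3)
      stop(sprintf("mode %d column norm %.6f deviates from unity by more than 1e-3",
                   k, nrm))
    modes[, k] <- v / nrm
    pos <- pos + 1 + nat
  }
  new("NormalModeSet", equilibrium = eq, modes = modes, frequencies = freqs)
}

#' Write a normal-mode file
#'
#' Inverse of [readModeFile()].
#'
#' @param modeset a [NormalModeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModeFile <- function(modeset, path) {
  eq <- modeset@equilibrium
  nat <- nAtoms(eq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nat, nModes(modeset)), con)
  for (a in seq_len(nat))
    writeLines(sprintf("%s %.12f %.12f %.12f", eq@species[a],
                       eq@coords[a, 1], eq@coords[a, 2], eq@coords[a, 3]), con)
  for (k in seq_len(nModes(modeset))) {
    writeLines(sprintf("mode %d %.6f", k, modeset@frequencies[k]), con)
    m <- matrix(modeset@modes[, k], ncol = 3, byrow = TRUE)
    for (a in seq_len(nat))
      writeLines(sprintf("%.12f %.12f %.12f", m[a, 1], m[a, 2], m[a, 3]), con)
  }
  invisible(path)
}

## ---- pipeline configuration ------------------------------------------------

#' Default pipeline configuration
#'
#' Nested parameter blocks for every stage, with defaults equal to the
#' published protocol values: coordinate scaling 0.96..1.10 in steps of
#' 0.02 with random displacements up to 0.16 Angstrom; normal-mode
#' displacement factor 0.8 Angstrom with 5 steps per direction; descriptor
#' cutoff 6.0 Angstrom; force:energy loss weighting 10:1; learning rate
#' 0.005; batch size 5; 80/20 train/validation split; MD time step 0.5 fs;
#' VDOS Lorentzian smoothing 20 cm^-1; cumulative cutoff grid
#' {50, 100, 200, 300, 400, Inf} kcal/mol.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    perturbation = list(scale_min = 0.96, scale_max = 1.10, scale_step = 0.02,
                        max_displacement = 0.16, replicates_per_scale = 1L),
    nm_sampling = list(displacement_factor = 0.8, steps_per_direction = 5L,
                       exclude_zero = TRUE),
    descriptor = list(cutoff_radius = 6.0, n_radial = 8L, r_min = 0.6,
                      degree = 2L),
    training = list(split_fraction = 0.8, force_weight = 10, energy_weight = 1,
                    learning_rate = 0.005, batch_size = 5L, max_epochs = 600L,
                    patience = 600L, lr_decay = 0.5, lr_patience = 20L,
                    min_lr = 1e-5, plateau_tol = 1e-4, min_steps = 20000L,
                    target = "cohesive", optimizer = "adam", seed = 1L),
    md = list(temperature = 300, dt = 0.5, n_steps = 2000L,
              thermostat = "none", friction = 0.02, rescale_interval = 50L,
              save_stride = 10L, seed = 1L),
    active_learning = list(disagreement_threshold = 0.02, per_atom = FALSE,
                           max_cycles = 5L, md_temperatures = c(100, 200, 300),
                           md_steps = 500L, n_select = 10L,
                           model_seeds = c(101L, 202L), dedup_rmsd = 1e-4),
    evaluation = list(cutoffs = c(50, 100, 200, 300, 400, Inf),
                      smoothing_width = 20, vacf_origin_stride = 10L,
                      cross_n_frames = 1000L, rdf_n_bins = 100L,
                      rdf_r_max = 6.0),
    solvation = list(n_molecules = 50L, conformers_per_molecule = 10L,
                     scale_min = 0.98, scale_max = 1.06, scale_step = 0.02,
                     max_displacement = 0.08, replicates_per_scale = 1L),
    workflow = list(n_seed_conformers = 24L, final_train_conformers = 120L,
                    eval_md_steps = 2000L, eval_scan_from = 1.25,
                    eval_scan_to = 1.65, eval_scan_step = 0.05,
                    sfe_molecules = 8L)
  )
}

.mergeConfig <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults)) {
      valid <- names(defaults)
      d <- utils::adist(key, valid)
      hint <- valid[which.min(d)]
      stop(sprintf("unknown config key '%s'%s; did you mean '%s'? Valid keys: %s",
                   paste(here, collapse = "."),
                   if (length(path)) "" else " at top level", hint,
                   paste(valid, collapse = ", ")))
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], here)
    else
      defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load a pipeline configuration
#'
#' Reads a YAML config and merges it over [defaultConfig()]. Unknown keys
#' are a fail-fast error naming the nearest valid key; unspecified fields
#' keep their defaults.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return nested named list.
#' @export
loadConfig <- function(path = NULL) {
  defaults <- defaultConfig()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  .mergeConfig(defaults, user)
}
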