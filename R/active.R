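## Two-process active learning: committee (two-model) disagreement
## selection over candidate pools, MD-driven sampling with re-evaluation by
## the second model, and the outer loop iterating until the maximum
## disagreement on newly generated configurations falls below threshold.

#' Committee disagreement scores
#'
#' Absolute energy-prediction difference `|E_1 - E_2|` between two models
#' for each structure, in eV (optionally per atom).
#'
#' @param model1,model2 [Calculator-class] objects (typically two
#'   [BaselineModel-class] fits with different initialization seeds).
#' @param structures list of [Structure-class].
#' @param environment "gas" or "solvent".
#' @param perAtom divide each score by the structure's atom count.
#' @return numeric vector of nonnegative scores aligned with the input.
#' @export
disagreementScores <- function(model1, model2, structures,
                               environment = "gas", perAtom = FALSE) {
  vapply(structures, function(st) {
    d <- abs(calculate(model1, st, environment)$energy -
             calculate(model2, st, environment)$energy)
    if (perAtom) d / nAtoms(st) else d
  }, numeric(1))
}

#' Select structures for reference labeling
#'
#' Structures whose disagreement exceeds the threshold, ranked by
#' descending score and truncated to `n_select`; ties keep input order
#' (stable ranking).
#'
#' @param scores disagreement scores aligned with `structures`.
#' @param structures candidate list.
#' @param cfg active-learning config block (`disagreement_threshold`,
#'   `n_select`; see [defaultConfig()]).
#' @return list with `structures`, `scores` and original `indices` of the
#'   selected subset (possibly empty).
#' @export
selectForLabeling <- function(scores, structures, cfg) {
  stopifnot(length(scores) == length(structures))
  above <- which(scores > cfg$disagreement_threshold)
  ord <- above[order(-scores[above])]   # order() is stable for ties
  sel <- utils::head(ord, cfg$n_select)
  list(structures = structures[sel], scores = scores[sel], indices = sel)
}

#' MD-driven sampling of underrepresented configurations
#'
#' Runs MD under `model1`, re-evaluates every saved frame with `model2`,
#' and returns the frames whose absolute energy difference exceeds the
#' threshold, tagged with simulation time and score.
#'
#' @param model1 the MD driver model.
#' @param model2 the re-evaluation model.
#' @param structure MD starting geometry.
#' @param mdcfg MD config block.
#' @param threshold disagreement threshold, eV.
#' @param environment "gas" or "solvent".
#' @return list with `structures`, `scores`, `times` (fs) of the flagged
#'   frames, plus `allScores` over every saved frame.
#' @export
mdDrivenSampling <- function(model1, model2, structure, mdcfg, threshold,
                             environment = "gas") {
  traj <- runMD(model1, structure, mdcfg, environment = environment)
  if (isTRUE(attr(traj, "aborted")))
    warning("MD aborted early; flags cover the stable prefix only")
  nf <- nFrames(traj)
  frames <- lapply(seq_len(nf), function(k)
    Structure(traj@species, traj@positions[, , k],
              id = sprintf("%s-md-%06.1ffs", structure@id, traj@times[k]),
              provenance = sprintf("md-sample t=%.1ffs T=%gK",
                                   traj@times[k], mdcfg$temperature)))
  scores <- vapply(seq_len(nf), function(k)
    abs(traj@ePot[k] -
        calculate(model2, frames[[k]], environment)$energy), numeric(1))
  flag <- which(scores > threshold)
  list(structures = frames[flag], scores = scores[flag],
       times = traj@times[flag], allScores = scores)
}

## RMSD after optimal (Kabsch) superposition; used for duplicate
## suppression of newly flagged structures.
.alignedRMSD <- function(a, b) {
  pa <- sweep(a, 2, colMeans(a))
  pb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(pa, pb))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((pa %*% t(rot) - pb)^2)))
}

#' Run the active-learning loop
#'
#' Each cycle trains two committee models on the current dataset with
#' distinct seeds, generates candidates by both processes (perturbation
#' pool scored by committee disagreement; MD under model 1 re-evaluated by
#' model 2), labels the flagged structures with the reference calculator,
#' de-duplicates (aligned RMSD below `dedup_rmsd` against existing
#' records), appends, and repeats. Terminates when the maximum disagreement
#' over the cycle's newly generated configurations falls below
#' `disagreement_threshold`, or after `max_cycles`.
#'
#' @param seedDataset nonempty list of oracle-labeled
#'   [LabeledRecord-class]; the first record's geometry seeds candidate
#'   generation and MD.
#' @param oracle the reference [Calculator-class] used for labeling.
#' @param alcfg active-learning config block (see [defaultConfig()]).
#' @param tcfg training config block.
#' @param dcfg descriptor config.
#' @param perturbCfg perturbation config for the candidate pool.
#' @param environment "gas" or "solvent".
#' @return an [ALState-class] with the grown dataset, final committee
#'   models, per-cycle log and termination reason.
#' @export
runALLoop <- function(seedDataset, oracle,
                      alcfg = defaultConfig()$active_learning,
                      tcfg = defaultConfig()$training,
                      dcfg = descriptorConfig(),
                      perturbCfg = defaultConfig()$perturbation,
                      environment = "gas") {
  stopifnot(length(seedDataset) >= 2, alcfg$disagreement_threshold > 0)
  seeds <- alcfg$model_seeds
  if (length(seeds) < 2 || seeds[1] == seeds[2])
    stop("two distinct model seeds are required")
  dataset <- seedDataset
  refStruct <- seedDataset[[1]]@structure
  logRows <- list()
  model1 <- model2 <- NULL
  reason <- "max_cycles"
  nTemp <- length(alcfg$md_temperatures)
  for (cycle in seq_len(alcfg$max_cycles)) {
    sp <- splitDataset(dataset, fraction = 0.8, seed = 1000L + cycle)
    t1 <- tcfg; t1$seed <- seeds[1] + cycle
    t2 <- tcfg; t2$seed <- seeds[2] + cycle
    model1 <- trainModel(sp$train, sp$val, t1, dcfg, atomicRef = oracle@atomicRef)
    model2 <- trainModel(sp$train, sp$val, t2, dcfg, atomicRef = oracle@atomicRef)
    Sv <- .stackDesigns(sp$val, dcfg, model1@elements, model1@target)
    valRmse <- .lossAndMetrics(model1@theta, Sv, 1, 0)$rmseE
    ## process 1: committee disagreement over a fresh perturbation pool
    pool <- perturbConformers(refStruct, perturbCfg, seed = 7000L + cycle)
    pool <- lapply(pool, function(st) {
      st@id <- sprintf("c%02d-%s", cycle, st@id)  # ids unique across cycles
      st
    })
    poolScores <- disagreementScores(model1, model2, pool, environment,
                                     perAtom = isTRUE(alcfg$per_atom))
    picked <- selectForLabeling(poolScores, pool, alcfg)
    ## process 2: MD under model 1, re-evaluated by model 2
    mdcfg <- defaultConfig()$md
    mdcfg$temperature <- alcfg$md_temperatures[(cycle - 1) %% nTemp + 1]
    mdcfg$n_steps <- alcfg$md_steps
    mdcfg$thermostat <- "langevin"
    mdcfg$seed <- 8000L + cycle
    mdFlag <- mdDrivenSampling(model1, model2, refStruct, mdcfg,
                               alcfg$disagreement_threshold, environment)
    mdFlag$structures <- lapply(mdFlag$structures, function(st) {
      st@id <- sprintf("c%02d-%s", cycle, st@id)
      st
    })
    newScores <- c(poolScores, mdFlag$allScores)
    maxDis <- max(newScores)
    candidates <- c(picked$structures, mdFlag$structures)
    ## duplicate suppression against the existing dataset and within batch
    added <- 0L
    if (maxDis >= alcfg$disagreement_threshold) {
      existing <- lapply(dataset, atomCoords)
      for (st in candidates) {
        dup <- any(vapply(existing, function(xc)
          .alignedRMSD(xc, st@coords) < alcfg$dedup_rmsd, logical(1)))
        if (dup) next
        rec <- tryCatch(labelStructures(st, oracle, environment)[[1]],
                        error = function(e) {
                          message("oracle failed on ", st@id, ": ",
                                  conditionMessage(e), " (skipped)")
                          NULL
                        })
        if (is.null(rec)) next
        dataset[[length(dataset) + 1L]] <- rec
        existing[[length(existing) + 1L]] <- st@coords
        added <- added + 1L
      }
    }
    logRows[[cycle]] <- data.frame(cycle = cycle, maxDisagreement = maxDis,
                                   meanDisagreement = mean(newScores),
                                   nAdded = added, nDataset = length(dataset),
                                   valRmse = valRmse)
    if (maxDis < alcfg$disagreement_threshold) {
      reason <- "converged"
      break
    }
  }
  new("ALState", cycle = length(logRows), dataset = dataset,
      model1 = model1, model2 = model2, log = do.call(rbind, logRows),
      terminationReason = reason)
}
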