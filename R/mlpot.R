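## The trainable baseline potential: smooth atom-centered radial
## descriptors with element-resolved channels, a per-element linear model
## over them (energy = sum of per-atom contributions), analytic forces via
## the chain rule, and the weighted energy+force training protocol.

#' Descriptor configuration
#'
#' Atom-centered radial descriptors: for each neighbor element channel, a
#' set of Gaussians centered on `n_radial` points between `r_min` and the
#' cutoff, multiplied by a smooth cosine cutoff so value and gradient vanish
#' at `cutoff_radius`. The descriptors are invariant under rigid rotation,
#' translation and permutation of identical atoms by construction.
#'
#' @param cutoff_radius neighbor cutoff, Angstrom (default 6.0).
#' @param n_radial number of radial Gaussians per element channel.
#' @param r_min center of the innermost Gaussian, Angstrom.
#' @param elements ordered element channels the descriptor resolves.
#' @param degree 1 for a linear per-element model over the descriptors, 2
#'   (default) to add pairwise descriptor products, which supply the
#'   three-body (angular) sensitivity a purely radial linear model lacks
#'   and reproduce the local surface to second order.
#' @return descriptor config list.
#' @export
descriptorConfig <- function(cutoff_radius = 6.0, n_radial = 8L,
                             r_min = 0.6, elements = c("C", "H", "N", "O"),
                             degree = 2L) {
  stopifnot(degree %in% c(1L, 2L))
  centers <- seq(r_min, cutoff_radius, length.out = n_radial)
  dmu <- centers[2] - centers[1]
  list(cutoff_radius = cutoff_radius, n_radial = as.integer(n_radial),
       r_min = r_min, elements = elements, centers = centers,
       eta = 1 / (2 * dmu^2), degree = as.integer(degree))
}

## radial basis g_k(r) and its derivative; both vanish smoothly at cutoff
.radialBasis <- function(r, cfg) {
  fc <- .fcut(r, cfg$cutoff_radius)
  dfc <- .dfcut(r, cfg$cutoff_radius)
  g <- exp(-cfg$eta * (r - cfg$centers)^2)
  list(value = g * fc, deriv = g * (dfc - 2 * cfg$eta * (r - cfg$centers) * fc))
}

#' Per-atom descriptor features
#'
#' @param structure a [Structure-class].
#' @param cfg descriptor config from [descriptorConfig()].
#' @param gradients also return the full analytic feature gradients.
#' @return list with `features` (N x F matrix, F = n_channels * n_radial)
#'   and, when requested, `gradients` (array N x F x N x 3: d feature
#'   (i, f) / d coordinate (j, d)).
#' @export
featurize <- function(structure, cfg = descriptorConfig(), gradients = FALSE) {
  fg <- .featuresAndGrads(structure@species, structure@coords, cfg,
                          gradients = gradients)
  out <- list(features = fg$phi)
  if (gradients) {
    n <- nrow(fg$phi)
    out$gradients <- aperm(array(fg$gr, c(n, ncol(fg$phi), 3, n)),
                           c(1, 2, 4, 3))
  }
  out
}

## Per-atom radial descriptors phi (N x F) and, optionally, their full
## Cartesian gradients gr (N x F x 3N; coordinate index m = 3*(atom-1)+d).
.featuresAndGrads <- function(sp, x, cfg, gradients = TRUE) {
  n <- nrow(x)
  nr <- cfg$n_radial
  nf <- length(cfg$elements) * nr
  phi <- matrix(0, n, nf)
  gr <- if (gradients) array(0, c(n, nf, 3 * n)) else NULL
  zi <- match(sp, cfg$elements)
  if (anyNA(zi))
    stop("element(s) not covered by descriptor channels: ",
         paste(setdiff(unique(sp), cfg$elements), collapse = ", "))
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- x[i, ] - x[j, ]
    r <- sqrt(sum(d * d))
    if (r >= cfg$cutoff_radius) next
    rb <- .radialBasis(r, cfg)
    u <- d / r
    ci <- (zi[j] - 1) * nr + seq_len(nr)  # channel of i keyed by element of j
    cj <- (zi[i] - 1) * nr + seq_len(nr)
    phi[i, ci] <- phi[i, ci] + rb$value
    phi[j, cj] <- phi[j, cj] + rb$value
    if (gradients) {
      dv <- outer(rb$deriv, u)            # nr x 3
      mi <- 3 * (i - 1) + 1:3; mj <- 3 * (j - 1) + 1:3
      gr[i, ci, mi] <- gr[i, ci, mi] + dv
      gr[i, ci, mj] <- gr[i, ci, mj] - dv
      gr[j, cj, mj] <- gr[j, cj, mj] - dv
      gr[j, cj, mi] <- gr[j, cj, mi] + dv
    }
  }
  list(phi = phi, gr = gr)
}

## Pooled design for one structure: energy row Ae (length P) with
## E = Ae . theta, and force design Af (3N x P) with F = -Af . theta.
## Per-atom basis psi_i is phi_i (degree 1) optionally extended by the
## upper-triangle products phi_p phi_q (degree 2); theta holds one weight
## block per model element plus one offset per element.
.designMatrix <- function(structure, cfg, elements) {
  .designMatrix2(structure@species, structure@coords, cfg, elements)
}

.psiLength <- function(cfg) {
  nf <- length(cfg$elements) * cfg$n_radial
  if (identical(cfg$degree, 2L)) nf + nf * (nf + 1) / 2 else nf
}

.designMatrix2 <- function(sp, x, cfg, elements) {
  n <- nrow(x)
  ei <- match(sp, elements)
  if (anyNA(ei))
    stop("element(s) not covered by the model: ",
         paste(setdiff(unique(sp), elements), collapse = ", "))
  fg <- .featuresAndGrads(sp, x, cfg)
  nf <- ncol(fg$phi)
  quad <- identical(cfg$degree, 2L)
  if (quad) {
    qidx <- which(upper.tri(diag(nf), diag = TRUE), arr.ind = TRUE)
    qp <- qidx[, 1]; qq <- qidx[, 2]
  }
  P1 <- .psiLength(cfg)
  P <- length(elements) * P1 + length(elements)
  Ae <- numeric(P)
  Af <- matrix(0, 3 * n, P)
  for (i in seq_len(n)) {
    blk <- (ei[i] - 1) * P1 + seq_len(P1)
    gi <- matrix(fg$gr[i, , ], nrow = nf)      # F x 3N
    if (quad) {
      psi <- c(fg$phi[i, ], fg$phi[i, qp] * fg$phi[i, qq])
      dpsi <- rbind(gi, fg$phi[i, qp] * gi[qq, , drop = FALSE] +
                        fg$phi[i, qq] * gi[qp, , drop = FALSE])
    } else {
      psi <- fg$phi[i, ]
      dpsi <- gi
    }
    Ae[blk] <- Ae[blk] + psi
    Af[, blk] <- Af[, blk] + t(dpsi)
  }
  offs <- length(elements) * P1 + seq_along(elements)
  Ae[offs] <- tabulate(ei, nbins = length(elements))
  list(Ae = Ae, Af = Af)
}

#' Split a labeled dataset into training and validation sets
#'
#' Random, disjoint, exhaustive split with `round(fraction * n)` training
#' records; deterministic under `seed`.
#'
#' @param records list of [LabeledRecord-class] (length >= 2).
#' @param fraction training fraction (default 0.8, the published protocol).
#' @param seed RNG seed.
#' @return list with elements `train` and `val`.
#' @export
splitDataset <- function(records, fraction = 0.8, seed = 1L) {
  n <- length(records)
  if (n < 2) stop("need at least 2 records to split")
  stopifnot(fraction > 0, fraction < 1)
  nTrain <- round(fraction * n)
  nTrain <- max(1L, min(n - 1L, nTrain))
  rng <- .seededRNG(seed)
  idx <- rng$sample(n, nTrain)
  list(train = records[sort(idx)], val = records[-sort(idx)])
}

.recordTarget <- function(rec, target) {
  y <- if (target == "cohesive") rec@eCohesive else rec@eTotal
  if (!is.finite(y))
    stop("record lacks a finite ", target, " energy label")
  y
}

## Precompute stacked design matrices for a record list.
.stackDesigns <- function(records, cfg, elements, target) {
  nrec <- length(records)
  P <- length(elements) * .psiLength(cfg) + length(elements)
  Me <- matrix(0, nrec, P)
  natoms <- integer(nrec)
  ye <- numeric(nrec)
  afList <- vector("list", nrec)
  yfList <- vector("list", nrec)
  for (k in seq_len(nrec)) {
    rec <- records[[k]]
    dm <- .designMatrix(rec@structure, cfg, elements)
    natoms[k] <- nAtoms(rec)
    Me[k, ] <- dm$Ae
    ye[k] <- .recordTarget(rec, target)
    afList[[k]] <- dm$Af
    yfList[[k]] <- as.numeric(t(rec@forces))
  }
  Mf <- do.call(rbind, afList)
  yf <- unlist(yfList)
  frows <- split(seq_len(nrow(Mf)),
                 factor(rep(seq_len(nrec), times = 3 * natoms),
                        levels = seq_len(nrec)))
  list(Me = Me, ye = ye, natoms = natoms, Mf = Mf, yf = yf, frows = frows,
       P = P)
}

## Direct solution of the (convex, linear-in-parameters) weighted
## least-squares objective via ridge-regularized normal equations — the
## route linear-model potentials (SNAP/ACE-style fits) use in practice.
.trainLSQ <- function(St, Sv, ew, fw, l2) {
  nE <- nrow(St$Me); nF <- nrow(St$Mf)
  A <- rbind(St$Me / St$natoms * sqrt(ew / nE), -St$Mf * sqrt(fw / nF))
  b <- c(St$ye / St$natoms * sqrt(ew / nE), St$yf * sqrt(fw / nF))
  G <- crossprod(A)
  diag(G) <- diag(G) + max(l2, 1e-10 * mean(diag(G)))
  theta <- tryCatch(solve(G, crossprod(A, b)), error = function(e) {
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > 1e-12 * max(eg$values)
    eg$vectors[, keep] %*% (crossprod(eg$vectors[, keep], crossprod(A, b)) /
                            eg$values[keep])
  })
  theta <- as.numeric(theta)
  mt <- .lossAndMetrics(theta, St, ew, fw)
  mv <- .lossAndMetrics(theta, Sv, ew, fw)
  list(theta = theta,
       history = data.frame(epoch = 1L, trainLoss = mt$loss,
                            valLoss = mv$loss, trainMaeE = mt$maeE,
                            valMaeE = mv$maeE, trainMaeF = mt$maeF,
                            valMaeF = mv$maeF, lr = NA_real_,
                            bestValLoss = mv$loss))
}

.lossAndMetrics <- function(theta, S, ew, fw) {
  resE <- (S$Me %*% theta - S$ye) / S$natoms
  resF <- -(S$Mf %*% theta) - S$yf
  list(loss = ew * mean(resE^2) + fw * mean(resF^2),
       maeE = mean(abs(resE)), maeF = mean(abs(resF)),
       rmseE = sqrt(mean(resE^2)), rmseF = sqrt(mean(resF^2)))
}

#' Train the baseline descriptor potential
#'
#' Minimizes `energy_weight * MSE(per-atom energy) + force_weight *
#' MSE(force components)` by mini-batch first-order optimization (Adam by
#' default, plain SGD switchable), with the published protocol defaults:
#' force:energy weighting 10:1, learning rate 0.005, batch size 5. The
#' model with the best validation loss seen during training is returned;
#' the training history records per-epoch train/validation MAE for
#' per-atom energies and force components.
#'
#' @param train,val lists of [LabeledRecord-class]; all records must share
#'   one environment tag.
#' @param tcfg training config block (see [defaultConfig()]); `target` is
#'   "cohesive" (default) or "total".
#' @param dcfg descriptor config from [descriptorConfig()].
#' @param atomicRef optional named isolated-atom energies (eV), stored with
#'   the model so cohesive predictions can be converted to totals.
#' @return a fitted [BaselineModel-class].
#' @export
trainModel <- function(train, val, tcfg = defaultConfig()$training,
                       dcfg = descriptorConfig(), atomicRef = numeric()) {
  stopifnot(length(train) >= 1, length(val) >= 1)
  envs <- unique(vapply(c(train, val), function(r) r@environment, ""))
  if (length(envs) != 1)
    stop("all records must share one environment tag; found: ",
         paste(envs, collapse = ", "))
  target <- if (is.null(tcfg$target)) "cohesive" else tcfg$target
  elements <- sort(unique(unlist(lapply(train, atomSpecies))))
  St <- .stackDesigns(train, dcfg, elements, target)
  Sv <- .stackDesigns(val, dcfg, elements, target)
  ## scale columns to comparable magnitude so one learning rate serves all
  colScale <- sqrt(colMeans(rbind(St$Me / St$natoms, St$Mf)^2))
  ## floor relative to the largest column: near-dead columns (tiny products
  ## of far-tail Gaussians) must not be amplified into the active range
  colScale <- pmax(colScale, 1e-4 * max(colScale, 1e-300))
  if (max(colScale) <= 0) colScale[] <- 1
  St$Me <- sweep(St$Me, 2, colScale, "/"); St$Mf <- sweep(St$Mf, 2, colScale, "/")
  Sv$Me <- sweep(Sv$Me, 2, colScale, "/"); Sv$Mf <- sweep(Sv$Mf, 2, colScale, "/")
  ew <- tcfg$energy_weight; fw <- tcfg$force_weight
  stopifnot(ew > 0 || fw > 0, fw >= 0, ew >= 0)
  ## small ridge penalty: pins the null directions of the (convex) problem
  ## so differently-seeded fits share one optimum away from the data too
  l2 <- tcfg$l2 %||% 1e-6
  P <- St$P
  rng <- .seededRNG(if (is.null(tcfg$seed)) 1L else tcfg$seed)
  ## small random initialization: committee members trained with different
  ## seeds start from different weights (and see different batch orders)
  theta <- 0.05 * rng$norm(P)
  optimizer <- tcfg$optimizer %||% "adam"
  if (identical(optimizer, "lsq")) {
    fitted <- .trainLSQ(St, Sv, ew, fw, l2)
    return(new("BaselineModel", name = "baseline-descriptor",
               elements = elements, supportedElements = elements,
               theta = as.numeric(fitted$theta / colScale), descriptor = dcfg,
               featureScale = 1, target = target, environment = envs,
               atomicRef = atomicRef, history = fitted$history))
  }
  mAdam <- numeric(P); vAdam <- numeric(P)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  lr <- tcfg$learning_rate
  nrec <- length(train)
  bs <- max(1L, min(nrec, as.integer(tcfg$batch_size)))
  decayFactor <- tcfg$lr_decay %||% 0.5
  decayPatience <- tcfg$lr_patience %||% 20L
  minLr <- tcfg$min_lr %||% 1e-5
  plateauTol <- tcfg$plateau_tol %||% 1e-4
  bestVal <- Inf; bestTheta <- theta
  bestTrain <- Inf
  ## small datasets have few batches per epoch; run at least min_steps
  ## optimizer steps so every fit reaches a comparable optimization depth
  minSteps <- tcfg$min_steps %||% 20000L
  nBatches <- ceiling(nrec / bs)
  nEpochs <- max(as.integer(tcfg$max_epochs),
                 min(20000L, as.integer(ceiling(minSteps / nBatches))))
  bestVal <- Inf
  hist <- vector("list", nEpochs)
  sinceBest <- 0L
  sincePlateau <- 0L
  step <- 0L
  for (epoch in seq_len(nEpochs)) {
    ord <- rng$sample(nrec, nrec)
    for (b0 in seq(1, nrec, by = bs)) {
      batch <- ord[b0:min(b0 + bs - 1, nrec)]
      nb <- length(batch)
      resE <- (St$Me[batch, , drop = FALSE] %*% theta - St$ye[batch]) / St$natoms[batch]
      gradE <- crossprod(St$Me[batch, , drop = FALSE] / St$natoms[batch],
                         resE) * (2 * ew / nb)
      fr <- unlist(St$frows[batch], use.names = FALSE)
      resF <- -(St$Mf[fr, , drop = FALSE] %*% theta) - St$yf[fr]
      gradF <- crossprod(St$Mf[fr, , drop = FALSE], resF) *
        (-2 * fw / length(fr))
      grad <- as.numeric(gradE + gradF) + 2 * l2 * theta
      if (any(!is.finite(grad)))
        stop("training diverged (non-finite gradient); try a smaller learning rate")
      step <- step + 1L
      if (identical(tcfg$optimizer, "sgd")) {
        theta <- theta - lr * grad
      } else {
        mAdam <- beta1 * mAdam + (1 - beta1) * grad
        vAdam <- beta2 * vAdam + (1 - beta2) * grad^2
        mh <- mAdam / (1 - beta1^step)
        vh <- vAdam / (1 - beta2^step)
        theta <- theta - lr * mh / (sqrt(vh) + epsA)
      }
    }
    mt <- .lossAndMetrics(theta, St, ew, fw)
    mv <- .lossAndMetrics(theta, Sv, ew, fw)
    if (!is.finite(mt$loss))
      stop("training diverged (loss is not finite); try a smaller learning rate")
    if (mv$loss < bestVal) {
      bestVal <- mv$loss; bestTheta <- theta; sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    ## plateau detection on the optimization (training) loss
    if (mt$loss < bestTrain * (1 - plateauTol)) {
      bestTrain <- min(bestTrain, mt$loss)
      sincePlateau <- 0L
    } else {
      bestTrain <- min(bestTrain, mt$loss)
      sincePlateau <- sincePlateau + 1L
    }
    hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = mt$loss,
                                valLoss = mv$loss, trainMaeE = mt$maeE,
                                valMaeE = mv$maeE, trainMaeF = mt$maeF,
                                valMaeF = mv$maeF, lr = lr,
                                bestValLoss = bestVal)
    ## reduce-on-plateau learning-rate schedule
    if (sincePlateau >= decayPatience) {
      lr <- lr * decayFactor
      sincePlateau <- 0L
    }
    if (lr < minLr) break
    if (!is.null(tcfg$patience) && sinceBest >= tcfg$patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  new("BaselineModel", name = "baseline-descriptor", elements = elements,
      supportedElements = elements, theta = as.numeric(bestTheta / colScale),
      descriptor = dcfg, featureScale = 1, target = target,
      environment = envs, atomicRef = atomicRef, history = history)
}

#' @describeIn calculate baseline-model evaluation. Returns the energy on
#'   the model's training-target scale (cohesive by default; add the
#'   isolated-atom references for totals) and analytic forces from the
#'   chain rule through the descriptor gradients. For environment-specific
#'   models the requested environment must match the model's.
#' @export
setMethod("calculate", "BaselineModel",
  function(calculator, structure, environment = "gas", ...) {
    if (nzchar(calculator@environment) &&
        !identical(environment, calculator@environment))
      stop(sprintf("model was trained for the %s environment, not %s",
                   calculator@environment, environment))
    dm <- .designMatrix(structure, calculator@descriptor, calculator@elements)
    e <- as.numeric(dm$Ae %*% calculator@theta)
    f <- matrix(-as.numeric(dm$Af %*% calculator@theta), ncol = 3, byrow = TRUE)
    list(energy = e, forces = f)
  })

#' Serialize a baseline model to a portable text file
#'
#' Versioned JSON: descriptor configuration, element list, parameter
#' vector, target convention and atomic references. [loadModel()] restores
#' an equivalent [BaselineModel-class].
#'
#' @param model a [BaselineModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  payload <- list(format = "nnpforge-baseline-model", version = 1L,
                  name = model@name, elements = model@elements,
                  target = model@target, environment = model@environment,
                  descriptor = model@descriptor[c("cutoff_radius", "n_radial",
                                                  "r_min", "elements",
                                                  "degree")],
                  theta = model@theta,
                  atomicRef = as.list(model@atomicRef))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "nnpforge-baseline-model"))
    stop("not a serialized baseline model: ", path)
  dcfg <- descriptorConfig(p$descriptor$cutoff_radius, p$descriptor$n_radial,
                           p$descriptor$r_min, p$descriptor$elements,
                           p$descriptor$degree)
  new("BaselineModel", name = p$name, elements = p$elements,
      supportedElements = p$elements, theta = as.numeric(p$theta),
      descriptor = dcfg, featureScale = 1, target = p$target,
      environment = p$environment,
      atomicRef = unlist(p$atomicRef) %||% numeric(),
      history = data.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
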