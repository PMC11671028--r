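# Solvation-box construction and minimization behind a pluggable backend
# contract. The "engine" backend hands the solvated system to an external
# molecular-dynamics engine (registered via
# options(mumiscan.engineBackend = <function>)); the built-in "fallback"
# backend is a vacuum steepest-descent minimizer on a reduced potential
# (harmonic bonds/angles at the input geometry, Lennard-Jones,
# distance-capped Coulomb) used for testing and desk-scale pipelines.

#' Solvation specification
#'
#' @param padding minimum solute-to-box-face distance, A (default 10, so
#'   periodic images are separated by at least 20 A).
#' @param salt salt species (default "KCl").
#' @param concentration salt concentration, mol/L (default 0.15, isotonic).
#' @param waterModel water model identifier (three-site default).
#' @param neutralize add counterions to neutralise the solute charge.
#' @return list of class `SolvationSpec`.
#' @export
solvationSpec <- function(padding = 10, salt = "KCl", concentration = 0.15,
                          waterModel = "three-site", neutralize = TRUE) {
  stopifnot(padding > 0, concentration >= 0)
  structure(list(padding = padding, salt = salt,
                 concentration = concentration, waterModel = waterModel,
                 neutralize = neutralize), class = "SolvationSpec")
}

#' Minimization specification
#'
#' @param steps maximum number of minimization steps (default 10000).
#' @param backend `"fallback"` (built-in reduced potential) or `"engine"`
#'   (registered external engine).
#' @param energyReportInterval record the energy every this many accepted
#'   steps.
#' @param energyThreshold final energies above this value mark the run as
#'   failed (default `Inf`; cohort-level flagging is applied by
#'   [runMumi()]).
#' @return list of class `MinimizationSpec`.
#' @export
minimizationSpec <- function(steps = 10000L,
                             backend = c("fallback", "engine"),
                             energyReportInterval = 50L,
                             energyThreshold = Inf) {
  stopifnot(steps > 0)
  structure(list(steps = as.integer(steps), backend = match.arg(backend),
                 energyReportInterval = as.integer(energyReportInterval),
                 energyThreshold = energyThreshold),
            class = "MinimizationSpec")
}

.AVOGADRO_PER_A3 <- 6.02214076e-4  # molecules per A^3 at 1 mol/L
.WATER_NUMBER_DENSITY <- 0.0334    # molecules per A^3

#' Solvate a structure in a cubic box with salt
#'
#' Builds a cubic box whose edge is at least the solute extent plus twice
#' the padding, fills it with a pre-equilibrated water lattice pruned by a
#' 2.4 A heavy-atom overlap criterion, and places ions by seeded random
#' substitution of waters: `round(concentration x volume x N_A)` of each
#' salt species plus counterions neutralising the solute formal charge.
#'
#' @param structure solute [Structure-class].
#' @param spec a [solvationSpec()].
#' @param seed integer; identical seeds give identical water/ion placement.
#' @return a [SolvatedSystem-class].
#' @export
buildBox <- function(structure, spec = solvationSpec(), seed = 1L) {
  co <- coords(structure)[isHeavy(structure), , drop = FALSE]
  lo <- apply(co, 2L, min)
  hi <- apply(co, 2L, max)
  edge <- max(hi - lo) + 2 * spec$padding
  center <- (lo + hi) / 2
  origin <- center - edge / 2

  spacing <- .WATER_NUMBER_DENSITY^(-1 / 3)
  nside <- floor(edge / spacing)
  g <- (seq_len(nside) - 0.5) * spacing
  lat <- as.matrix(expand.grid(g, g, g))
  lat <- sweep(lat, 2L, origin, "+")
  ## prune waters overlapping the solute (heavy-atom distance < 2.4 A)
  if (nrow(co)) {
    d <- crossDist(lat, co)
    lat <- lat[apply(d, 1L, min) >= 2.4, , drop = FALSE]
  }

  nSalt <- round(spec$concentration * edge^3 * .AVOGADRO_PER_A3)
  a <- atomData(structure)
  q <- round(sum(formalCharge(a$resname, a$name)))
  species <- strsplit(spec$salt, "(?<=[a-z])(?=[A-Z])", perl = TRUE)[[1L]]
  if (length(species) != 2L) species <- c("K", "Cl")
  nCat <- nSalt + if (spec$neutralize) max(0L, -q) else 0L
  nAni <- nSalt + if (spec$neutralize) max(0L, q) else 0L
  nIons <- nCat + nAni
  if (nIons > nrow(lat))
    stop("box too small to place ", nIons, " ions")
  set.seed(seed)
  pick <- if (nIons > 0L) sample(nrow(lat), nIons) else integer()
  ions <- data.frame(
    species = rep(c(species[1L], species[2L]), c(nCat, nAni)),
    x = lat[pick, 1L], y = lat[pick, 2L], z = lat[pick, 3L],
    stringsAsFactors = FALSE)
  waters <- if (length(pick)) lat[-pick, , drop = FALSE] else lat
  new("SolvatedSystem", solute = structure, waters = waters, ions = ions,
      boxEdge = edge, origin = origin)
}

## ---------------------------------------------------------------------------
## Reduced fallback potential (kcal/mol, A, radians)
## ---------------------------------------------------------------------------

.KBOND <- 300
.KANGLE <- 50
.KHRES <- 10
.COULOMB_K <- 332.0636
.DIELECTRIC <- 10
.COULOMB_CAP <- 2.0

## topology: bonds (with equilibrium at the input geometry - ideal for
## template-built structures), angles, and nonbonded pair list
.fallbackTopology <- function(structure) {
  co <- coords(structure)
  a <- atomData(structure)
  n <- nrow(co)
  bonds <- .bondList(structure)
  r0 <- if (nrow(bonds))
    sqrt(rowSums((co[bonds[, 1L], , drop = FALSE] -
                    co[bonds[, 2L], , drop = FALSE])^2)) else numeric()
  ## angles from the bond graph
  ang <- matrix(integer(), 0L, 3L)
  if (nrow(bonds)) {
    adj <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
    angList <- list()
    for (ctr in names(adj)) {
      nb <- sort(unique(adj[[ctr]]))
      if (length(nb) >= 2L) {
        cmb <- utils::combn(nb, 2L)
        angList[[ctr]] <- cbind(cmb[1L, ], as.integer(ctr), cmb[2L, ])
      }
    }
    if (length(angList)) ang <- do.call(rbind, angList)
  }
  th0 <- if (nrow(ang))
    vapply(seq_len(nrow(ang)), function(k)
      angleDeg(co[ang[k, 1L], ], co[ang[k, 2L], ], co[ang[k, 3L], ]) *
        .deg2rad, numeric(1)) else numeric()
  ## nonbonded: all pairs minus 1-2/1-3
  nb <- matrix(integer(), 0L, 2L)
  if (n >= 2L) {
    cmb <- t(utils::combn(n, 2L))
    keys <- paste(cmb[, 1L], cmb[, 2L])
    excl <- .excludedPairs(structure, bonds)
    nb <- cmb[!keys %in% excl, , drop = FALSE]
  }
  el <- toupper(a$element)
  lj <- ljParameters(unique(el))
  eps <- stats::setNames(lj$eps, lj$element)[el]
  rv <- stats::setNames(lj$rvdw, lj$element)[el]
  ## hydrogen-bond accommodation of the reduced model: polar hydrogens get
  ## a small repulsive core, and inter-residue N/O pairs a minimum at the
  ## hydrogen-bonded contact distance instead of the vdW contact
  rv[el == "H"] <- 0.6
  eps[el == "H"] <- 0.01
  epsPair <- sqrt(eps[nb[, 1L]] * eps[nb[, 2L]])
  rmPair <- rv[nb[, 1L]] + rv[nb[, 2L]]
  if (nrow(nb)) {
    polar <- el[nb[, 1L]] %in% c("N", "O") & el[nb[, 2L]] %in% c("N", "O")
    diffRes <- paste(a$chain[nb[, 1L]], a$resno[nb[, 1L]]) !=
      paste(a$chain[nb[, 2L]], a$resno[nb[, 2L]])
    hb <- polar & diffRes
    rmPair[hb] <- pmin(rmPair[hb], 2.85)
    epsPair[hb] <- pmax(epsPair[hb], 0.20)
  }
  ## soft restraints on hydrogen bonds present in the input: a weak
  ## harmonic H...acceptor term supplies the directionality the isotropic
  ## nonbonded terms lack, so relaxation preserves input interactions
  ## while relieving strain (absent donors get no restraint)
  hIdx <- which(el == "H" & !a$het)
  accIdx <- which(el %in% c("N", "O") & !a$het)
  hres <- matrix(integer(), 0L, 2L)
  hresR0 <- numeric()
  if (length(hIdx) && length(accIdx)) {
    d <- crossDist(co[hIdx, , drop = FALSE], co[accIdx, , drop = FALSE])
    sameRes <- outer(paste(a$chain[hIdx], a$resno[hIdx]),
                     paste(a$chain[accIdx], a$resno[accIdx]), "==")
    hit <- which(d <= 2.5 & !sameRes, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      h <- hIdx[hit[k, 1L]]
      acc <- accIdx[hit[k, 2L]]
      ## hold the H...A contact plus the donor-vertex angle, so the bond
      ## direction (what the geometric criterion measures) is preserved,
      ## not just the contact distance
      hres <- rbind(hres, c(h, acc))
      hresR0 <- c(hresR0, max(d[hit[k, 1L], hit[k, 2L]], 1.85))
      don <- which(el %in% c("N", "O", "S") & !a$het &
                     a$chain == a$chain[h] & a$resno == a$resno[h])
      if (length(don)) {
        dd <- sqrt(distSqTo(co[h, ], co[don, , drop = FALSE]))
        don <- don[which.min(dd)]
        if (min(dd) < 1.45) {
          ang <- rbind(ang, c(h, don, acc))
          th0 <- c(th0, angleDeg(co[h, ], co[don, ], co[acc, ]) * .deg2rad)
        }
      }
    }
  }
  charge <- formalCharge(a$resname, a$name)
  list(bonds = bonds, r0 = r0, angles = ang, th0 = th0, nb = nb,
       epsPair = epsPair, rmPair = rmPair,
       qqPair = charge[nb[, 1L]] * charge[nb[, 2L]],
       hres = hres, hresR0 = hresR0)
}

.accumulate <- function(g, idx, val) {
  s <- rowsum(val, idx)
  rows <- as.integer(rownames(s))
  g[rows, ] <- g[rows, ] + s
  g
}

## energy and gradient of the reduced potential
.fallbackEnergy <- function(x, top, gradient = TRUE) {
  n <- nrow(x)
  E <- 0
  g <- if (gradient) matrix(0, n, 3L) else NULL
  if (nrow(top$bonds)) {
    i <- top$bonds[, 1L]; j <- top$bonds[, 2L]
    u <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- sqrt(rowSums(u^2))
    dr <- r - top$r0
    E <- E + .KBOND * sum(dr^2)
    if (gradient) {
      coef <- 2 * .KBOND * dr / pmax(r, 1e-8)
      gi <- u * coef
      g <- .accumulate(g, i, gi)
      g <- .accumulate(g, j, -gi)
    }
  }
  if (nrow(top$angles)) {
    i <- top$angles[, 1L]; jc <- top$angles[, 2L]; k <- top$angles[, 3L]
    u <- x[i, , drop = FALSE] - x[jc, , drop = FALSE]
    v <- x[k, , drop = FALSE] - x[jc, , drop = FALSE]
    ru <- sqrt(rowSums(u^2)); rv <- sqrt(rowSums(v^2))
    ct <- rowSums(u * v) / (ru * rv)
    ct <- pmin(1 - 1e-10, pmax(-1 + 1e-10, ct))
    th <- acos(ct)
    dth <- th - top$th0
    E <- E + .KANGLE * sum(dth^2)
    if (gradient) {
      st <- sqrt(1 - ct^2)
      uh <- u / ru; vh <- v / rv
      dthi <- (uh * ct - vh) / (ru * st)
      dthk <- (vh * ct - uh) / (rv * st)
      coef <- 2 * .KANGLE * dth
      gi <- dthi * coef
      gk <- dthk * coef
      g <- .accumulate(g, i, gi)
      g <- .accumulate(g, k, gk)
      g <- .accumulate(g, jc, -(gi + gk))
    }
  }
  if (nrow(top$hres)) {
    i <- top$hres[, 1L]; j <- top$hres[, 2L]
    u <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- sqrt(rowSums(u^2))
    dr <- r - top$hresR0
    E <- E + .KHRES * sum(dr^2)
    if (gradient) {
      coef <- 2 * .KHRES * dr / pmax(r, 1e-8)
      gi <- u * coef
      g <- .accumulate(g, i, gi)
      g <- .accumulate(g, j, -gi)
    }
  }
  if (nrow(top$nb)) {
    i <- top$nb[, 1L]; j <- top$nb[, 2L]
    u <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- sqrt(rowSums(u^2))
    r <- pmax(r, 0.3)
    s6 <- (top$rmPair / r)^6
    E <- E + sum(top$epsPair * (s6^2 - 2 * s6))
    rc <- pmax(r, .COULOMB_CAP)
    E <- E + sum(.COULOMB_K * top$qqPair / (.DIELECTRIC * rc))
    if (gradient) {
      dEdr <- -12 * top$epsPair / r * (s6^2 - s6)
      dEdr <- dEdr - ifelse(r > .COULOMB_CAP,
                            .COULOMB_K * top$qqPair / (.DIELECTRIC * r^2), 0)
      coef <- dEdr / r
      gi <- u * coef
      g <- .accumulate(g, i, gi)
      g <- .accumulate(g, j, -gi)
    }
  }
  list(E = E, g = g)
}

#' Minimize a structure or solvated system
#'
#' With the `"fallback"` backend, runs adaptive steepest descent on the
#' reduced vacuum potential until the step budget is exhausted or the
#' energy change stalls; the reported energy sequence is non-increasing.
#' With the `"engine"` backend the solvated system is handed to a
#' registered external engine (`options(mumiscan.engineBackend = fn)`); an
#' informative error instructs the caller to use the fallback when no
#' engine is registered.
#'
#' @param x a [Structure-class] (vacuum) or [SolvatedSystem-class].
#' @param spec a [minimizationSpec()].
#' @return a [RelaxResult-class]; the result structure is the solute only.
#' @export
minimizeSystem <- function(x, spec = minimizationSpec()) {
  if (spec$backend == "engine") {
    fn <- getOption("mumiscan.engineBackend")
    if (!is.function(fn))
      stop("minimization backend 'engine' is not available; register one ",
           "via options(mumiscan.engineBackend = <function>) or use ",
           'backend = "fallback"')
    return(fn(x, spec))
  }
  st <- if (is(x, "SolvatedSystem")) solute(x) else x
  stopifnot(is(st, "Structure"))
  top <- .fallbackTopology(st)
  co <- coords(st)
  ev <- .fallbackEnergy(co, top)
  E0 <- ev$E
  if (!is.finite(E0)) {
    return(new("RelaxResult", structure = st, initialEnergy = E0,
               finalEnergy = E0, converged = FALSE,
               failureReason = "non-finite initial energy",
               trace = numeric()))
  }
  E <- E0
  trace <- E0
  failure <- ""
  fn <- function(p) {
    v <- .fallbackEnergy(matrix(p, ncol = 3L), top, gradient = FALSE)$E
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(p) {
    g <- .fallbackEnergy(matrix(p, ncol = 3L), top)$g
    g[!is.finite(g)] <- 0
    as.vector(g)
  }
  par <- as.vector(co)
  done <- 0L
  while (done < spec$steps) {
    chunk <- min(spec$energyReportInterval, spec$steps - done)
    opt <- tryCatch(
      stats::optim(par, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = chunk)),
      error = function(e) NULL)
    if (is.null(opt)) {
      failure <- "minimizer failure"
      break
    }
    done <- done + chunk
    if (opt$value <= E) {  # descent method never reports worse than start
      par <- opt$par
      dE <- E - opt$value
      E <- opt$value
      trace <- c(trace, E)
      if (dE < 1e-8 * (abs(E) + 1)) break
    } else break
  }
  co <- matrix(par, ncol = 3L)
  out <- st
  coords(out) <- co
  conv <- is.finite(E) && nchar(failure) == 0L && E <= spec$energyThreshold
  if (!conv && nchar(failure) == 0L)
    failure <- if (!is.finite(E)) "non-finite energy" else
      "final energy above threshold"
  new("RelaxResult", structure = out, initialEnergy = E0, finalEnergy = E,
      converged = conv, failureReason = failure, trace = trace)
}

#' Run the mutation-and-minimization scan
#'
#' For each mutation specification: graft the mutant side chain
#' ([applyMutation()]), relax ([minimizeSystem()]; with the engine backend
#' each mutant is first solvated via [buildBox()]), and collect the
#' relaxed solutes into a mutant-collection ensemble with a manifest.
#' Failures are recorded per mutant, never fatal. After the scan, mutants
#' whose final energy is non-finite or exceeds the cohort mean by more
#' than `cohortSigma` standard deviations are flagged as excess-energy
#' failures.
#'
#' @param wt wild-type [Structure-class] (complex or monomer).
#' @param specs data.frame of mutation specifications
#'   ([enumerateMutations()]).
#' @param chain chain to mutate.
#' @param solvation a [solvationSpec()] (engine backend only).
#' @param minimization a [minimizationSpec()].
#' @param cohortSigma excess-energy flagging threshold in cohort standard
#'   deviations (default 5).
#' @param seed integer seed for solvation.
#' @return list with `ensemble` (usable mutants,
#'   [StructureEnsemble-class]), `manifest` (data.frame: label, position,
#'   wt, mut, converged, initial_energy, final_energy, failure_reason) and
#'   `results` (list of [RelaxResult-class]).
#' @export
runMumi <- function(wt, specs, chain = chains(wt)[1L],
                    solvation = solvationSpec(),
                    minimization = minimizationSpec(), cohortSigma = 5,
                    seed = 1L) {
  n <- nrow(specs)
  results <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    spec <- specs[k, ]
    res <- tryCatch({
      mut <- applyMutation(wt, spec, chain = chain)
      sys <- if (minimization$backend == "engine")
        buildBox(mut, solvation, seed = seed + k) else mut
      minimizeSystem(sys, minimization)
    }, error = function(e) {
      new("RelaxResult", structure = wt, initialEnergy = NA_real_,
          finalEnergy = NA_real_, converged = FALSE,
          failureReason = conditionMessage(e), trace = numeric())
    })
    results[[k]] <- res
    rows[[k]] <- data.frame(
      label = spec$label, position = spec$position, wt = spec$wt,
      mut = spec$mut, converged = res@converged,
      initial_energy = res@initialEnergy, final_energy = res@finalEnergy,
      failure_reason = res@failureReason, stringsAsFactors = FALSE)
  }
  manifest <- if (n) do.call(rbind, rows) else data.frame(
    label = character(), position = integer(), wt = character(),
    mut = character(), converged = logical(), initial_energy = numeric(),
    final_energy = numeric(), failure_reason = character(),
    stringsAsFactors = FALSE)
  ## cohort-level excess-energy flagging
  fin <- manifest$final_energy
  ok <- manifest$converged & is.finite(fin)
  if (sum(ok) >= 3L) {
    mu <- mean(fin[ok])
    sg <- stats::sd(fin[ok])
    if (is.finite(sg) && sg > 0) {
      bad <- ok & fin > mu + cohortSigma * sg
      if (any(bad)) {
        manifest$converged[bad] <- FALSE
        manifest$failure_reason[bad] <- "excess energy (cohort outlier)"
        for (k in which(bad)) results[[k]]@converged <- FALSE
      }
    }
  }
  usable <- which(manifest$converged)
  ens <- newEnsemble(lapply(results[usable], relaxedStructure),
                     source = "mutant-collection")
  list(ensemble = ens, manifest = manifest, results = results)
}

#' Count usable systems in a scan manifest
#' @param manifest manifest data.frame from [runMumi()].
#' @return integer count of converged mutants.
#' @export
usableSystems <- function(manifest) sum(manifest$converged)
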