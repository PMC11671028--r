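# Deterministic synthetic-structure generators with known ground truth:
# ideal helical peptides, two-chain toy complexes with hydrogen-bond
# donor/acceptor pairs at prescribed geometry, coordinate-jittered
# ensembles and pseudo-atom clusters. These emulate the geometric features
# the analyses measure; they are not physical decoys.

## Build an ideal peptide chain (N, CA, C, O + template side chains).
## phi/psi recycled over residues; returns a Structure.
buildPeptide <- function(sequence, phi = -57, psi = -47, chain = "A",
                         startResno = 1L, label = "peptide") {
  aa1 <- strsplit(toupper(sequence), "")[[1L]]
  if (!length(aa1)) stop("sequence must be nonempty")
  if (!all(aa1 %in% names(.AA3)))
    stop("non-canonical amino acid letter(s): ",
         paste(unique(aa1[!aa1 %in% names(.AA3)]), collapse = ", "))
  n <- length(aa1)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  resname <- aa123(aa1)

  Ns <- CAs <- Cs <- Os <- matrix(NA_real_, n, 3L)
  Ns[1L, ] <- c(0, 0, 0)
  CAs[1L, ] <- c(1.458, 0, 0)
  dC <- as.vector(rotationMatrix(c(0, 0, 1), 111.2) %*% c(-1, 0, 0))
  Cs[1L, ] <- CAs[1L, ] + 1.525 * dC
  if (n > 1L) {
    for (i in 2:n) {
      Ns[i, ] <- placeAtom(Ns[i - 1L, ], CAs[i - 1L, ], Cs[i - 1L, ],
                           1.329, 116.2, psi[i - 1L])
      CAs[i, ] <- placeAtom(CAs[i - 1L, ], Cs[i - 1L, ], Ns[i, ],
                            1.458, 121.7, 180)
      Cs[i, ] <- placeAtom(Cs[i - 1L, ], Ns[i, ], CAs[i, ],
                           1.525, 111.2, phi[i])
    }
  }
  for (i in seq_len(n)) {
    Os[i, ] <- placeAtom(Ns[i, ], CAs[i, ], Cs[i, ], 1.231, 120.5,
                         psi[i] + 180)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    co <- rbind(Ns[i, ], CAs[i, ], Cs[i, ], Os[i, ])
    sc <- buildSideChain(resname[i], Ns[i, ], CAs[i, ], Cs[i, ])
    if (nrow(sc$atoms)) {
      nm <- c(nm, sc$atoms$name)
      el <- c(el, sc$atoms$element)
      co <- rbind(co, sc$coords)
    }
    rows[[i]] <- list(
      atoms = data.frame(name = nm, element = el,
                         resno = startResno + i - 1L, resname = resname[i],
                         chain = chain, het = FALSE, flag = FALSE,
                         stringsAsFactors = FALSE),
      coords = co)
  }
  atoms <- do.call(rbind, lapply(rows, `[[`, "atoms"))
  coords <- do.call(rbind, lapply(rows, `[[`, "coords"))
  newStructure(atoms, coords, label = label)
}

#' Ideal alpha-helical peptide fixture
#'
#' Builds a peptide on ideal backbone geometry with helical torsions
#' (default phi = -58, psi = -50 degrees, chosen inside the alpha basin so
#' the i -> i+4 amide-carbonyl geometry lands inside the criterion) and
#' single-conformer template
#' side chains. For n >= 5 the i -> i+4 backbone hydrogen bonds satisfy
#' the 3.0 A / 20 degree criterion.
#'
#' @param n number of residues (>= 3).
#' @param sequence 1-letter sequence (default poly-alanine of length `n`).
#' @param phi,psi backbone torsions, degrees.
#' @param chain chain identifier.
#' @return a [Structure-class] object (no hydrogens; see
#'   [addPolarHydrogens()]).
#' @examples
#' h <- makeHelixPeptide(10)
#' detectHBonds(addPolarHydrogens(h))
#' @export
makeHelixPeptide <- function(n, sequence = strrep("A", n), phi = -58,
                             psi = -50, chain = "A") {
  if (n < 3L) stop("helix fixture needs n >= 3")
  if (nchar(sequence) != n) stop("sequence length must equal n")
  buildPeptide(sequence, phi = phi, psi = psi, chain = chain,
               label = sprintf("helix_%d", n))
}

## default donor/acceptor heavy atoms per residue type for the toy dimer
.donorAtomFor <- function(resname) {
  d <- .SC_DONORS[[resname]]
  if (!is.null(d)) names(d)[1L] else "N"
}
.acceptorAtomFor <- function(resname) {
  a <- .SC_ACCEPTORS[[resname]]
  if (!is.null(a)) a[1L] else "O"
}
## bonded heavy parent of an acceptor atom (for orientation)
.parentOf <- function(resname, atom) {
  if (atom == "O") return("C")
  tpl <- .SIDECHAIN_TEMPLATES[[resname]]
  hit <- tpl$rb[tpl$name == atom]
  if (!length(hit)) "CA" else hit[1L]
}

#' Two-chain toy complex with prescribed hydrogen-bond geometry
#'
#' Builds one focal residue per specification on chain A (spaced so the
#' pairs are independent) and places a partner residue on chain B so that
#' the donor-acceptor pair realizes the prescribed heavy-atom distance and
#' donor-vertex angle exactly. Donors use the residue's canonical
#' side-chain donor (backbone/amino N-H for residues without one);
#' acceptors the canonical side-chain acceptor (backbone O otherwise).
#'
#' @param specs data.frame with columns `donor`, `acceptor` (1- or
#'   3-letter residue codes), `distance` (A, donor-acceptor heavy atoms)
#'   and `angle` (degrees at the donor between D-H and D-A).
#' @param spacing separation between consecutive pairs along x (A).
#' @return list with elements `structure` (protonated two-chain
#'   [Structure-class]) and `manifest` (data.frame of the realized
#'   per-pair geometry, with a `satisfied` column evaluated against the
#'   default 3.0 A / 20 degree criterion).
#' @examples
#' td <- makeToyDimer(data.frame(donor = "S", acceptor = "D",
#'                               distance = 2.9, angle = 10))
#' td$manifest
#' @export
makeToyDimer <- function(specs, spacing = 12) {
  stopifnot(is.data.frame(specs),
            all(c("donor", "acceptor", "distance", "angle") %in% names(specs)))
  if (any(specs$distance <= 0) || any(specs$angle < 0) ||
      any(specs$angle >= 90))
    stop("infeasible hydrogen-bond specification: need distance > 0 and ",
         "0 <= angle < 90")
  to1 <- function(x) ifelse(nchar(x) == 1L, toupper(x), aa321(x))
  don1 <- to1(specs$donor)
  acc1 <- to1(specs$acceptor)
  if (any(don1 == "X") || any(acc1 == "X") ||
      any(!c(don1, acc1) %in% names(.AA3)))
    stop("infeasible specification: unknown residue type")

  nspec <- nrow(specs)
  chainAFrames <- vector("list", nspec)
  for (i in seq_len(nspec)) {
    r <- buildPeptide(don1[i], chain = "A", startResno = i,
                      label = "toy_dimer")
    co <- coords(r)
    co[, 1L] <- co[, 1L] + (i - 1L) * spacing
    coords(r) <- co
    chainAFrames[[i]] <- r
  }
  chainA <- do.call(.rbindStructures, chainAFrames)
  chainA <- addPolarHydrogens(chainA)

  aA <- atomData(chainA)
  cA <- coords(chainA)
  partnerFrames <- vector("list", nspec)
  man <- vector("list", nspec)
  for (i in seq_len(nspec)) {
    dres <- aa123(don1[i])
    datom <- .donorAtomFor(dres)
    sel <- aA$chain == "A" & aA$resno == i
    D <- cA[which(sel & aA$name == datom)[1L], ]
    hn <- if (datom == "N") c("H", "H1", "H2", "H3") else
      .SC_DONORS[[dres]][[datom]]
    hIdx <- which(sel & aA$name %in% hn)
    if (!length(hIdx)) stop("internal: donor hydrogen missing for pair ", i)
    H <- cA[hIdx[1L], ]
    u <- unitv(H - D)
    dir <- as.vector(rotationMatrix(perpVector(u), specs$angle[i]) %*% u)
    target <- D + specs$distance[i] * dir

    ares <- aa123(acc1[i])
    aatom <- .acceptorAtomFor(ares)
    patom <- .parentOf(ares, aatom)
    res <- buildPeptide(acc1[i], chain = "B", startResno = i,
                        label = "toy_dimer")
    aR <- atomData(res)
    cR <- coords(res)
    X0 <- cR[which(aR$name == aatom)[1L], ]
    P0 <- cR[which(aR$name == patom)[1L], ]
    from <- unitv(P0 - X0)
    to <- unitv(target - D)
    ax <- cross3(from, to)
    R <- if (vnorm(ax) < 1e-8) diag(3) else
      rotationMatrix(ax, angleDeg(from, c(0, 0, 0), to))
    cR <- sweep(cR, 2L, X0) %*% t(R)
    cR <- sweep(cR, 2L, target, "+")
    coords(res) <- cR
    partnerFrames[[i]] <- res

    angles <- vapply(hIdx, function(k)
      angleDeg(cA[k, ], D, target), numeric(1))
    man[[i]] <- data.frame(
      pair = i, donor_resno = i, donor_resname = dres, donor_atom = datom,
      acceptor_resno = i, acceptor_resname = ares, acceptor_atom = aatom,
      distance = specs$distance[i], angle = min(angles),
      stringsAsFactors = FALSE)
  }
  chainB <- do.call(.rbindStructures, partnerFrames)
  structure <- .rbindStructures(chainA, chainB)
  structure@label <- "toy_dimer"
  manifest <- do.call(rbind, man)
  manifest$satisfied <- manifest$distance <= 3.0 & manifest$angle <= 20
  list(structure = structure, manifest = manifest)
}

## concatenate structures, renumbering serials
.rbindStructures <- function(...) {
  parts <- list(...)
  atoms <- do.call(rbind, lapply(parts, atomData))
  co <- do.call(rbind, lapply(parts, coords))
  atoms$serial <- seq_len(nrow(atoms))
  newStructure(atoms, co, label = parts[[1L]]@label)
}

#' Coordinate-jittered ensemble
#'
#' `n` copies of a base structure with i.i.d. Gaussian displacement of
#' every atomic coordinate; a stand-in for dynamical ensembles when
#' exercising occupancy and binding-probability statistics. The jitter is
#' uncorrelated noise, not physical dynamics.
#'
#' @param base a [Structure-class].
#' @param sigma displacement standard deviation per coordinate (A).
#' @param nFrames number of frames.
#' @param seed integer seed; the output is byte-identical for a fixed seed.
#' @return a [StructureEnsemble-class] with source `"trajectory"`.
#' @export
makeJitterEnsemble <- function(base, sigma, nFrames, seed = 1L) {
  stopifnot(sigma >= 0, nFrames >= 1L)
  co <- coords(base)
  set.seed(seed)
  frames <- lapply(seq_len(nFrames), function(i) {
    s <- base
    s@coords <- co + matrix(stats::rnorm(length(co), sd = sigma),
                            nrow = nrow(co))
    s@label <- sprintf("%s_frame%d", base@label, i)
    s
  })
  newEnsemble(frames, source = "trajectory")
}

#' Pseudo-atom cluster fixtures
#'
#' `makeAtomCluster` wraps raw coordinates as a hetero pseudo-structure
#' (one pseudo-residue per atom) for surface-area tests;
#' `makeSphereCluster` samples `n` atoms uniformly in a ball of the given
#' radius (seeded, deterministic).
#'
#' @param coords numeric n x 3 matrix (A).
#' @param element element symbol(s), recycled.
#' @return a [Structure-class] of flagged hetero pseudo-atoms.
#' @export
makeAtomCluster <- function(coords, element = "C") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  el <- rep_len(toupper(element), n)
  atoms <- data.frame(name = paste0(el, seq_len(n)), element = el,
                      resno = seq_len(n), resname = "SPH", chain = "X",
                      het = TRUE, flag = FALSE, stringsAsFactors = FALSE)
  newStructure(atoms, coords, label = "cluster")
}

#' @rdname makeAtomCluster
#' @param n number of atoms.
#' @param radius ball radius (A).
#' @param seed integer seed.
#' @export
makeSphereCluster <- function(n, radius = 8, seed = 1L, element = "C") {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3L * n), ncol = 3L)
  pts <- pts / sqrt(rowSums(pts^2)) * radius * stats::runif(n)^(1 / 3)
  makeAtomCluster(pts, element = element)
}
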