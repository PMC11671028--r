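# Geometric hydrogen-bond analysis: deterministic polar-hydrogen
# construction, donor/acceptor detection under a distance+angle criterion,
# ensemble occupancies, dominant-bond selection, maintained-WT-bond
# counting and salt-bridge center-of-mass distances.

#' Hydrogen-bond criterion
#'
#' The geometric definition used throughout: heavy-atom donor-acceptor
#' distance at most `dMax` and hydrogen-bond angle at most `thetaMax`
#' (both inclusive). The angle is measured at the donor between the D-H
#' and D-A vectors by default (`angleConvention = "donor"`); the
#' alternative `"linearity"` convention measures the deviation of D-H...A
#' from linear at the hydrogen.
#'
#' @param dMax donor-acceptor distance cutoff, A (default 3.0).
#' @param thetaMax angle cutoff, degrees (default 20).
#' @param angleConvention `"donor"` or `"linearity"`.
#' @return list of class `HBondCriterion`.
#' @export
hbondCriterion <- function(dMax = 3.0, thetaMax = 20,
                           angleConvention = c("donor", "linearity")) {
  stopifnot(dMax > 0, thetaMax > 0, thetaMax < 90)
  structure(list(dMax = dMax, thetaMax = thetaMax,
                 angleConvention = match.arg(angleConvention)),
            class = "HBondCriterion")
}

## ---------------------------------------------------------------------------
## Polar hydrogen construction
## ---------------------------------------------------------------------------

.NH_BOND <- 1.01
.OH_BOND <- 0.96
.SH_BOND <- 1.34

## sp3 rotatable group: hydrogens on a cone about the X->parent axis,
## oriented so the first H points toward the nearest acceptor (or phi = 0
## when no acceptor exists). Returns k x 3 matrix.
.rotatableHs <- function(X, parent, k, bond, acceptors) {
  u <- unitv(X - parent)           # axis away from parent
  e1 <- perpVector(u)
  e2 <- cross3(u, e1)
  th <- (180 - 109.5) * .deg2rad   # angle of H direction from u
  hdir <- function(phi) {
    cos(th) * u + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
  }
  phi0 <- 0
  if (!is.null(acceptors) && nrow(acceptors)) {
    phis <- seq(0, 2 * pi, length.out = 181L)[-181L]
    best <- Inf
    for (p in phis) {
      H <- X + bond * hdir(p)
      dmin <- min(distSqTo(H, acceptors))
      if (dmin < best - 1e-12) {
        best <- dmin
        phi0 <- p
      }
    }
  }
  t(vapply(seq_len(k) - 1L,
           function(j) X + bond * hdir(phi0 + j * 2 * pi / k),
           numeric(3L)))
}

## sp2 N-H on a nitrogen with two heavy neighbours: bisector placement
.bisectorH <- function(X, nb1, nb2, bond = .NH_BOND) {
  X + bond * unitv(-(unitv(nb1 - X) + unitv(nb2 - X)))
}

## sp2 NH2: two hydrogens in the plane defined by (ref, parent, X)
.sp2TwoHs <- function(X, parent, ref, bond = .NH_BOND) {
  nrm <- unitv(cross3(parent - ref, X - parent))
  u <- unitv(parent - X)
  rbind(X + bond * as.vector(rotationMatrix(nrm, 120) %*% u),
        X + bond * as.vector(rotationMatrix(nrm, -120) %*% u))
}

#' Add polar hydrogens at ideal geometry
#'
#' Constructs hydrogens on N-H, O-H, S-H and terminal NH3+ groups of
#' standard residues: backbone amide H in the C-N-CA plane opposite the
#' bisector; fixed sp2 hydrogens (Arg, Asn, Gln, Trp, His) from the local
#' plane; rotatable O-H/S-H/NH3+ groups oriented toward the nearest
#' acceptor (deterministic; ties resolved by lowest residue index then
#' atom name, and a fixed reference orientation is used when no acceptor
#' exists). Existing hydrogens are preserved, so the operation is
#' idempotent. Nonstandard residues are skipped with a warning.
#'
#' @param structure a [Structure-class] with complete heavy atoms.
#' @param hisTautomer `"ND1"` (default, neutral ND1-protonated) or
#'   `"NE2"`.
#' @return protonated [Structure-class].
#' @export
addPolarHydrogens <- function(structure, hisTautomer = c("ND1", "NE2")) {
  hisTautomer <- match.arg(hisTautomer)
  a <- atomData(structure)
  co <- coords(structure)
  std <- !a$het & isStandardRes(a$resname)
  skip <- unique(a$resname[!a$het & !isStandardRes(a$resname)])
  if (length(skip))
    warning("nonstandard residue(s) skipped during protonation: ",
            paste(skip, collapse = ", "), call. = FALSE)

  ## acceptor heavy-atom coordinates (for orienting rotatable groups);
  ## ordered by residue index then atom name for deterministic ties
  accIdx <- .acceptorIndices(a)
  ord <- order(a$resno[accIdx], a$name[accIdx])
  accCo <- co[accIdx[ord], , drop = FALSE]

  rt <- residueTable(structure)
  newAtoms <- list()
  newCo <- list()
  key <- paste(a$chain, a$resno)

  getAt <- function(idx, nm) {
    j <- idx[a$name[idx] == nm]
    if (!length(j)) NULL else co[j[1L], ]
  }
  hasH <- function(idx, nms) any(a$name[idx] %in% nms)
  addH <- function(resrow, names, coords) {
    coords <- rbind(coords)
    newAtoms[[length(newAtoms) + 1L]] <<- data.frame(
      name = names, element = "H", resno = resrow$resno,
      resname = resrow$resname, chain = resrow$chain, het = FALSE,
      flag = FALSE, stringsAsFactors = FALSE)
    newCo[[length(newCo) + 1L]] <<- coords
  }

  for (r in seq_len(nrow(rt))) {
    rr <- rt[r, ]
    if (!isStandardRes(rr$resname)) next
    idx <- which(key == paste(rr$chain, rr$resno) & std)
    N <- getAt(idx, "N"); CA <- getAt(idx, "CA"); C <- getAt(idx, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next

    ## backbone amide / N-terminal amino hydrogens
    if (rr$resname != "PRO" && !hasH(idx, c("H", "H1", "H2", "H3"))) {
      prevIdx <- which(a$chain == rr$chain & a$resno == rr$resno - 1L & std)
      Cprev <- getAt(prevIdx, "C")
      bonded <- !is.null(Cprev) && vnorm(N - Cprev) < 1.8
      if (bonded) {
        addH(rr, "H", .bisectorH(N, CA, Cprev))
      } else {
        hs <- .rotatableHs(N, CA, 3L, .NH_BOND, accCo)
        addH(rr, c("H1", "H2", "H3"), hs)
      }
    }

    scDonors <- .SC_DONORS[[rr$resname]]
    if (is.null(scDonors)) next
    for (datom in names(scDonors)) {
      hn <- scDonors[[datom]]
      if (hasH(idx, hn)) next
      X <- getAt(idx, datom)
      if (is.null(X)) next
      res <- rr$resname
      if (res == "SER" || res == "THR" || res == "TYR" || res == "CYS") {
        parent <- getAt(idx, .parentOf(res, datom))
        bond <- if (res == "CYS") .SH_BOND else .OH_BOND
        addH(rr, hn, .rotatableHs(X, parent, 1L, bond, accCo))
      } else if (res == "LYS") {
        CE <- getAt(idx, "CE")
        addH(rr, hn, .rotatableHs(X, CE, 3L, .NH_BOND, accCo))
      } else if (res == "ARG") {
        if (datom == "NE") {
          addH(rr, hn, .bisectorH(X, getAt(idx, "CD"), getAt(idx, "CZ")))
        } else {
          other <- if (datom == "NH1") "NH2" else "NH1"
          addH(rr, hn, .sp2TwoHs(X, getAt(idx, "CZ"), getAt(idx, other)))
        }
      } else if (res == "ASN" && datom == "ND2") {
        addH(rr, hn, .sp2TwoHs(X, getAt(idx, "CG"), getAt(idx, "OD1")))
      } else if (res == "GLN" && datom == "NE2") {
        addH(rr, hn, .sp2TwoHs(X, getAt(idx, "CD"), getAt(idx, "OE1")))
      } else if (res == "TRP" && datom == "NE1") {
        addH(rr, hn, .bisectorH(X, getAt(idx, "CD1"), getAt(idx, "CE2")))
      } else if (res == "HIS") {
        if (datom != hisTautomer) next
        nbs <- if (datom == "ND1") c("CG", "CE1") else c("CD2", "CE1")
        addH(rr, hn, .bisectorH(X, getAt(idx, nbs[1L]), getAt(idx, nbs[2L])))
      }
    }
  }

  if (!length(newAtoms)) return(structure)
  addA <- do.call(rbind, newAtoms)
  addC <- do.call(rbind, newCo)
  ## insert hydrogens after their residue's atoms, preserving residue order
  allA <- rbind(a[, c("name", "element", "resno", "resname", "chain",
                      "het", "flag")], addA)
  allC <- rbind(co, addC)
  reskey <- paste(allA$chain, allA$resno, allA$het)
  orderKey <- match(reskey, unique(paste(a$chain, a$resno, a$het)))
  ord <- order(orderKey, seq_len(nrow(allA)))
  allA <- allA[ord, , drop = FALSE]
  allC <- allC[ord, , drop = FALSE]
  allA$serial <- seq_len(nrow(allA))
  newStructure(allA, allC, label = structure@label)
}

## ---------------------------------------------------------------------------
## Donor / acceptor bookkeeping
## ---------------------------------------------------------------------------

## indices of acceptor heavy atoms given an atom table; N acceptors only
## when no hydrogen is attached (decided by name lookup in the same table)
.acceptorIndices <- function(a, includeWater = FALSE) {
  std <- !a$het & isStandardRes(a$resname)
  acc <- logical(nrow(a))
  acc[std & a$name %in% c("O", "OXT")] <- TRUE
  for (rn in names(.SC_ACCEPTORS)) {
    hit <- std & a$resname == rn & a$name %in% .SC_ACCEPTORS[[rn]]
    acc[hit] <- TRUE
  }
  ## drop N acceptors that carry a hydrogen (e.g. protonated His ND1)
  nAcc <- which(acc & substr(a$name, 1, 1) == "N")
  if (length(nAcc)) {
    key <- paste(a$chain, a$resno)
    for (i in nAcc) {
      hn <- .SC_DONORS[[a$resname[i]]][[a$name[i]]]
      if (!is.null(hn) &&
          any(a$name[key == key[i]] %in% hn))
        acc[i] <- FALSE
    }
  }
  if (includeWater) acc[isWaterRes(a$resname) & a$element == "O"] <- TRUE
  which(acc)
}

## donors: heavy N/O/S atoms with at least one covalently attached H.
## Returns data.frame(donor = index, hydrogens = list of H indices).
.donorIndices <- function(a, co, includeWater = FALSE) {
  cand <- which(toupper(a$element) %in% c("N", "O", "S") &
                  (includeWater | !isWaterRes(a$resname)) & !a$het)
  hIdx <- which(toupper(a$element) == "H")
  if (!length(cand) || !length(hIdx)) return(list())
  hCo <- co[hIdx, , drop = FALSE]
  out <- vector("list", length(cand))
  nkeep <- 0L
  for (d in cand) {
    d2 <- distSqTo(co[d, ], hCo)
    att <- hIdx[d2 < 1.45^2]
    ## same residue only
    att <- att[a$chain[att] == a$chain[d] & a$resno[att] == a$resno[d]]
    if (length(att)) {
      nkeep <- nkeep + 1L
      out[[nkeep]] <- list(donor = d, hydrogens = att)
    }
  }
  out[seq_len(nkeep)]
}

.moietyOf <- function(name) {
  ifelse(name %in% c("N", "C", "O", "CA", "OXT", "H", "H1", "H2", "H3"),
         "backbone", "side-chain")
}

## ---------------------------------------------------------------------------
## Detection
## ---------------------------------------------------------------------------

#' Detect geometric hydrogen bonds
#'
#' Finds all donor/acceptor pairs whose heavy-atom distance and
#' hydrogen-bond angle satisfy the criterion (cutoffs inclusive). Donors
#' are polar heavy atoms (N/O/S) carrying at least one hydrogen actually
#' present in the structure (see [addPolarHydrogens()]); acceptors follow
#' canonical residue chemistry ([hbondChemistry()]). Pairs within one
#' residue and moiety, and pairs covalently bonded or sharing a bonded
#' neighbour, are excluded. The angle is taken as the minimum over the
#' donor's hydrogens.
#'
#' @param structure a protonated [Structure-class].
#' @param criterion an [hbondCriterion()].
#' @param between optional list of two chain-id sets; only bonds linking
#'   the two sets are returned, reported with the donor/acceptor residue
#'   of the first set as the focal side.
#' @param includeWater include water molecules (default `FALSE`).
#' @return data.frame, one row per hydrogen bond, sorted by donor then
#'   acceptor residue: donor/acceptor chain, residue number, residue name,
#'   atom, moiety, plus `hydrogen`, `distance` (A) and `angle` (degrees).
#' @export
detectHBonds <- function(structure, criterion = hbondCriterion(),
                         between = NULL, includeWater = FALSE) {
  a <- atomData(structure)
  co <- coords(structure)
  donors <- .donorIndices(a, co, includeWater)
  accIdx <- .acceptorIndices(a, includeWater)
  empty <- data.frame(
    donor_chain = character(), donor_resno = integer(),
    donor_resname = character(), donor_atom = character(),
    donor_moiety = character(), hydrogen = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(), acceptor_atom = character(),
    acceptor_moiety = character(), distance = numeric(), angle = numeric(),
    stringsAsFactors = FALSE)
  if (!length(donors) || !length(accIdx)) return(empty)

  excl <- .excludedPairs(structure)
  dIdx <- vapply(donors, `[[`, integer(1), "donor")
  dm <- crossDist(co[dIdx, , drop = FALSE], co[accIdx, , drop = FALSE])
  rows <- list()
  for (k in seq_along(donors)) {
    d <- dIdx[k]
    near <- which(dm[k, ] <= criterion$dMax)
    for (j in near) {
      acc <- accIdx[j]
      if (acc == d) next
      sameRes <- a$chain[acc] == a$chain[d] & a$resno[acc] == a$resno[d]
      mD <- .moietyOf(a$name[d])
      mA <- .moietyOf(a$name[acc])
      if (sameRes && mD == mA) next
      if (paste(min(d, acc), max(d, acc)) %in% excl) next
      hyd <- donors[[k]]$hydrogens
      angs <- vapply(hyd, function(h) {
        if (criterion$angleConvention == "donor")
          angleDeg(co[h, ], co[d, ], co[acc, ])
        else
          180 - angleDeg(co[d, ], co[h, ], co[acc, ])
      }, numeric(1))
      best <- which.min(angs)
      if (angs[best] > criterion$thetaMax) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = a$chain[d], donor_resno = a$resno[d],
        donor_resname = a$resname[d], donor_atom = a$name[d],
        donor_moiety = mD, hydrogen = a$name[hyd[best]],
        acceptor_chain = a$chain[acc], acceptor_resno = a$resno[acc],
        acceptor_resname = a$resname[acc], acceptor_atom = a$name[acc],
        acceptor_moiety = mA, distance = dm[k, j], angle = angs[best],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (!is.null(between)) {
    s1 <- between[[1L]]
    s2 <- between[[2L]]
    fwd <- out$donor_chain %in% s1 & out$acceptor_chain %in% s2
    rev <- out$donor_chain %in% s2 & out$acceptor_chain %in% s1
    out <- out[fwd | rev, , drop = FALSE]
  }
  out <- out[order(out$donor_resno, out$acceptor_resno,
                   out$donor_atom, out$acceptor_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## residue-moiety pair table of a bond list, with the `between[[1]]` side
## as focal. One row per distinct pair (duplicates within a frame collapse).
.bondPairs <- function(bonds, between, atomic = FALSE) {
  if (!nrow(bonds)) {
    return(data.frame(focal_chain = character(), focal_resno = integer(),
                      focal_moiety = character(), partner_chain = character(),
                      partner_resno = integer(), partner_moiety = character(),
                      acceptor_atom = character(), stringsAsFactors = FALSE))
  }
  donorFocal <- bonds$donor_chain %in% between[[1L]]
  out <- data.frame(
    focal_chain = ifelse(donorFocal, bonds$donor_chain, bonds$acceptor_chain),
    focal_resno = ifelse(donorFocal, bonds$donor_resno, bonds$acceptor_resno),
    focal_moiety = ifelse(donorFocal, bonds$donor_moiety,
                          bonds$acceptor_moiety),
    partner_chain = ifelse(donorFocal, bonds$acceptor_chain,
                           bonds$donor_chain),
    partner_resno = ifelse(donorFocal, bonds$acceptor_resno,
                           bonds$donor_resno),
    partner_moiety = ifelse(donorFocal, bonds$acceptor_moiety,
                            bonds$donor_moiety),
    acceptor_atom = if (atomic) bonds$acceptor_atom else "",
    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

.pairKey <- function(p) {
  paste(p$focal_chain, p$focal_resno, p$focal_moiety,
        p$partner_chain, p$partner_resno, p$partner_moiety, p$acceptor_atom)
}

#' Hydrogen-bond occupancies over an ensemble
#'
#' Fraction of frames in which each residue-moiety donor/acceptor pair
#' satisfies the geometric criterion (a pair is present in a frame when at
#' least one atomic hydrogen bond matches it). Frames without hydrogens
#' are protonated on the fly.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param criterion an [hbondCriterion()].
#' @param between list of two chain-id sets; the first set is the focal
#'   side of each reported pair. When `NULL`, all bonds are aggregated
#'   with the donor side as focal.
#' @param atomic also distinguish pairs by acceptor atom identity
#'   (default `FALSE`: residue-moiety granularity).
#' @return data.frame with the pair columns plus `occupancy`,
#'   `frames_present`, `frames_total`, sorted by occupancy descending.
#' @export
hbondOccupancy <- function(ensemble, criterion = hbondCriterion(),
                           between = NULL, atomic = FALSE) {
  if (!nFrames(ensemble)) stop("empty ensemble")
  fr <- frames(ensemble)
  betweenEff <- if (is.null(between))
    list(unique(atomData(fr[[1L]])$chain), character()) else between
  counts <- list()
  for (f in fr) {
    if (!any(toupper(atomData(f)$element) == "H"))
      f <- suppressWarnings(addPolarHydrogens(f))
    bonds <- detectHBonds(f, criterion, between = between)
    pairs <- .bondPairs(bonds, betweenEff, atomic = atomic)
    keys <- .pairKey(pairs)
    for (k in seq_along(keys)) {
      key <- keys[k]
      if (is.null(counts[[key]]))
        counts[[key]] <- list(row = pairs[k, , drop = FALSE], n = 1L)
      else counts[[key]]$n <- counts[[key]]$n + 1L
    }
  }
  ntot <- length(fr)
  if (!length(counts)) {
    out <- .bondPairs(detectHBonds(fr[[1L]], criterion)[0L, ], betweenEff)
    out$occupancy <- numeric(0)
    out$frames_present <- integer(0)
    out$frames_total <- integer(0)
    return(out)
  }
  out <- do.call(rbind, lapply(counts, `[[`, "row"))
  out$frames_present <- vapply(counts, `[[`, integer(1), "n")
  out$frames_total <- ntot
  out$occupancy <- out$frames_present / ntot
  out <- out[order(-out$occupancy, out$focal_resno, out$partner_resno), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter dominant hydrogen bonds
#'
#' Retains pairs with occupancy strictly greater than the threshold
#' (default 20 percent), sorted by occupancy descending.
#'
#' @param occupancies output of [hbondOccupancy()] (any data.frame with an
#'   `occupancy` column).
#' @param threshold occupancy fraction (default 0.20).
#' @return filtered data.frame.
#' @export
dominantBonds <- function(occupancies, threshold = 0.20) {
  out <- occupancies[occupancies$occupancy > threshold, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count maintained wild-type hydrogen bonds
#'
#' How many of a reference set of residue-moiety pairs (typically the
#' dominant wild-type interface bonds) are geometrically satisfied in a
#' structure.
#'
#' @param structure a relaxed complex ([Structure-class]); protonated on
#'   the fly if needed.
#' @param wtBonds data.frame with columns `focal_resno`, `focal_moiety`,
#'   `partner_resno`, `partner_moiety` (chains optional; `acceptor_atom`
#'   used when present and nonempty).
#' @param criterion an [hbondCriterion()].
#' @param between list of two chain-id sets defining the focal/partner
#'   sides.
#' @return integer in `[0, nrow(wtBonds)]`.
#' @export
countWtBonds <- function(structure, wtBonds, criterion = hbondCriterion(),
                         between) {
  if (!any(toupper(atomData(structure)$element) == "H"))
    structure <- suppressWarnings(addPolarHydrogens(structure))
  bonds <- detectHBonds(structure, criterion, between = between)
  atomic <- !is.null(wtBonds$acceptor_atom) &&
    any(nzchar(wtBonds$acceptor_atom))
  pairs <- .bondPairs(bonds, between, atomic = atomic)
  presentKeys <- paste(pairs$focal_resno, pairs$focal_moiety,
                       pairs$partner_resno, pairs$partner_moiety,
                       pairs$acceptor_atom)
  wtKeys <- paste(wtBonds$focal_resno, wtBonds$focal_moiety,
                  wtBonds$partner_resno, wtBonds$partner_moiety,
                  if (atomic) wtBonds$acceptor_atom else "")
  sum(wtKeys %in% presentKeys)
}

#' Salt-bridge center-of-mass distance
#'
#' Distance between the mass center of an acidic side chain's carboxylate
#' oxygens and the mass center of a basic side chain's nitrogen(s).
#'
#' @param structure a [Structure-class].
#' @param acidic,basic residue references: vectors `c(chain, resno)`.
#' @return distance in Angstrom.
#' @export
saltBridgeDistance <- function(structure, acidic, basic) {
  a <- atomData(structure)
  co <- coords(structure)
  pick <- function(ref, kind) {
    chain <- as.character(ref[[1L]])
    resno <- as.integer(ref[[2L]])
    idx <- which(a$chain == chain & a$resno == resno & !a$het)
    if (!length(idx)) stop("no residue ", chain, resno)
    rn <- a$resname[idx[1L]]
    atoms <- switch(kind,
      acidic = switch(rn, ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                      stop("residue ", chain, resno, " (", rn,
                           ") is not an acidic residue")),
      basic = switch(rn, LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"),
                     stop("residue ", chain, resno, " (", rn,
                          ") is not a basic residue")))
    sel <- idx[a$name[idx] %in% atoms]
    if (length(sel) != length(atoms))
      stop("incomplete side chain for residue ", chain, resno)
    m <- atomicMass(a$element[sel])
    colSums(co[sel, , drop = FALSE] * m) / sum(m)
  }
  vnorm(pick(acidic, "acidic") - pick(basic, "basic"))
}
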