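# Saturation-mutagenesis enumeration and backbone-preserving side-chain
# replacement. A mutation grafts a single-conformer template side chain
# into the backbone frame (N/CA/C) of the target residue; no atom outside
# the mutated residue moves. Steric strain is relieved downstream by
# minimization, with a deterministic chi sweep as a first-aid step when
# the grafted rotamer clashes badly.

#' Enumerate all single-point mutations of a sequence
#'
#' Produces the full computational deep-mutational-scanning book-keeping:
#' every position times the 19 non-identity substitutions, ordered by
#' position then alphabetical mutant letter. A 56-residue sequence yields
#' 1064 specifications; restricting to 14 positions yields 266.
#'
#' @param sequence 1-letter amino-acid string (canonical letters only).
#' @param positions optional integer vector restricting the scanned
#'   positions (1-based).
#' @return data.frame with columns `position`, `wt`, `mut`, `label`
#'   (e.g. "E27V").
#' @examples
#' nrow(enumerateMutations(strrep("A", 56)))  # 1064
#' @export
enumerateMutations <- function(sequence, positions = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (!length(aa)) stop("sequence must be nonempty")
  bad <- which(!aa %in% names(.AA3))
  if (length(bad))
    stop("non-canonical amino acid '", aa[bad[1L]], "' at position ", bad[1L])
  if (is.null(positions)) positions <- seq_along(aa)
  if (any(positions < 1L | positions > length(aa)))
    stop("positions out of range 1..", length(aa))
  letters20 <- sort(names(.AA3))
  out <- do.call(rbind, lapply(positions, function(p) {
    muts <- setdiff(letters20, aa[p])
    data.frame(position = p, wt = aa[p], mut = muts,
               label = paste0(aa[p], p, muts), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

## Cartesian side-chain atoms for a residue type given backbone N/CA/C.
## chi overrides the template defaults (padded with defaults when short).
buildSideChain <- function(resname, N, CA, C, chi = NULL) {
  tpl <- sideChainTemplate(resname)
  atoms <- tpl$atoms
  chiVals <- tpl$chi
  if (!is.null(chi)) chiVals[seq_along(chi)] <- chi
  pos <- list(N = N, CA = CA, C = C)
  if (!nrow(atoms))
    return(list(atoms = data.frame(name = character(),
                                   element = character(),
                                   stringsAsFactors = FALSE),
                coords = matrix(numeric(), 0L, 3L)))
  co <- matrix(NA_real_, nrow(atoms), 3L)
  for (k in seq_len(nrow(atoms))) {
    row <- atoms[k, ]
    dih <- if (row$chi > 0L) chiVals[row$chi] + row$off else row$off
    co[k, ] <- placeAtom(pos[[row$rd]], pos[[row$ra]], pos[[row$rb]],
                         row$bond, row$angle, dih)
    pos[[row$name]] <- co[k, ]
  }
  list(atoms = data.frame(name = atoms$name, element = atoms$element,
                          stringsAsFactors = FALSE),
       coords = co)
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")

## clash count of candidate side-chain coords against environment coords
.clashCount <- function(sc, env, threshold) {
  if (!nrow(sc) || !nrow(env)) return(0L)
  d <- crossDist(sc, env)
  sum(d < threshold)
}

#' Apply a single-point mutation to a structure
#'
#' Replaces the side chain of one residue with a template-built side chain
#' of the mutant type, leaving the backbone (N, CA, C, O) and every other
#' residue byte-identical in coordinates. If the grafted most-common
#' rotamer produces heavy-atom contacts below 1.5 A, chi1 (then chi2) is
#' swept in 30-degree steps and the clash-minimal conformer kept
#' (ties broken by smallest deviation from the template rotamer) - a
#' deterministic, seed-free first aid; residual strain is left to
#' minimization. Proline is grafted without ring-closure refinement.
#'
#' @param structure a [Structure-class].
#' @param spec one row of [enumerateMutations()] output (or a list with
#'   `position`, `wt`, `mut`).
#' @param chain chain to mutate (default: first chain).
#' @param clashThreshold heavy-atom distance (A) below which the chi sweep
#'   is triggered.
#' @return mutated [Structure-class] with renumbered serials.
#' @export
applyMutation <- function(structure, spec, chain = chains(structure)[1L],
                          clashThreshold = 1.5) {
  a <- atomData(structure)
  co <- coords(structure)
  pos <- as.integer(spec$position)
  sel <- which(a$chain == chain & a$resno == pos & !a$het)
  if (!length(sel)) stop("no residue ", pos, " on chain ", chain)
  found3 <- a$resname[sel[1L]]
  if (aa321(found3) != toupper(spec$wt))
    stop("wild-type mismatch at position ", pos, ": found ",
         aa321(found3), " (", found3, "), expected ", spec$wt)
  bbIdx <- sel[a$name[sel] %in% .BACKBONE_NAMES]
  if (!all(c("N", "CA", "C", "O") %in% a$name[bbIdx]))
    stop("incomplete backbone at position ", pos, " on chain ", chain)
  mut3 <- aa123(spec$mut)
  if (is.na(mut3)) stop("unknown mutant amino acid '", spec$mut, "'")
  if (mut3 == "PRO")  # grafted proline keeps no amide H
    bbIdx <- bbIdx[!a$name[bbIdx] %in% c("H", "H1", "H2", "H3")]

  N <- co[sel[a$name[sel] == "N"][1L], ]
  CA <- co[sel[a$name[sel] == "CA"][1L], ]
  C <- co[sel[a$name[sel] == "C"][1L], ]

  tpl <- sideChainTemplate(mut3)
  env <- co[-sel, , drop = FALSE]
  env <- env[toupper(a$element[-sel]) != "H", , drop = FALSE]
  sc <- buildSideChain(mut3, N, CA, C)
  nclash <- .clashCount(sc$coords, env, clashThreshold)
  if (nclash > 0L && length(tpl$chi)) {
    best <- list(sc = sc, n = nclash, dev = 0)
    sweep1 <- tpl$chi[1L] + seq(0, 330, by = 30)
    sweep2 <- if (length(tpl$chi) >= 2L)
      tpl$chi[2L] + seq(0, 330, by = 30) else tpl$chi[2L][0]
    for (c1 in sweep1) {
      cand1 <- buildSideChain(mut3, N, CA, C, chi = c1)
      n1 <- .clashCount(cand1$coords, env, clashThreshold)
      dev1 <- abs(c1 - tpl$chi[1L])
      if (n1 < best$n || (n1 == best$n && dev1 < best$dev)) {
        best <- list(sc = cand1, n = n1, dev = dev1, chi = c1)
      }
    }
    if (best$n > 0L && length(sweep2)) {
      c1 <- if (!is.null(best$chi)) best$chi else tpl$chi[1L]
      for (c2 in sweep2) {
        cand2 <- buildSideChain(mut3, N, CA, C, chi = c(c1, c2))
        n2 <- .clashCount(cand2$coords, env, clashThreshold)
        dev2 <- abs(c1 - tpl$chi[1L]) + abs(c2 - tpl$chi[2L])
        if (n2 < best$n || (n2 == best$n && dev2 < best$dev))
          best <- list(sc = cand2, n = n2, dev = dev2, chi = c1)
      }
    }
    sc <- best$sc
  }

  keepBefore <- seq_len(nrow(a)) < min(sel)
  keepAfter <- seq_len(nrow(a)) > max(sel)
  bbRel <- bbIdx
  newAtoms <- rbind(
    a[keepBefore, , drop = FALSE],
    transform(a[bbRel, , drop = FALSE], resname = mut3),
    if (nrow(sc$atoms)) data.frame(
      serial = 0L, name = sc$atoms$name, element = sc$atoms$element,
      resno = pos, resname = mut3, chain = chain, het = FALSE, flag = FALSE,
      stringsAsFactors = FALSE),
    a[keepAfter, , drop = FALSE])
  newCo <- rbind(co[keepBefore, , drop = FALSE],
                 co[bbRel, , drop = FALSE],
                 sc$coords,
                 co[keepAfter, , drop = FALSE])
  newAtoms$serial <- seq_len(nrow(newAtoms))
  out <- newStructure(newAtoms, newCo,
                      label = paste0(structure@label, "_",
                                     spec$wt, pos, spec$mut))
  out
}

#' Detect steric clashes
#'
#' All heavy-atom pairs closer than `threshold`, excluding covalently
#' bonded (1-2) and angle (1-3) pairs; sorted by distance ascending.
#'
#' @param structure a [Structure-class].
#' @param threshold distance cutoff (A).
#' @return data.frame with columns `i`, `j` (atom indices), `distance`.
#' @export
detectClashes <- function(structure, threshold) {
  heavy <- which(isHeavy(structure))
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (threshold <= 0 || length(heavy) < 2L) return(empty)
  co <- coords(structure)[heavy, , drop = FALSE]
  d <- crossDist(co, co)
  excl <- .excludedPairs(structure)
  hits <- which(upper.tri(d) & d < threshold, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  gi <- heavy[hits[, 1L]]
  gj <- heavy[hits[, 2L]]
  pkey <- paste(pmin(gi, gj), pmax(gi, gj))
  ok <- !pkey %in% excl
  out <- data.frame(i = gi[ok], j = gj[ok],
                    distance = d[hits][ok])
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## covalent bond list by distance criterion (r_cov sum + 0.4 A).
## Hetero atoms (waters, ions, pseudo-atoms) never form inferred bonds.
.bondList <- function(structure) {
  a <- atomData(structure)
  co <- coords(structure)
  n <- nrow(co)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  rc <- covalentRadius(a$element)
  rc[a$het] <- -10  # het atoms cannot satisfy the bond criterion
  d <- crossDist(co, co)
  lim <- outer(rc, rc, "+") + 0.4
  hits <- which(upper.tri(d) & d < lim & d > 0.1, arr.ind = TRUE)
  unname(as.matrix(hits))
}

## keys "i j" (i<j) of 1-2 and 1-3 pairs
.excludedPairs <- function(structure, bonds = .bondList(structure)) {
  if (!nrow(bonds)) return(character())
  keys <- paste(pmin(bonds[, 1L], bonds[, 2L]),
                pmax(bonds[, 1L], bonds[, 2L]))
  adj <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  for (ctr in names(adj)) {
    nb <- adj[[ctr]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      keys <- c(keys, paste(cmb[1L, ], cmb[2L, ]))
    }
  }
  unique(keys)
}
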