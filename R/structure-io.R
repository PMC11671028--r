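# PDB input/output, complex splitting and heavy-atom RMSD.
# Parsing and least-squares superposition are delegated to bio3d; this
# layer adds altLoc resolution by occupancy, insertion-code rejection,
# multi-model ensembles and the S4 container.

## element symbol from a PDB atom record
.inferElement <- function(elety, elesy = NULL) {
  el <- if (!is.null(elesy)) toupper(trimws(elesy)) else
    rep("", length(elety))
  fix <- is.na(el) | el == "" | !el %in% names(.VDW_RADII)
  if (any(fix)) {
    nm <- toupper(trimws(elety[fix]))
    nm <- sub("^[0-9']+", "", nm)
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    guess <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "SD"),
                    ifelse(two == "SD", "S", two), one)
    el[fix] <- guess
  }
  el
}

.bio3dToAtoms <- function(at) {
  data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = .inferElement(at$elety, at$elesy),
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    het = at$type == "HETATM",
    flag = FALSE,
    stringsAsFactors = FALSE)
}

## resolve alternate locations: keep highest occupancy, ties -> first listed
.resolveAltLoc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt))) return(seq_len(nrow(at)))
  key <- paste(at$chain, at$resno, at$resid, trimws(at$elety))
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[!is.na(alt)])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    best <- idx[which.max(occ[idx])]  # which.max: ties -> first listed
    keep[setdiff(idx, best)] <- FALSE
  }
  which(keep)
}

.checkBackbone <- function(atoms) {
  std <- !atoms$het & isStandardRes(atoms$resname)
  if (!any(std)) return(atoms)
  key <- paste(atoms$chain, atoms$resno)
  bad <- character()
  for (k in unique(key[std])) {
    idx <- which(key == k & std)
    if (!all(c("N", "CA", "C", "O") %in% atoms$name[idx])) {
      atoms$flag[idx] <- TRUE
      bad <- c(bad, paste0(atoms$chain[idx[1L]], atoms$resno[idx[1L]]))
    }
  }
  if (length(bad))
    warning("residue(s) with incomplete backbone flagged: ",
            paste(bad, collapse = ", "), call. = FALSE)
  atoms
}

#' Read a PDB coordinate file
#'
#' Parses ATOM/HETATM records into a [Structure-class]. Waters and hetero
#' groups are retained but flagged; alternate locations are resolved to
#' the highest-occupancy conformer (ties keep the first listed); residues
#' missing backbone atoms are flagged with a warning. Files containing
#' insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param model model number for multi-model files (default 1).
#' @param label optional label (default: file name).
#' @return a [Structure-class] object.
#' @seealso [readPdbEnsemble()] for all models, [writePdb()].
#' @export
readPdb <- function(path, model = 1L, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (any(!is.na(at$insert) & trimws(at$insert) != ""))
    stop("insertion codes are not supported (found in '", path, "')")
  keep <- .resolveAltLoc(at)
  nmodels <- nrow(pdb$xyz)
  if (is.null(nmodels)) nmodels <- 1L
  if (model < 1L || model > nmodels)
    stop("model ", model, " requested but file has ", nmodels, " model(s)")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  co <- matrix(xyz, ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
  atoms <- .checkBackbone(.bio3dToAtoms(at[keep, , drop = FALSE]))
  newStructure(atoms, co, label = label)
}

#' Read all models of a multi-model PDB as an ensemble
#'
#' @inheritParams readPdb
#' @return a [StructureEnsemble-class] with source `"multi-model-pdb"`.
#' @export
readPdbEnsemble <- function(path, label = basename(path)) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  frames <- lapply(seq_len(nmodels), function(m)
    readPdb(path, model = m, label = paste0(label, "#", m)))
  newEnsemble(frames, source = "multi-model-pdb")
}

.formatAtomName <- function(name, element) {
  # columns 13-16; single-letter elements start in column 14
  base <- ifelse(nchar(name) >= 4L, substr(name, 1, 4),
                 ifelse(nchar(element) == 1L, paste0(" ", name), name))
  sprintf("%-4s", base)
}

.atomRecords <- function(x) {
  a <- x@atoms
  co <- x@coords
  rectype <- ifelse(a$het, "HETATM", "ATOM  ")
  sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, a$serial %% 100000L, .formatAtomName(a$name, a$element),
          "", formatC(a$resname, width = 3L), substr(a$chain, 1, 1),
          a$resno %% 10000L, "", co[, 1L], co[, 2L], co[, 3L], 1, 0,
          formatC(toupper(a$element), width = 2L))
}

#' Write a Structure or ensemble to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records with 3-decimal coordinates (so a
#' read/write round trip is coordinate-stable to 0.001 A); ensembles are
#' written as MODEL/ENDMDL blocks.
#'
#' @param x a [Structure-class] or [StructureEnsemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePdb <- function(x, path) {
  if (is(x, "StructureEnsemble")) {
    lines <- unlist(lapply(seq_along(x@frames), function(i)
      c(sprintf("MODEL     %4d", i), .atomRecords(x@frames[[i]]), "ENDMDL")))
    writeLines(c(lines, "END"), path)
    return(invisible(path))
  }
  stopifnot(is(x, "Structure"))
  if (nAtoms(x) > 99999L)
    stop("PDB format limit exceeded: ", nAtoms(x), " atoms (max 99999)")
  writeLines(c(.atomRecords(x), "END"), path)
  invisible(path)
}

#' Split a complex into focal and partner structures
#'
#' Partitions the solute atoms of a complex by chain: the focal chains on
#' one side, everything else on the other. Waters and monoatomic ions are
#' excluded from both parts.
#'
#' @param complex a [Structure-class].
#' @param focalChains character vector of chain identifiers.
#' @return list with elements `focal` and `partner`, both
#'   [Structure-class] objects.
#' @export
splitComplex <- function(complex, focalChains) {
  a <- atomData(complex)
  avail <- unique(a$chain)
  if (!length(focalChains)) stop("focalChains must be nonempty")
  if (!all(focalChains %in% avail))
    stop("unknown chain id(s) ",
         paste(setdiff(focalChains, avail), collapse = ", "),
         "; available chains: ", paste(avail, collapse = ", "))
  solvent <- isWaterRes(a$resname) | isIonRes(a$resname)
  fidx <- which(a$chain %in% focalChains & !solvent)
  pidx <- which(!(a$chain %in% focalChains) & !solvent)
  if (!length(pidx)) stop("partner is empty: all solute chains are focal")
  list(focal = subsetStructure(complex, fidx,
                               label = paste0(complex@label, ":focal")),
       partner = subsetStructure(complex, pidx,
                                 label = paste0(complex@label, ":partner")))
}

#' Heavy-atom RMSD between two structures
#'
#' Root-mean-square deviation over heavy (non-hydrogen) atoms, paired by
#' chain, residue number and atom name. With `superpose = TRUE` an optimal
#' rigid-body least-squares fit (Kabsch, via bio3d) is applied first.
#'
#' @param a,b [Structure-class] objects with matching heavy atoms.
#' @param superpose apply optimal superposition first (default `FALSE`:
#'   minimization keeps the laboratory frame, so raw deviations are the
#'   quantity of interest).
#' @return RMSD in Angstrom.
#' @export
rmsdHeavy <- function(a, b, superpose = FALSE) {
  ka <- which(isHeavy(a))
  kb <- which(isHeavy(b))
  aa <- atomData(a)[ka, ]
  ab <- atomData(b)[kb, ]
  keyA <- paste(aa$chain, aa$resno, aa$name)
  keyB <- paste(ab$chain, ab$resno, ab$name)
  m <- match(keyA, keyB)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1L]
    stop("atom mismatch: no counterpart for ", keyA[bad])
  }
  if (anyDuplicated(keyB) || length(keyB) != length(keyA)) {
    extra <- setdiff(keyB, keyA)
    if (length(extra)) stop("atom mismatch: no counterpart for ", extra[1L])
  }
  A <- coords(a)[ka, , drop = FALSE]
  B <- coords(b)[kb, , drop = FALSE][m, , drop = FALSE]
  if (superpose) {
    xyzA <- as.vector(t(A))
    xyzB <- as.vector(t(B))
    B <- matrix(bio3d::fit.xyz(fixed = xyzA, mobile = xyzB,
                               fixed.inds = seq_along(xyzA),
                               mobile.inds = seq_along(xyzB)),
                ncol = 3L, byrow = TRUE)
  }
  sqrt(mean(rowSums((A - B)^2)))
}
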